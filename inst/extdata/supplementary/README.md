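# Published field data (not distributed)

The field study's supplementary trap-catch data are not distributed with
this package. To run the full-data checks, place the table here as
`trap_catches.csv` in the package's long format:

    transect,period,distance_m,trap,species,count

with `period` one of `early_spring`, `late_spring`, `summer`,
`late_summer`, `autumn`; `distance_m` one of -20, -10, -3, 0, 3, 10, 20
(woodlot negative); `trap` 1-4. See `?read_catch_table`.
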