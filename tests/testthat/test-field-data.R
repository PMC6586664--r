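test_that("catch tables round-trip through delimited files and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(transect = "T1", period = "summer", distance_m = 0,
                       trap = 1, species = "Poecilus cupreus", count = 5),
            path, row.names = FALSE)
  tab <- read_catch_table(path)
  expect_s3_class(tab, "catch_table")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$count, 5L)
  expect_equal(tab$species, "Poecilus cupreus")

  bad <- data.frame(transect = "T1", period = "summer", distance_m = 15,
                    trap = 1, species = "x", count = 1)
  expect_error(as_catch_table(bad), "distance_m outside the sampling design")
  bad$distance_m <- 0; bad$count <- -2
  expect_error(as_catch_table(bad), "non-negative integer")
  bad$count <- 1; bad$trap <- 9
  expect_error(as_catch_table(bad), "trap index")
  bad$trap <- 1; bad$period <- "monsoon"
  expect_error(as_catch_table(bad), "unknown sampling period")
})

test_that("full design coverage: 112 traps per period, 28 pooled samples", {
  g <- generate_catch_table(tiny_scenario(), seed = 1)
  per <- unique(as.character(g$catch$period))
  for (p in per) {
    sub <- g$catch[g$catch$period == p, ]
    expect_equal(nrow(unique(sub[c("transect", "distance_m", "trap")])), 112L)
  }
  pooled <- pool_traps(g$catch)
  for (p in per) {
    sub <- pooled[pooled$period == p, ]
    expect_equal(nrow(unique(sub[c("transect", "distance_m")])), 28L)
  }
})

test_that("exclude_period drops exactly the named period", {
  g <- generate_catch_table(tiny_scenario(), seed = 2)
  out <- exclude_period(g$catch, "autumn")
  expect_false("autumn" %in% as.character(out$period))
  expect_equal(sum(out$count),
               sum(g$catch$count) - sum(g$catch$count[g$catch$period == "autumn"]))
  # excluding an absent period leaves the table unchanged
  again <- exclude_period(out, "autumn")
  expect_equal(as.data.frame(again), as.data.frame(out))
  expect_error(exclude_period(g$catch, "monsoon"), "unknown sampling period")
})

test_that("pool_traps sums the four traps and conserves totals", {
  tab <- as_catch_table(data.frame(
    transect = "T1", period = "summer", distance_m = 0, trap = 1:4,
    species = "sp open A", count = 1:4))
  pooled <- pool_traps(tab)
  expect_equal(pooled$count, 10L)

  g <- generate_catch_table(tiny_scenario(), seed = 3)
  pooled <- pool_traps(g$catch)
  # brute-force aggregation oracle
  key <- paste(g$catch$transect, g$catch$period, g$catch$distance_m,
               g$catch$species)
  oracle <- tapply(g$catch$count, key, sum)
  got <- setNames(pooled$count, paste(pooled$transect, pooled$period,
                                      pooled$distance_m, pooled$species))
  oracle <- oracle[oracle > 0 | names(oracle) %in% names(got)]
  expect_equal(sum(pooled$count), sum(g$catch$count))
  expect_true(all(got == oracle[names(got)]))
  # per-period conservation
  expect_equal(tapply(pooled$count, pooled$period, sum),
               tapply(g$catch$count, g$catch$period, sum))
})

test_that("pool_traps warns when a site has missing trap indices", {
  tab <- as_catch_table(data.frame(
    transect = "T1", period = "summer", distance_m = 0, trap = c(1, 2),
    species = "sp open A", count = c(3, 4)))
  expect_warning(pool_traps(tab), "fewer than 4 distinct trap")
  expect_silent(p <- pool_traps(tab, warn_missing = FALSE))
  expect_equal(p$count, 7L)
})

test_that("rare-species filter uses the 'fewer than min_total' boundary and is idempotent", {
  pooled <- pool_traps(as_catch_table(data.frame(
    transect = "T1", period = "summer", distance_m = 0, trap = 1,
    species = rep(c("rare", "kept"), c(3, 4)), count = 1)),
    warn_missing = FALSE)
  filt <- filter_rare_species(pooled, 4)
  expect_setequal(unique(filt$species), "kept")
  expect_equal(filter_rare_species(filt, 4), filt)

  # random table equals the two-pass tally-then-drop oracle
  set.seed(42)
  g <- generate_catch_table(tiny_scenario(), seed = 4)
  pooled <- pool_traps(g$catch)
  filt <- filter_rare_species(pooled, 10)
  tot <- tapply(pooled$count, pooled$species, sum)
  expect_setequal(unique(filt$species), names(tot)[tot >= 10])

  expect_error(filter_rare_species(pooled, 1e6), "no species left")
})

test_that("relative abundance: normalisation, groups, undefined profiles", {
  tr <- toy_traits()
  # equal counts everywhere -> 1/7 each
  tab <- toy_catch(counts = 2L)
  prof <- relative_abundance(pool_traps(tab, warn_missing = FALSE), tr, "all")
  expect_equal(prof$value, rep(1 / 7, 7))
  expect_equal(sum(prof$value), 1)

  # all individuals in one sample -> 1 there, 0 elsewhere
  grid <- expand.grid(trap = 1:4, distance_m = design_distances(),
                      KEEP.OUT.ATTRS = FALSE)
  grid$transect <- "T1"; grid$period <- "summer"
  grid$species <- "sp open A"
  grid$count <- ifelse(grid$distance_m == 3, 5L, 0L)
  prof <- relative_abundance(pool_traps(as_catch_table(grid),
                                        warn_missing = FALSE), tr, "all")
  expect_equal(prof$value[prof$distance_m == 3], 1)
  expect_equal(sum(prof$value), 1)

  # species missing from traits is a named error
  tab2 <- toy_catch()
  tab2$species[1] <- "Unknownus beetlei"
  expect_error(
    relative_abundance(pool_traps(tab2, warn_missing = FALSE), tr,
                       "open_habitat"),
    "Unknownus beetlei")

  # group absent -> undefined (NA) profile, not zeros
  prof <- relative_abundance(pool_traps(toy_catch(), warn_missing = FALSE),
                             tr, "generalist")
  expect_true(all(is.na(prof$value)))
  expect_equal(unique(prof$denominator), 0L)
})

test_that("group=all abundance equals the group-weighted mixture of group profiles", {
  sc <- tiny_scenario()
  g <- generate_catch_table(sc, seed = 5)
  pooled <- pool_traps(g$catch)
  tr <- scenario_traits(sc)
  p_all <- relative_abundance(pooled, tr, "all")
  groups <- habitat_groups()
  parts <- lapply(groups, function(gr) relative_abundance(pooled, tr, gr))
  for (tp in unique(paste(p_all$transect, p_all$period))) {
    sel <- paste(p_all$transect, p_all$period) == tp
    denom_all <- p_all$denominator[sel][1]
    mix <- rep(0, sum(sel))
    for (k in seq_along(groups)) {
      pk <- parts[[k]][paste(parts[[k]]$transect, parts[[k]]$period) == tp, ]
      if (pk$denominator[1] > 0) {
        mix <- mix + pk$value * pk$denominator[1] / denom_all
      }
    }
    expect_equal(p_all$value[sel], mix, tolerance = 1e-12)
  }
})

test_that("relative richness: bounds, extremes and presence oracle", {
  tr <- toy_traits()
  # one species present everywhere -> all values 1, sum 7
  tab <- toy_catch(counts = 1L)
  tab <- tab[tab$species == "sp open A", ]
  class(tab) <- c("catch_table", "data.frame")
  prof <- relative_richness(pool_traps(tab, warn_missing = FALSE), tr, "all")
  expect_equal(prof$value, rep(1, 7))
  expect_equal(sum(prof$value), 7)

  # species present at exactly one distance each -> values sum to 1
  grid <- data.frame(transect = "T1", period = "summer",
                     distance_m = design_distances(), trap = 1L,
                     species = paste("sp", 1:7), count = 1L)
  tr7 <- as_species_traits(data.frame(species = paste("sp", 1:7),
                                      group = "open_habitat"))
  prof <- relative_richness(pool_traps(as_catch_table(grid),
                                       warn_missing = FALSE), tr7, "all")
  expect_equal(sum(prof$value), 1)

  # random data against a presence/absence oracle
  g <- generate_catch_table(tiny_scenario(), seed = 6)
  pooled <- pool_traps(g$catch)
  tr2 <- scenario_traits(tiny_scenario())
  prof <- relative_richness(pooled, tr2, "open_habitat")
  open_sp <- tr2$species[tr2$group == "open_habitat"]
  sub <- pooled[pooled$species %in% open_sp & pooled$count > 0, ]
  for (i in sample(nrow(prof), 20)) {
    row <- prof[i, ]
    here <- sub[sub$transect == row$transect & sub$period == row$period, ]
    pool_n <- length(unique(here$species))
    at_d <- length(unique(here$species[here$distance_m == row$distance_m]))
    if (pool_n == 0) expect_true(is.na(row$value))
    else expect_equal(row$value, at_d / pool_n)
  }
  expect_true(all(prof$value >= 0 & prof$value <= 1, na.rm = TRUE))
})

test_that("log transform is log10(x+1) and rejects negatives", {
  expect_equal(log_transform(matrix(c(0, 9, 99), 1)), matrix(c(0, 1, 2), 1))
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("community matrix completes the design grid and places counts", {
  g <- generate_catch_table(tiny_scenario(), seed = 7)
  pooled <- pool_traps(g$catch)
  comm <- community_matrix(pooled)
  expect_equal(nrow(comm$abund), nrow(comm$meta))
  expect_equal(nrow(comm$abund), 4 * 4 * 7)
  expect_equal(sum(comm$abund), sum(pooled$count))
  i <- which(pooled$count > 0)[1]
  r <- paste(pooled$transect[i], pooled$period[i], pooled$distance_m[i],
             sep = ".")
  expect_equal(comm$abund[r, pooled$species[i]], pooled$count[i])
})
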