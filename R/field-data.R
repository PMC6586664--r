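#' Design constants of the transect sampling layout
#'
#' The sampling design places pitfall-trap sites along transects crossing an
#' arable field-woodlot boundary at seven signed distances (negative = into the
#' woodlot, positive = into the field, 0 = the boundary), with four traps per
#' site, four transects, and five named sampling periods of which the damaged
#' late-summer one is excluded from analysis.
#'
#' @return `design_distances()`: integer vector of the seven signed trap-site
#'   distances in metres. `period_levels()`: character vector of the five
#'   sampling-period labels in seasonal order. `analysis_periods()`: the four
#'   periods retained for analysis. `habitat_groups()`: the three
#'   habitat-preference classes used to split analyses.
#' @export
design_distances <- function() c(-20L, -10L, -3L, 0L, 3L, 10L, 20L)

#' @rdname design_distances
#' @export
period_levels <- function() {
  c("early_spring", "late_spring", "summer", "late_summer", "autumn")
}

#' @rdname design_distances
#' @export
analysis_periods <- function() {
  c("early_spring", "late_spring", "summer", "autumn")
}

#' @rdname design_distances
#' @export
habitat_groups <- function() c("open_habitat", "forest", "generalist")

## species names are matched exactly after whitespace squeeze + case folding
normalize_species <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Construct a validated catch table
#'
#' A catch table is the raw observational unit: one row per
#' (transect, period, distance, trap, species) with a non-negative count.
#'
#' @param df data frame with columns `transect`, `period`, `distance_m`,
#'   `trap`, `species`, `count`.
#' @param species_map optional data frame with columns `from`, `to` mapping
#'   species name variants (e.g. abbreviations) to canonical names; applied
#'   after whitespace/case normalisation.
#' @param distances allowed signed trap-site distances (metres).
#' @param traps_per_site maximum trap index allowed at a site.
#' @return a `catch_table` (a data frame with factor `period` in seasonal
#'   order and integer `distance_m`, `trap`, `count`).
#' @export
as_catch_table <- function(df, species_map = NULL,
                           distances = design_distances(),
                           traps_per_site = 4L) {
  required <- c("transect", "period", "distance_m", "trap", "species", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("catch table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]

  df$distance_m <- suppressWarnings(as.integer(df$distance_m))
  df$trap <- suppressWarnings(as.integer(df$trap))
  count_num <- suppressWarnings(as.numeric(df$count))

  bad <- which(is.na(count_num) | count_num < 0 | count_num != round(count_num))
  if (length(bad)) {
    stop("invalid count (must be a non-negative integer) in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df$count <- as.integer(count_num)

  bad <- which(is.na(df$distance_m) | !(df$distance_m %in% distances))
  if (length(bad)) {
    stop("distance_m outside the sampling design (",
         paste(distances, collapse = ", "), ") in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(is.na(df$trap) | df$trap < 1L | df$trap > traps_per_site)
  if (length(bad)) {
    stop("trap index outside 1..", traps_per_site, " in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }

  per <- as.character(df$period)
  bad <- which(!(per %in% period_levels()))
  if (length(bad)) {
    stop("unknown sampling period '", per[bad[1L]], "' in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (known: ", paste(period_levels(), collapse = ", "), ")")
  }
  df$period <- factor(per, levels = intersect(period_levels(), unique(per)))
  df$transect <- factor(as.character(df$transect))

  df$species <- gsub("[[:space:]]+", " ", trimws(as.character(df$species)))
  if (!is.null(species_map)) {
    stopifnot(all(c("from", "to") %in% names(species_map)))
    key <- normalize_species(species_map$from)
    hit <- match(normalize_species(df$species), key)
    df$species[!is.na(hit)] <- as.character(species_map$to)[hit[!is.na(hit)]]
  }

  rownames(df) <- NULL
  class(df) <- c("catch_table", "data.frame")
  attr(df, "distances") <- as.integer(distances)
  attr(df, "traps_per_site") <- as.integer(traps_per_site)
  df
}

#' Read a long-format trap-catch table
#'
#' @param path path to a delimited text file with header columns `transect`,
#'   `period`, `distance_m`, `trap`, `species`, `count`.
#' @param sep field delimiter; if `NULL`, auto-detected (tab vs comma).
#' @inheritParams as_catch_table
#' @return a validated [as_catch_table()] object.
#' @export
read_catch_table <- function(path, sep = NULL, species_map = NULL,
                             distances = design_distances(),
                             traps_per_site = 4L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  as_catch_table(raw, species_map = species_map, distances = distances,
                 traps_per_site = traps_per_site)
}

#' Read a species-trait table mapping species to habitat groups
#'
#' Habitat-preference classes (after the standard carabid classification):
#' open-habitat specialists, forest specialists and habitat generalists.
#' Group labels are normalised (e.g. `"open-habitat"` -> `"open_habitat"`).
#'
#' @param path delimited text file with columns `species` and `group`.
#' @param sep delimiter, auto-detected when `NULL`.
#' @return data frame with columns `species`, `group` (factor with levels
#'   [habitat_groups()]).
#' @export
read_species_traits <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_species_traits(raw)
}

#' @rdname read_species_traits
#' @param df data frame with columns `species`, `group`.
#' @export
as_species_traits <- function(df) {
  if (!all(c("species", "group") %in% names(df))) {
    stop("trait table needs columns 'species' and 'group'")
  }
  grp <- gsub("[-[:space:]]+", "_", tolower(trimws(as.character(df$group))))
  grp[grp %in% c("open", "open_habitat_species")] <- "open_habitat"
  grp[grp %in% c("forest_species", "woodland")] <- "forest"
  grp[grp %in% c("habitat_generalist", "generalist_species")] <- "generalist"
  bad <- !(grp %in% habitat_groups())
  if (any(bad)) {
    stop("unknown habitat group(s): ",
         paste(unique(df$group[bad]), collapse = ", "))
  }
  out <- data.frame(
    species = gsub("[[:space:]]+", " ", trimws(as.character(df$species))),
    group = factor(grp, levels = habitat_groups()),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(normalize_species(out$species))) {
    stop("duplicated species in trait table")
  }
  out
}

#' Drop a sampling period from a catch table
#'
#' Used to remove the damaged late-summer sampling period before analysis.
#'
#' @param x a `catch_table`.
#' @param period one or more period labels to drop (must be known levels).
#' @return the catch table without rows from those periods.
#' @export
exclude_period <- function(x, period = "late_summer") {
  stopifnot(inherits(x, "catch_table"))
  bad <- setdiff(period, period_levels())
  if (length(bad)) stop("unknown sampling period: ", paste(bad, collapse = ", "))
  keep <- !(as.character(x$period) %in% period)
  out <- x[keep, , drop = FALSE]
  out$period <- droplevels(out$period)
  out$transect <- droplevels(out$transect)
  rownames(out) <- NULL
  out
}

#' Pool the four traps of each sampling site into one sample
#'
#' Counts are summed over trap index within each
#' (transect, period, distance) cell; with the full design this yields 28
#' pooled samples per period. Sites represented by fewer than
#' `traps_per_site` distinct trap indices are pooled over what exists, with a
#' warning (zero-catch traps omitted from a sparse input file are
#' indistinguishable from missing traps).
#'
#' @param x a `catch_table`.
#' @param warn_missing warn when a site has fewer than the design number of
#'   distinct trap indices.
#' @return a `pooled_catch` data frame with columns `transect`, `period`,
#'   `distance_m`, `species`, `count`.
#' @export
pool_traps <- function(x, warn_missing = TRUE) {
  stopifnot(inherits(x, "catch_table"))
  tps <- attr(x, "traps_per_site")
  if (is.null(tps)) tps <- 4L
  if (warn_missing && nrow(x)) {
    site <- interaction(x$transect, x$period, x$distance_m, drop = TRUE)
    ntrap <- tapply(x$trap, site, function(t) length(unique(t)))
    short <- sum(ntrap < tps)
    if (short > 0) {
      warning(short, " site(s) have fewer than ", tps,
              " distinct trap indices; pooling over what exists")
    }
  }
  agg <- stats::aggregate(count ~ transect + period + distance_m + species,
                          data = x, FUN = sum)
  agg <- agg[order(agg$period, agg$transect, agg$distance_m, agg$species), ]
  rownames(agg) <- NULL
  class(agg) <- c("pooled_catch", "data.frame")
  attr(agg, "distances") <- attr(x, "distances")
  agg
}

#' Exclude rare species from pooled samples
#'
#' Species represented by fewer than `min_total` specimens over the whole
#' (post-exclusion) dataset are removed everywhere; retained species keep all
#' their counts. The operation is idempotent.
#'
#' @param x a `pooled_catch` (or any data frame with `species` and `count`).
#' @param min_total minimum grand-total specimen count for a species to be
#'   retained (default 4: species with fewer than 4 specimens are dropped).
#' @return the filtered object.
#' @export
filter_rare_species <- function(x, min_total = 4L) {
  stopifnot(min_total >= 1)
  tot <- tapply(x$count, x$species, sum)
  keep <- names(tot)[tot >= min_total]
  out <- x[x$species %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no species left after the rare-species filter (min_total = ",
         min_total, ")")
  }
  rownames(out) <- NULL
  out
}

#' Totals of individuals and species, overall and per period
#'
#' Bookkeeping summary of a catch table or pooled samples: grand totals plus
#' per-period individual and species counts.
#'
#' @param x a `catch_table` or `pooled_catch`.
#' @return list with `individuals`, `species`, and a data frame `per_period`.
#' @export
dataset_summary <- function(x) {
  present <- x[x$count > 0L, , drop = FALSE]
  per <- levels(x$period)
  per_period <- data.frame(
    period = per,
    individuals = vapply(per, function(p)
      sum(x$count[x$period == p]), numeric(1)),
    species = vapply(per, function(p)
      length(unique(present$species[present$period == p])), numeric(1)),
    row.names = NULL
  )
  list(individuals = sum(x$count),
       species = length(unique(present$species)),
       per_period = per_period)
}

## subset rows of pooled samples to one habitat group ("all" keeps everything)
select_group <- function(x, traits, group) {
  group <- match.arg(group, c("all", habitat_groups()))
  if (group == "all") return(x)
  if (is.null(traits)) stop("a species-trait table is required for group = '",
                            group, "'")
  hit <- match(normalize_species(x$species), normalize_species(traits$species))
  if (anyNA(hit)) {
    stop("species missing from the trait table: ",
         paste(unique(x$species[is.na(hit)]), collapse = ", "))
  }
  x[as.character(traits$group)[hit] == group, , drop = FALSE]
}

#' Relative abundance and relative species richness profiles
#'
#' For each (transect, period), relative abundance at a distance is the pooled
#' specimen count there divided by the total collected along that transect in
#' that period (for the chosen habitat group); the seven values sum to 1.
#' Relative richness replaces specimen counts by species counts: the value at
#' a distance is the number of species present there divided by the number of
#' species present anywhere on the transect in that period. Because a species
#' can occur at several distances, richness values may sum to more than 1
#' (at most 7).
#'
#' A transect-period where the group is entirely absent has denominator 0 and
#' is carried as an explicit undefined profile (`value = NA`), distinct from
#' observed zeros; such profiles are excluded from curve fitting.
#'
#' @param x a `pooled_catch`.
#' @param traits trait table (see [read_species_traits()]); required unless
#'   `group = "all"`.
#' @param group `"all"` or one of [habitat_groups()].
#' @param distances the gradient positions to profile over.
#' @return a `relative_profiles` data frame with columns `transect`, `period`,
#'   `group`, `response`, `distance_m`, `value`, `denominator`.
#' @export
relative_abundance <- function(x, traits = NULL, group = "all",
                               distances = design_distances()) {
  profile_engine(x, traits, group, distances, response = "abundance")
}

#' @rdname relative_abundance
#' @export
relative_richness <- function(x, traits = NULL, group = "all",
                              distances = design_distances()) {
  profile_engine(x, traits, group, distances, response = "richness")
}

profile_engine <- function(x, traits, group, distances, response) {
  stopifnot(inherits(x, "pooled_catch") || is.data.frame(x))
  sel <- select_group(x, traits, group)
  combos <- unique(data.frame(transect = as.character(x$transect),
                              period = as.character(x$period),
                              stringsAsFactors = FALSE))
  combos <- combos[order(combos$period, combos$transect), , drop = FALSE]
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- sel[as.character(sel$transect) == combos$transect[i] &
               as.character(sel$period) == combos$period[i], , drop = FALSE]
    if (response == "abundance") {
      denom <- sum(sub$count)
      vals <- vapply(distances, function(d)
        sum(sub$count[sub$distance_m == d]), numeric(1))
    } else {
      pres <- sub[sub$count > 0L, , drop = FALSE]
      denom <- length(unique(pres$species))
      vals <- vapply(distances, function(d)
        length(unique(pres$species[pres$distance_m == d])), numeric(1))
    }
    value <- if (denom > 0) vals / denom else rep(NA_real_, length(distances))
    out[[i]] <- data.frame(
      transect = combos$transect[i], period = combos$period[i],
      group = group, response = response,
      distance_m = as.integer(distances), value = value,
      denominator = as.integer(denom), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$period <- factor(res$period, levels = intersect(period_levels(),
                                                      unique(res$period)))
  rownames(res) <- NULL
  class(res) <- c("relative_profiles", "data.frame")
  res
}

#' Wide community matrix of pooled samples by species
#'
#' One row per pooled sample (transect x period x distance, completed to the
#' full set of design distances with zero counts), one column per species.
#'
#' @param x a `pooled_catch`.
#' @param distances gradient positions defining the completed sample grid.
#' @return a `community_matrix`: list with `abund` (samples x species count
#'   matrix) and `meta` (data frame of `transect`, `period`, `distance_m`
#'   aligned with the rows).
#' @export
community_matrix <- function(x, distances = design_distances()) {
  stopifnot(inherits(x, "pooled_catch") || is.data.frame(x))
  transects <- sort(unique(as.character(x$transect)))
  periods <- intersect(period_levels(), unique(as.character(x$period)))
  meta <- expand.grid(distance_m = as.integer(distances),
                      transect = transects, period = periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[c("transect", "period", "distance_m")]
  species <- sort(unique(as.character(x$species)))
  Y <- matrix(0, nrow(meta), length(species),
              dimnames = list(paste(meta$transect, meta$period,
                                    meta$distance_m, sep = "."), species))
  row_id <- match(paste(x$transect, x$period, x$distance_m, sep = "."),
                  rownames(Y))
  col_id <- match(as.character(x$species), species)
  for (k in seq_len(nrow(x))) {
    Y[row_id[k], col_id[k]] <- Y[row_id[k], col_id[k]] + x$count[k]
  }
  meta$period <- factor(meta$period, levels = periods)
  meta$transect <- factor(meta$transect)
  structure(list(abund = Y, meta = meta), class = "community_matrix")
}

#' Log-transform community counts
#'
#' Elementwise `log10(x + 1)`; zeros map to zero. Applied to the community
#' matrix before ordination.
#'
#' @param x a numeric matrix or a `community_matrix`.
#' @return object of the same shape with transformed entries.
#' @export
log_transform <- function(x) {
  if (inherits(x, "community_matrix")) {
    x$abund <- log_transform(x$abund)
    return(x)
  }
  x <- as.matrix(x)
  if (any(x < 0)) stop("log_transform requires non-negative entries")
  log10(x + 1)
}
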