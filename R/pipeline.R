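#' Run the full envelope-comparison surface
#'
#' For every habitat group x response x focal period, builds the relative
#' profiles, bootstraps the focal and pooled-period envelopes and tests for
#' pointwise non-overlap; with the full default grid this is 4 groups x 2
#' responses x 4 periods = 32 comparisons. Groups that are entirely absent
#' from some transect-period contribute undefined profiles, which are dropped
#' from fitting with a warning rather than imputed as zeros.
#'
#' @param catch a `catch_table` (already period-excluded as desired).
#' @param traits species-trait table (required for group analyses).
#' @param groups,responses,focal_periods the comparison grid; defaults cover
#'   the full surface.
#' @param config an [envelope_config()]; per-comparison seeds are derived from
#'   `seed` deterministically.
#' @param seed base integer seed.
#' @param out_dir optional directory: per-comparison curve tables and a
#'   summary CSV are written there.
#' @return list with `summary` (one row per comparison: group, response,
#'   focal_period, significant, n_nonoverlap, seed) and `comparisons` (named
#'   list of [compare_focal_to_pooled()] results).
#' @export
run_profiles <- function(catch, traits = NULL,
                         groups = c("all", habitat_groups()),
                         responses = c("abundance", "richness"),
                         focal_periods = NULL,
                         config = envelope_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(catch, "catch_table"))
  if (any(groups != "all") && is.null(traits)) {
    stop("a species-trait table is required for group-level analyses")
  }
  pooled <- pool_traps(catch, warn_missing = FALSE)
  if (is.null(focal_periods)) {
    focal_periods <- intersect(period_levels(),
                               unique(as.character(catch$period)))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  comparisons <- list()
  rows <- list()
  k <- 0L
  for (grp in groups) {
    for (resp in responses) {
      prof <- if (resp == "abundance") {
        relative_abundance(pooled, traits, grp)
      } else {
        relative_richness(pooled, traits, grp)
      }
      n_undef <- sum(is.na(prof$value)) / length(unique(prof$distance_m))
      if (n_undef > 0) {
        warning(grp, "/", resp, ": ", n_undef,
                " undefined transect-period profile(s) excluded")
      }
      for (fp in focal_periods) {
        k <- k + 1L
        cfg <- config
        cfg$seed <- (seed + 7919L * k) %% .Machine$integer.max
        cmp <- compare_focal_to_pooled(prof, fp, cfg)
        id <- paste(grp, resp, fp, sep = "_")
        comparisons[[id]] <- cmp
        rows[[k]] <- data.frame(group = grp, response = resp,
                                focal_period = fp,
                                significant = cmp$significant,
                                n_nonoverlap = sum(cmp$nonoverlap),
                                seed = cfg$seed,
                                stringsAsFactors = FALSE)
        if (!is.null(out_dir)) {
          utils::write.csv(as.data.frame(cmp),
                           file.path(out_dir, paste0("envelope_", id, ".csv")),
                           row.names = FALSE)
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "envelope_summary.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, comparisons = comparisons)
}

#' Run the three constrained ordinations
#'
#' Pools traps, applies the rare-species filter, log10(x+1)-transforms the
#' community matrix and runs: the spatial partial CCA (distance constraint),
#' the interaction CCA (distance x period constraint), and the db-RDA
#' (Bray-Curtis PCoA + RDA of the interaction), each with its restricted
#' permutation test.
#'
#' @param catch a `catch_table`.
#' @param min_total rare-species filter threshold (specimens over the whole
#'   dataset).
#' @param n_perm permutations per test.
#' @param seed base integer seed (each test gets a derived seed).
#' @param covariate_mode,distance_coding passed to [spatial_cca()].
#' @param out_dir optional directory for CSV exports (summary, species
#'   scores, permutation null distributions).
#' @return list with `summary` data frame (analysis, pseudo_f, p_value,
#'   net_variance_pct, raw_variance_pct), the three result objects
#'   (`spatial`, `interaction`, `dbrda`) and the filtered `community`.
#' @export
run_ordination <- function(catch, min_total = 4L, n_perm = 499L, seed = 1L,
                           covariate_mode = "caption",
                           distance_coding = "numeric", out_dir = NULL) {
  stopifnot(inherits(catch, "catch_table"))
  pooled <- pool_traps(catch, warn_missing = FALSE)
  pooled <- filter_rare_species(pooled, min_total)
  comm <- log_transform(community_matrix(pooled))

  spat <- spatial_cca(comm, covariate_mode = covariate_mode,
                      distance_coding = distance_coding,
                      n_perm = n_perm, seed = seed)
  inter <- interaction_cca(comm, n_perm = n_perm, seed = seed + 1L)
  dbr <- dbrda(comm, n_perm = n_perm, seed = seed + 2L)

  results <- list(spatial = spat, interaction = inter, dbrda = dbr)
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(analysis = nm, pseudo_f = r$pseudo_f, p_value = r$p_value,
               net_variance_pct = r$variance_explained_pct,
               raw_variance_pct = r$variance_raw_pct,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "ordination_summary.csv"),
                     row.names = FALSE)
    if (!is.null(spat$species_scores)) {
      utils::write.csv(as.data.frame(spat$species_scores),
                       file.path(out_dir, "spatial_cca_species_scores.csv"))
    }
    if (!is.null(inter$species_scores)) {
      utils::write.csv(as.data.frame(inter$species_scores),
                       file.path(out_dir, "interaction_cca_species_scores.csv"))
    }
    for (nm in names(results)) {
      utils::write.csv(data.frame(f_perm = results[[nm]]$f_perm),
                       file.path(out_dir, paste0(nm, "_null_f.csv")),
                       row.names = FALSE)
    }
  }
  c(list(summary = summary, community = comm), results)
}
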