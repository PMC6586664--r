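#' Configuration for bootstrap confidence envelopes
#'
#' @param n_boot number of bootstrap replicates (default 499, matching the
#'   permutation count used throughout the analysis).
#' @param grid_size number of evaluation points on the scaled gradient.
#' @param ci_level two-sided confidence level for the envelope.
#' @param seed optional integer seed; when set, the envelope is reproducible.
#' @param criterion,family,types,bound passed to [select_hof()].
#' @param fast use the reduced multistart grid for the bootstrap refits (the
#'   nested warm-start chain plus a few generic starts); the default, since
#'   each envelope refits hundreds of perturbed profiles.
#' @param gradient_range metre range mapped onto \eqn{[0, 1]}.
#' @param whole_transects resample whole transect profiles instead of
#'   per-distance values (non-default variant; see Details).
#' @param pooled_mode how the pooled-period envelope is built in
#'   [compare_focal_to_pooled()]: `"pool_period_curves"` (default) bootstraps
#'   each non-focal period separately and pools the fitted curve sets before
#'   taking the median and quantiles, so the pooled band reflects the same
#'   per-distance information as a single period plus the between-period
#'   spread; `"resample_pooled"` refits curves to resamples of the pooled
#'   data, drawing as many values per distance as the pooled set holds
#'   (e.g. 12).
#' @details The default resampling scheme draws, at each distance
#'   independently, as many values (with replacement) as were observed there
#'   across transects, conserving the per-distance sample sizes. The
#'   `whole_transects` variant resamples entire transect profiles instead.
#' @return an `envelope_config` list.
#' @export
envelope_config <- function(n_boot = 499L, grid_size = 101L, ci_level = 0.95,
                            seed = NULL, criterion = "aicc",
                            family = "binomial",
                            types = c("I", "II", "III", "IV", "V"),
                            bound = 50, gradient_range = c(-20, 20),
                            whole_transects = FALSE, fast = TRUE,
                            pooled_mode = c("pool_period_curves",
                                            "resample_pooled")) {
  stopifnot(n_boot >= 1, grid_size >= 2, ci_level > 0, ci_level < 1)
  pooled_mode <- match.arg(pooled_mode)
  structure(list(n_boot = as.integer(n_boot),
                 grid_size = as.integer(grid_size),
                 ci_level = ci_level, seed = seed, criterion = criterion,
                 family = family, types = types, bound = bound,
                 gradient_range = gradient_range,
                 whole_transects = whole_transects, fast = fast,
                 pooled_mode = pooled_mode),
            class = "envelope_config")
}

## defined (non-NA) profile rows only
defined_profiles <- function(profiles) {
  profiles[!is.na(profiles$value), , drop = FALSE]
}

#' Stratified bootstrap resampling of relative profiles
#'
#' Draws one bootstrap replicate of a set of relative profiles: at each
#' distance independently, values are sampled with replacement from the
#' across-transect (and, for pooled-period data, across-period) values
#' observed at that distance, keeping the number of observations per distance
#' constant. Values travel with their denominators so binomial refits remain
#' valid. Uses the current RNG state.
#'
#' @param profiles a `relative_profiles` data frame (undefined profiles are
#'   dropped first).
#' @param whole_transects if `TRUE`, resample whole (transect, period)
#'   profiles with replacement instead of per-distance values.
#' @return a data frame of the same shape with resampled rows.
#' @export
resample_profiles <- function(profiles, whole_transects = FALSE) {
  pr <- defined_profiles(profiles)
  if (!nrow(pr)) stop("no defined profile values to resample")
  if (whole_transects) {
    ids <- unique(paste(pr$transect, pr$period, sep = "\r"))
    pick <- sample(ids, length(ids), replace = TRUE)
    out <- do.call(rbind, lapply(seq_along(pick), function(i) {
      pr[paste(pr$transect, pr$period, sep = "\r") == pick[i], , drop = FALSE]
    }))
    rownames(out) <- NULL
    return(out)
  }
  idx <- unlist(lapply(split(seq_len(nrow(pr)), pr$distance_m), function(ii) {
    ii[sample.int(length(ii), length(ii), replace = TRUE)]
  }), use.names = FALSE)
  out <- pr[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap median curve and confidence envelope for HOF responses
#'
#' Refits a selected HOF curve to each of `n_boot` stratified bootstrap
#' replicates of the profiles and summarises the fitted curves pointwise on a
#' gradient grid: median and equal-tail confidence bounds (type-7 quantiles).
#' A tally of the model types selected across replicates is returned; failed
#' refits are dropped from the summaries and counted (an error is raised when
#' more than half fail).
#'
#' @param profiles a `relative_profiles` data frame (one group and response;
#'   one or more periods).
#' @param config an [envelope_config()].
#' @return a `hof_envelope`: list with `grid` (scaled), `grid_m` (metres),
#'   `median`, `lo`, `hi`, `type_tally`, `n_boot`, `n_fail`, `config`.
#' @export
bootstrap_envelope <- function(profiles, config = envelope_config()) {
  stopifnot(inherits(config, "envelope_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pr <- defined_profiles(profiles)
  if (length(unique(pr$distance_m)) < 2L) {
    stop("need defined values at >= 2 distances to fit response curves")
  }
  grid <- seq(0, 1, length.out = config$grid_size)
  curves <- matrix(NA_real_, config$n_boot, config$grid_size)
  tally <- stats::setNames(integer(5), c("I", "II", "III", "IV", "V"))
  n_fail <- 0L
  for (b in seq_len(config$n_boot)) {
    rs <- resample_profiles(pr, config$whole_transects)
    fit <- tryCatch(
      suppressWarnings(select_hof(
        scale_gradient(rs$distance_m, config$gradient_range),
        rs$value, trials = rs$denominator, types = config$types,
        criterion = config$criterion, family = config$family,
        bound = config$bound, gradient_range = config$gradient_range,
        fast = isTRUE(config$fast))),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_fail <- n_fail + 1L
      next
    }
    curves[b, ] <- predict(fit, grid)
    tally[fit$type] <- tally[fit$type] + 1L
  }
  if (n_fail > config$n_boot / 2) {
    stop("more than half of the bootstrap refits failed (", n_fail, "/",
         config$n_boot, ")")
  }
  envelope_from_curves(curves[stats::complete.cases(curves), , drop = FALSE],
                       grid, tally, config$n_boot, n_fail, config)
}

## pointwise summaries (type-7 quantiles) of a replicate-by-grid curve matrix
envelope_from_curves <- function(curves, grid, tally, n_boot, n_fail,
                                 config) {
  alpha <- (1 - config$ci_level) / 2
  qs <- apply(curves, 2, stats::quantile,
              probs = c(alpha, 0.5, 1 - alpha), type = 7, names = FALSE)
  structure(list(
    grid = grid,
    grid_m = config$gradient_range[1] + grid * diff(config$gradient_range),
    lo = qs[1, ], median = qs[2, ], hi = qs[3, ],
    curves = curves,
    type_tally = tally, n_boot = n_boot, n_fail = n_fail,
    config = config
  ), class = "hof_envelope")
}

## pooled-period envelope built by pooling the per-period bootstrap curve sets
pooled_curveset_envelope <- function(profiles, config) {
  pers <- unique(as.character(profiles$period))
  envs <- lapply(pers, function(p) {
    bootstrap_envelope(profiles[as.character(profiles$period) == p, ,
                                drop = FALSE], config)
  })
  curves <- do.call(rbind, lapply(envs, `[[`, "curves"))
  tally <- Reduce(`+`, lapply(envs, `[[`, "type_tally"))
  envelope_from_curves(curves, envs[[1]]$grid, tally,
                       sum(vapply(envs, `[[`, integer(1), "n_boot")),
                       sum(vapply(envs, `[[`, integer(1), "n_fail")),
                       config)
}

#' Compare a focal period's median curve against the pooled-period envelope
#'
#' The analysis' season-contrast: a bootstrap envelope is built for the focal
#' period and another for the pooled remaining periods. By default
#' (`pooled_mode = "pool_period_curves"`) each non-focal period is
#' bootstrapped separately and the fitted curve sets are pooled before the
#' median and quantiles are taken, so the pooled band carries the same
#' per-distance information as the focal curve plus the between-period
#' spread; `"resample_pooled"` instead refits curves to resamples of the
#' merged data (e.g. 12 values per distance for 3 periods x 4 transects).
#' The focal median curve is then tested pointwise for non-overlap with the
#' pooled envelope; the comparison is flagged significant when the focal
#' median leaves the pooled confidence band anywhere. Significance is
#' pointwise, with no multiplicity correction.
#'
#' @param profiles a `relative_profiles` data frame covering all periods for
#'   one group and response.
#' @param focal_period the period to contrast against the pooled others.
#' @param config an [envelope_config()]; its `seed` governs both envelopes.
#' @return an `envelope_comparison`: list with `focal` and `pooled`
#'   ([bootstrap_envelope()] results), `nonoverlap` (logical per grid point),
#'   `significant`, `focal_period`. `as.data.frame()` yields the tabular
#'   curve/band export.
#' @export
compare_focal_to_pooled <- function(profiles, focal_period,
                                    config = envelope_config()) {
  per <- as.character(profiles$period)
  if (!(focal_period %in% per)) {
    stop("focal period '", focal_period, "' not present in the profiles")
  }
  others <- setdiff(unique(per), focal_period)
  if (!length(others)) stop("no other periods to pool against")
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_inner <- config
  cfg_inner$seed <- NULL  # one RNG stream for both envelopes
  focal <- bootstrap_envelope(profiles[per == focal_period, , drop = FALSE],
                              cfg_inner)
  pooled <- if (identical(config$pooled_mode, "resample_pooled")) {
    bootstrap_envelope(profiles[per != focal_period, , drop = FALSE],
                       cfg_inner)
  } else {
    pooled_curveset_envelope(profiles[per != focal_period, , drop = FALSE],
                             cfg_inner)
  }
  mask <- focal$median < pooled$lo | focal$median > pooled$hi
  structure(list(focal = focal, pooled = pooled, nonoverlap = mask,
                 significant = any(mask), focal_period = focal_period,
                 group = profiles$group[1], response = profiles$response[1]),
            class = "envelope_comparison")
}

#' @export
as.data.frame.envelope_comparison <- function(x, ...) {
  data.frame(
    grid_m = x$focal$grid_m,
    focal_median = x$focal$median, focal_lo = x$focal$lo,
    focal_hi = x$focal$hi,
    pooled_median = x$pooled$median, pooled_lo = x$pooled$lo,
    pooled_hi = x$pooled$hi,
    nonoverlap = x$nonoverlap
  )
}

#' @export
print.envelope_comparison <- function(x, ...) {
  cat("Envelope comparison: ", as.character(x$group), " ",
      as.character(x$response), ", focal period ", x$focal_period, "\n",
      "  significant (pointwise non-overlap): ", x$significant,
      " (", sum(x$nonoverlap), "/", length(x$nonoverlap),
      " grid points)\n", sep = "")
  invisible(x)
}
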