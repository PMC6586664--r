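#' Restricted permutation schemes for the ordination tests
#'
#' Three schemes mirror the study design:
#' \describe{
#'   \item{`within_block`}{samples are shuffled only within blocks (the 16
#'     transect x period cells for the spatial test).}
#'   \item{`within_block_plus_period_labels`}{within each transect the period
#'     identities of whole cells are exchanged, and samples are additionally
#'     shuffled within cells (the interaction test).}
#'   \item{`transect_blocks`}{free shuffling within each transect (the db-RDA
#'     test).}
#' }
#'
#' @param mode one of the three scheme names.
#' @param blocks factor assigning each sample to a block (required for
#'   `within_block`).
#' @param transect,period factors per sample (required for
#'   `within_block_plus_period_labels`; `transect` also serves
#'   `transect_blocks`).
#' @param n_perm number of permutations (default 499; the attainable p-value
#'   floor is then 1/(n_perm+1) = 0.002).
#' @param seed optional integer seed.
#' @return a `permutation_scheme` list.
#' @export
permutation_scheme <- function(mode = c("within_block",
                                        "within_block_plus_period_labels",
                                        "transect_blocks"),
                               blocks = NULL, transect = NULL, period = NULL,
                               n_perm = 499L, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "within_block" && is.null(blocks)) {
    stop("within_block scheme needs 'blocks'")
  }
  if (mode == "within_block_plus_period_labels" &&
      (is.null(transect) || is.null(period))) {
    stop("within_block_plus_period_labels scheme needs 'transect' and 'period'")
  }
  if (mode == "transect_blocks") {
    if (is.null(transect)) stop("transect_blocks scheme needs 'transect'")
    blocks <- factor(transect)
  }
  structure(list(mode = mode,
                 blocks = if (!is.null(blocks)) factor(blocks),
                 transect = if (!is.null(transect)) factor(transect),
                 period = if (!is.null(period)) factor(period),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "permutation_scheme")
}

#' One permutation of sample indices under a restricted scheme
#'
#' @param scheme a [permutation_scheme()].
#' @param n number of samples (checked against the scheme's factors).
#' @return an integer permutation of `1:n`; uses the current RNG state.
#' @export
perm_indices <- function(scheme, n) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  idx <- seq_len(n)
  if (scheme$mode %in% c("within_block", "transect_blocks")) {
    blocks <- scheme$blocks
    if (length(blocks) != n) stop("scheme blocks do not match the samples")
    for (b in levels(blocks)) {
      ii <- which(blocks == b)
      idx[ii] <- ii[sample.int(length(ii))]
    }
    return(idx)
  }
  ## within_block_plus_period_labels: per transect, exchange whole period
  ## cells, then shuffle within cells
  tr <- scheme$transect
  pe <- scheme$period
  if (length(tr) != n || length(pe) != n) {
    stop("scheme transect/period do not match the samples")
  }
  for (t in levels(tr)) {
    pers <- levels(droplevels(pe[tr == t]))
    cells <- lapply(pers, function(p) which(tr == t & pe == p))
    sizes <- lengths(cells)
    if (length(unique(sizes)) != 1L) {
      stop("period cells within transect ", t,
           " differ in size; period labels cannot be exchanged")
    }
    relabel <- sample.int(length(pers))
    for (j in seq_along(pers)) {
      dest <- cells[[j]]
      src <- cells[[relabel[j]]]
      idx[dest] <- src[sample.int(length(src))]
    }
  }
  idx
}

#' Restricted permutation test of constrained inertia
#'
#' Reduced-model permutation: the covariates stay fixed, the rows of the raw
#' constraint matrix are permuted within blocks (row masses remain attached to
#' rows; the permuted constraints are re-centred and re-residualised each
#' time), and the pseudo-F statistic is recomputed.
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}; ties count as exceeding
#' (conservative), so the attainable p-values are \eqn{k/(n_{perm}+1)}.
#'
#' @inheritParams cca
#' @param scheme a [permutation_scheme()].
#' @return list with `p_value`, `f_obs`, `f_perm` (the permuted statistics),
#'   `n_perm`.
#' @export
permutation_test <- function(Y, constraints, covariates = NULL, scheme,
                             allow_aliased = FALSE) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  if (inherits(Y, "community_matrix")) Y <- Y$abund
  Y <- as.matrix(Y)
  constraints <- as.matrix(constraints)
  n_full <- nrow(Y)
  check_scheme_length(scheme, n_full)
  prep <- cca_prepare(Y, covariates)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  ## permutations act on the full design (blocks stay balanced even when
  ## zero-total samples are dropped from the response); cca_stat subsets the
  ## permuted constraints to the retained samples internally
  obs <- cca_stat(prep, constraints, check_rank = !allow_aliased)
  df_res <- prep$n - 1L - obs$q - prep$rank_z
  f_obs <- pseudo_f(obs$constrained, obs$residual, obs$q, df_res)
  f_perm <- numeric(scheme$n_perm)
  for (i in seq_len(scheme$n_perm)) {
    st <- cca_stat(prep,
                   constraints[perm_indices(scheme, n_full), , drop = FALSE])
    f_perm[i] <- pseudo_f(st$constrained, st$residual, st$q, df_res)
  }
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + scheme$n_perm)
  list(p_value = p, f_obs = f_obs, f_perm = f_perm, n_perm = scheme$n_perm)
}

check_scheme_length <- function(scheme, n) {
  for (f in c("blocks", "transect", "period")) {
    if (!is.null(scheme[[f]]) && length(scheme[[f]]) != n) {
      stop("permutation scheme '", f, "' does not match the ", n, " samples")
    }
  }
  invisible(TRUE)
}

#' Exact restricted permutation test by full enumeration
#'
#' Enumerates every within-block permutation (feasible only for tiny designs)
#' and returns the exact p-value; used to validate the Monte-Carlo test.
#'
#' @inheritParams permutation_test
#' @param blocks block factor.
#' @param max_perms guard on the enumeration size.
#' @return list with `p_value`, `f_obs`, `f_perm` (all permutations,
#'   including the identity).
#' @export
permutation_test_exact <- function(Y, constraints, covariates = NULL, blocks,
                                   max_perms = 50000L) {
  if (inherits(Y, "community_matrix")) Y <- Y$abund
  constraints <- as.matrix(constraints)
  prep <- cca_prepare(Y, covariates)
  stopifnot(all(prep$keep_rows))
  n <- prep$n
  blocks <- factor(blocks)
  stopifnot(length(blocks) == n)
  obs <- cca_stat(prep, constraints, check_rank = TRUE)
  df_res <- n - 1L - obs$q - prep$rank_z
  f_obs <- pseudo_f(obs$constrained, obs$residual, obs$q, df_res)

  block_perms <- lapply(levels(blocks), function(b) {
    all_perms(which(blocks == b))
  })
  total <- prod(vapply(block_perms, length, numeric(1)))
  if (total > max_perms) stop("enumeration too large: ", total)
  grid <- expand.grid(lapply(block_perms, seq_along))
  f_perm <- numeric(nrow(grid))
  base <- seq_len(n)
  for (g in seq_len(nrow(grid))) {
    idx <- base
    for (j in seq_along(block_perms)) {
      ii <- which(blocks == levels(blocks)[j])
      idx[ii] <- block_perms[[j]][[grid[g, j]]]
    }
    st <- cca_stat(prep, constraints[idx, , drop = FALSE])
    f_perm[g] <- pseudo_f(st$constrained, st$residual, st$q, df_res)
  }
  list(p_value = mean(f_perm >= f_obs - 1e-12), f_obs = f_obs, f_perm = f_perm)
}

## all permutations of a vector (tiny n only)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

## treatment-coded design helpers -------------------------------------------

factor_design <- function(f, prefix) {
  f <- factor(f)
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0(prefix, levels(f)[-1])
  mm
}

interaction_design <- function(distance, period) {
  d <- factor(distance)
  p <- factor(period)
  if (nlevels(p) < 2L) stop("interaction undefined with a single period")
  if (nlevels(d) < 2L) stop("interaction undefined with a single distance")
  mm <- stats::model.matrix(~ d * p)
  int <- mm[, grepl(":", colnames(mm)), drop = FALSE]
  main <- mm[, !grepl(":", colnames(mm)) & colnames(mm) != "(Intercept)",
             drop = FALSE]
  list(interaction = int, main = main)
}

#' Spatial partial CCA of the community on the boundary gradient
#'
#' CCA of the (log-transformed) community matrix with signed distance from the
#' boundary as the constraint. By default both transect identity and sampling
#' period are partialled out (`covariate_mode = "caption"`), matching the
#' convention under which the net spatial variance is reported; the
#' methods-literal alternative (`"methods"`) partials out transect identity
#' only. The permutation test shuffles samples within the transect x period
#' blocks.
#'
#' @param comm a `community_matrix` whose `abund` slot already holds the
#'   transformed abundances to ordinate.
#' @param covariate_mode `"caption"` (transect + period) or `"methods"`
#'   (transect only).
#' @param distance_coding `"numeric"` (signed metres, one constraint column)
#'   or `"factor"` (six contrast columns).
#' @param n_perm,seed permutation test settings.
#' @return a `cca_result` with `p_value`, `f_perm` and the scheme attached.
#' @export
spatial_cca <- function(comm, covariate_mode = c("caption", "methods"),
                        distance_coding = c("numeric", "factor"),
                        n_perm = 499L, seed = NULL) {
  covariate_mode <- match.arg(covariate_mode)
  distance_coding <- match.arg(distance_coding)
  stopifnot(inherits(comm, "community_matrix"))
  meta <- comm$meta
  X <- if (distance_coding == "numeric") {
    matrix(as.numeric(meta$distance_m), dimnames = list(NULL, "distance_m"))
  } else {
    factor_design(meta$distance_m, "dist")
  }
  Z <- factor_design(meta$transect, "transect")
  if (covariate_mode == "caption" && nlevels(factor(meta$period)) > 1L) {
    Z <- cbind(Z, factor_design(meta$period, "period"))
  }
  scheme <- permutation_scheme("within_block",
                               blocks = interaction(meta$transect,
                                                    meta$period, drop = TRUE),
                               n_perm = n_perm, seed = seed)
  finish_ordination(cca(comm$abund, X, Z, allow_aliased = TRUE),
                    permutation_test(comm$abund, X, Z, scheme,
                                     allow_aliased = TRUE), scheme)
}

#' Interaction CCA: does the spatial gradient response change over seasons?
#'
#' CCA with the distance x period interaction contrasts as constraints and the
#' main effects (distance, period) plus transect identity as covariates. The
#' permutation test exchanges period identities of whole cells within each
#' transect and shuffles samples within cells.
#'
#' @inheritParams spatial_cca
#' @return a `cca_result` with permutation results attached.
#' @export
interaction_cca <- function(comm, n_perm = 499L, seed = NULL) {
  stopifnot(inherits(comm, "community_matrix"))
  meta <- comm$meta
  des <- interaction_design(meta$distance_m, meta$period)
  Z <- cbind(factor_design(meta$transect, "transect"), des$main)
  scheme <- permutation_scheme("within_block_plus_period_labels",
                               transect = meta$transect, period = meta$period,
                               n_perm = n_perm, seed = seed)
  finish_ordination(cca(comm$abund, des$interaction, Z,
                        allow_aliased = TRUE),
                    permutation_test(comm$abund, des$interaction, Z, scheme,
                                     allow_aliased = TRUE),
                    scheme)
}

finish_ordination <- function(result, test, scheme) {
  result$p_value <- test$p_value
  result$f_perm <- test$f_perm
  result$n_perm <- test$n_perm
  result$scheme_mode <- scheme$mode
  stopifnot(abs(result$pseudo_f - test$f_obs) < 1e-8)
  result
}
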