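## ---- canonical correspondence analysis from first principles ----
##
## The community matrix Y is chi-square standardised:
##   P = Y / sum(Y); r = rowSums(P); c = colSums(P)
##   Qbar = (P - r c') / sqrt(r c')
## total inertia = sum(Qbar^2). Covariates and constraints are centred in the
## row-mass metric, scaled by sqrt(r), and Qbar is decomposed by successive
## least-squares projections; constrained axes come from the SVD of the fitted
## part. This reproduces the classical weighted-averaging eigenanalysis.

cca_prepare <- function(Y, covariates = NULL) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("community matrix must be non-negative")
  keep_rows <- rowSums(Y) > 0
  if (!all(keep_rows)) {
    warning(sum(!keep_rows), " sample(s) with zero total dropped")
  }
  keep_cols <- colSums(Y[keep_rows, , drop = FALSE]) > 0
  if (!all(keep_cols)) {
    warning(sum(!keep_cols), " empty species column(s) dropped")
  }
  Y <- Y[keep_rows, keep_cols, drop = FALSE]
  if (nrow(Y) < 2L || ncol(Y) < 2L) stop("need >= 2 samples and >= 2 species")
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Qbar <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  wt <- sqrt(r)

  ## weighted centring (weights r sum to 1), then sqrt(r) row scaling
  weight_design <- function(A) {
    A <- as.matrix(A)[keep_rows, , drop = FALSE]
    A <- sweep(A, 2, colSums(A * r), "-")
    A * wt
  }

  qrZ <- NULL
  cov_inertia <- 0
  Q1 <- Qbar
  rank_z <- 0L
  if (!is.null(covariates)) {
    Zc <- weight_design(covariates)
    qrZ <- qr(Zc)
    rank_z <- qrZ$rank
    fitZ <- qr.fitted(qrZ, Qbar)
    cov_inertia <- sum(fitZ^2)
    Q1 <- Qbar - fitZ
  }
  list(Y = Y, keep_rows = keep_rows, r = r, cm = cm, wt = wt,
       Qbar = Qbar, Q1 = Q1, total = sum(Qbar^2),
       cov_inertia = cov_inertia, qrZ = qrZ, rank_z = rank_z,
       weight_design = weight_design, n = nrow(Y))
}

## constrained/residual inertia for a (raw) constraint matrix X
cca_stat <- function(prep, X, check_rank = FALSE, svd_out = FALSE) {
  Xc <- prep$weight_design(X)
  if (!is.null(prep$qrZ)) Xc <- Xc - qr.fitted(prep$qrZ, Xc)
  qrX <- qr(Xc)
  if (check_rank && qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    stop("constraints are rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- qr.fitted(qrX, prep$Q1)
  constrained <- sum(fit^2)
  residual <- prep$total - prep$cov_inertia - constrained
  out <- list(constrained = constrained, residual = residual, q = qrX$rank)
  if (svd_out) out$svd <- svd(fit)
  out
}

#' Pseudo-F statistic for constrained ordination
#'
#' \eqn{F = (I_{constrained} / q) / (I_{residual} / df_{res})} with
#' \eqn{df_{res} = n - 1 - q - p_{cov}}; the significance of F is assessed by
#' restricted permutation, not by an F distribution.
#'
#' @param constrained,residual inertia (or sum-of-squares) components.
#' @param q rank of the constraints.
#' @param df_res residual degrees of freedom.
#' @return the pseudo-F value (0 when the constrained component is 0).
#' @export
pseudo_f <- function(constrained, residual, q, df_res) {
  stopifnot(q >= 1, df_res >= 1)
  if (constrained <= 0) return(0)
  (constrained / q) / (residual / df_res)
}

#' (Partial) canonical correspondence analysis
#'
#' Constrained ordination of a chi-square standardised community matrix on a
#' set of environmental constraints, optionally after removing covariate
#' effects (partial CCA). Implemented directly as the weighted least-squares
#' eigen-decomposition described in the field's standard texts; `vegan::cca`
#' serves as an independent cross-check in the package tests.
#'
#' @param Y samples x species matrix of non-negative (typically
#'   log10(x+1)-transformed) abundances, or a `community_matrix` (its `abund`
#'   slot is used).
#' @param constraints design matrix of constraining variables (no intercept
#'   needed; columns are centred internally in the row-mass metric).
#' @param covariates optional design matrix of covariates to partial out.
#' @param allow_aliased tolerate rank-deficient constraints (the projection
#'   uses the attained rank, as when dropped empty samples alias an
#'   interaction cell); by default rank deficiency is an error naming the
#'   collinear columns.
#' @return a `cca_result`: eigenvalues of the constrained axes, inertia
#'   decomposition (`total`, `covariate`, `constrained`, `residual`),
#'   `pseudo_f`, ranks, `species_scores` and `sample_scores` (linear
#'   combination scores), `variance_explained_pct` (net: constrained share of
#'   the covariate-adjusted total) and `variance_raw_pct`.
#' @export
cca <- function(Y, constraints, covariates = NULL, allow_aliased = FALSE) {
  if (inherits(Y, "community_matrix")) Y <- Y$abund
  constraints <- as.matrix(constraints)
  prep <- cca_prepare(Y, covariates)
  st <- cca_stat(prep, constraints, check_rank = !allow_aliased,
                 svd_out = TRUE)
  df_res <- prep$n - 1L - st$q - prep$rank_z
  if (df_res < 1L) stop("no residual degrees of freedom")
  eig <- st$svd$d^2
  keep <- eig > max(eig[1], 0) * 1e-12
  eig <- eig[keep]
  naxes <- length(eig)
  species_scores <- sample_scores <- NULL
  if (naxes) {
    V <- st$svd$v[, seq_len(naxes), drop = FALSE]
    U <- st$svd$u[, seq_len(naxes), drop = FALSE]
    species_scores <- (V / sqrt(prep$cm)) %*% diag(sqrt(eig), naxes)
    sample_scores <- (U / prep$wt) %*% diag(sqrt(eig), naxes)
    rownames(species_scores) <- colnames(prep$Y)
    rownames(sample_scores) <- rownames(prep$Y)
    colnames(species_scores) <- colnames(sample_scores) <-
      paste0("CCA", seq_len(naxes))
  }
  adj_total <- prep$total - prep$cov_inertia
  structure(list(
    method = "cca",
    eigenvalues = eig,
    inertia = c(total = prep$total, covariate = prep$cov_inertia,
                constrained = st$constrained, residual = st$residual),
    pseudo_f = pseudo_f(st$constrained, st$residual, st$q, df_res),
    q = st$q, rank_z = prep$rank_z, df_res = df_res, n = prep$n,
    variance_explained_pct = 100 * st$constrained / adj_total,
    variance_raw_pct = 100 * st$constrained / prep$total,
    axis1_net_pct = if (naxes) 100 * eig[1] / adj_total else 0,
    species_scores = species_scores, sample_scores = sample_scores,
    kept_rows = prep$keep_rows
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Constrained ordination (", x$method, ")\n", sep = "")
  cat("  inertia: total ", format(x$inertia["total"], digits = 5),
      ", covariate ", format(x$inertia["covariate"], digits = 5),
      ", constrained ", format(x$inertia["constrained"], digits = 5),
      ", residual ", format(x$inertia["residual"], digits = 5), "\n", sep = "")
  cat("  pseudo-F = ", format(x$pseudo_f, digits = 4),
      " (q = ", x$q, ", df_res = ", x$df_res, ")",
      if (!is.null(x$p_value)) paste0(", P = ", format(x$p_value, digits = 3)),
      "\n  net variance explained = ",
      format(x$variance_explained_pct, digits = 3), "%\n", sep = "")
  invisible(x)
}
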