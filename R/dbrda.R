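#' Bray-Curtis dissimilarity
#'
#' \eqn{d_{ij} = \sum_k |y_{ik} - y_{jk}| / \sum_k (y_{ik} + y_{jk})}, bounded
#' in \eqn{[0, 1]} for non-negative data; two empty samples get distance 0.
#'
#' @param Y samples x species matrix of non-negative abundances (or a
#'   `community_matrix`).
#' @return a `dist` object.
#' @export
bray_curtis <- function(Y) {
  if (inherits(Y, "community_matrix")) Y <- Y$abund
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Bray-Curtis requires non-negative entries")
  num <- as.matrix(stats::dist(Y, method = "manhattan"))
  rs <- rowSums(Y)
  den <- outer(rs, rs, "+")
  D <- ifelse(den > 0, num / den, 0)
  diag(D) <- 0
  stats::as.dist(D)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigen-decomposition of the double-centred matrix \eqn{-\tfrac12 D^2};
#' axes with positive eigenvalues are retained and scaled by the square root
#' of their eigenvalue, so Euclidean distances among scores reproduce any
#' Euclidean-embeddable input exactly. Negative eigenvalues (possible for
#' semi-metric dissimilarities such as Bray-Curtis) are reported but their
#' axes dropped.
#'
#' @param D a `dist` object or a symmetric matrix with zero diagonal.
#' @param tol relative tolerance deciding which eigenvalues count as positive.
#' @return a `pcoa_result`: `scores` (samples x retained axes),
#'   `eigenvalues` (all, descending), `positive` (logical), `n_retained`.
#' @export
pcoa <- function(D, tol = 1e-8) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-10)) {
      stop("distance matrix must be symmetric")
    }
    if (any(abs(diag(D)) > 1e-10)) stop("distance matrix must have zero diagonal")
    D <- stats::as.dist(D)
  }
  A <- -0.5 * as.matrix(D)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  thresh <- tol * max(abs(e$values))
  pos <- e$values > thresh
  scores <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(scores) <- attr(D, "Labels")
  colnames(scores) <- paste0("PCoA", seq_len(ncol(scores)))
  structure(list(scores = scores, eigenvalues = e$values, positive = pos,
                 n_retained = sum(pos)),
            class = "pcoa_result")
}

## unweighted RDA decomposition: SS of response projected on residualised
## constraints after removing covariates; mirrors cca_stat in the identity
## metric
rda_stat <- function(S, X, Z = NULL, check_rank = FALSE) {
  S <- scale(as.matrix(S), center = TRUE, scale = FALSE)
  total <- sum(S^2)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  cov_ss <- 0
  rank_z <- 0L
  if (!is.null(Z)) {
    Zc <- scale(as.matrix(Z), center = TRUE, scale = FALSE)
    qrZ <- qr(Zc)
    rank_z <- qrZ$rank
    cov_ss <- sum(qr.fitted(qrZ, S)^2)
    S <- S - qr.fitted(qrZ, S)
    Xc <- Xc - qr.fitted(qrZ, Xc)
  }
  qrX <- qr(Xc)
  if (check_rank && qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    stop("constraints are rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- qr.fitted(qrX, S)
  constrained <- sum(fit^2)
  list(total = total, covariate = cov_ss, constrained = constrained,
       residual = total - cov_ss - constrained, q = qrX$rank,
       rank_z = rank_z, fit = fit)
}

#' Distance-based redundancy analysis of the distance x period interaction
#'
#' Classical db-RDA: principal coordinates of the Bray-Curtis dissimilarities
#' among pooled samples are used as response variables in a redundancy
#' analysis with the distance x period interaction as the constraint and the
#' main effects (distance and period, factor-coded) as covariates. The
#' permutation test uses transects as blocks, permuting samples freely within
#' each transect.
#'
#' @param comm a `community_matrix` holding the (transformed) abundances.
#' @param n_perm,seed permutation test settings.
#' @return an ordination result list (class `cca_result` layout with
#'   `method = "dbrda"`): inertia decomposition of the retained PCoA space,
#'   pseudo-F, permutation p, eigenvalues of the constrained axes, sample
#'   scores, plus the underlying `pcoa_result`.
#' @export
dbrda <- function(comm, n_perm = 499L, seed = NULL) {
  stopifnot(inherits(comm, "community_matrix"))
  meta <- comm$meta
  des <- interaction_design(meta$distance_m, meta$period)
  Z <- des$main
  pc <- pcoa(bray_curtis(comm$abund))
  S <- pc$scores
  obs <- rda_stat(S, des$interaction, Z, check_rank = TRUE)
  df_res <- nrow(S) - 1L - obs$q - obs$rank_z
  if (df_res < 1L) stop("no residual degrees of freedom")
  f_obs <- pseudo_f(obs$constrained, obs$residual, obs$q, df_res)

  scheme <- permutation_scheme("transect_blocks", transect = meta$transect,
                               n_perm = n_perm, seed = seed)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- perm_indices(scheme, nrow(S))
    st <- rda_stat(S, des$interaction[idx, , drop = FALSE], Z)
    f_perm[i] <- pseudo_f(st$constrained, st$residual, st$q, df_res)
  }
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)

  sv <- svd(obs$fit)
  eig <- sv$d^2
  keep <- eig > max(eig[1], 0) * 1e-12
  eig <- eig[keep]
  sample_scores <- sv$u[, seq_along(eig), drop = FALSE] %*%
    diag(sqrt(eig), length(eig))
  rownames(sample_scores) <- rownames(comm$abund)
  if (length(eig)) colnames(sample_scores) <- paste0("dbRDA", seq_along(eig))
  adj_total <- obs$total - obs$covariate
  structure(list(
    method = "dbrda",
    eigenvalues = eig,
    inertia = c(total = obs$total, covariate = obs$covariate,
                constrained = obs$constrained, residual = obs$residual),
    pseudo_f = f_obs, p_value = p, f_perm = f_perm, n_perm = n_perm,
    q = obs$q, rank_z = obs$rank_z, df_res = df_res, n = nrow(S),
    variance_explained_pct = 100 * obs$constrained / adj_total,
    variance_raw_pct = 100 * obs$constrained / obs$total,
    sample_scores = sample_scores, pcoa = pc,
    scheme_mode = scheme$mode
  ), class = "cca_result")
}
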