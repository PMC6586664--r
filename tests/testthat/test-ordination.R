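test_that("CCA matches the brute-force oracle and vegan on small matrices", {
  skip_if_not_installed("vegan")
  suppressMessages(library(vegan))
  set.seed(1)
  for (i in 1:5) {
    Y <- matrix(rpois(8 * 6, 4) + 1, 8, 6,
                dimnames = list(NULL, paste0("sp", 1:6)))
    X <- cbind(x1 = rnorm(8), x2 = rnorm(8))
    Z <- cbind(z1 = rnorm(8))
    m <- cca(Y, X, Z)
    o <- oracle_cca(Y, X, Z)
    expect_equal(unname(m$inertia["total"]), o$total, tolerance = 1e-8)
    expect_equal(unname(m$inertia["covariate"]), o$covariate,
                 tolerance = 1e-8)
    expect_equal(unname(m$inertia["constrained"]), o$constrained,
                 tolerance = 1e-8)
    expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-8)
    v <- vegan::cca(Y ~ X + Condition(Z))
    expect_equal(unname(m$eigenvalues), unname(v$CCA$eig), tolerance = 1e-8)
    expect_equal(unname(m$inertia["covariate"]), v$pCCA$tot.chi,
                 tolerance = 1e-8)
  }
})

test_that("a 4x3 toy matrix with one binary constraint matches the oracle", {
  Y <- matrix(c(5, 1, 0,
                4, 2, 1,
                1, 3, 4,
                0, 2, 6), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  X <- matrix(c(1, 1, 0, 0), ncol = 1)
  m <- cca(Y, X)
  o <- oracle_cca(Y, X)
  expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-10)
  expect_equal(unname(m$inertia["constrained"]), o$constrained,
               tolerance = 1e-10)
})

test_that("inertia decomposition conserves the total and eigenvalues stay in [0, 1]", {
  set.seed(2)
  for (i in 1:10) {
    Y <- matrix(rpois(10 * 7, 3), 10, 7)
    Y[rowSums(Y) == 0, 1] <- 1
    X <- cbind(rnorm(10), rnorm(10))
    Z <- cbind(rnorm(10))
    m <- cca(Y, X, Z)
    expect_lt(abs(sum(m$inertia[c("covariate", "constrained", "residual")]) -
                  m$inertia[["total"]]), 1e-8)
    expect_true(all(m$eigenvalues >= 0 & m$eigenvalues <= 1))
  }
})

test_that("CCA is invariant to scaling and kills orthogonal constraints", {
  set.seed(3)
  Y <- matrix(rpois(8 * 5, 5) + 1, 8, 5)
  X <- cbind(rnorm(8))
  expect_equal(cca(Y, X)$eigenvalues, cca(7 * Y, X)$eigenvalues,
               tolerance = 1e-10)
  # constraint orthogonal (in the row-weighted metric) to species variation:
  # identical rows make the species matrix constant, so nothing is explainable
  Yc <- matrix(rep(c(3, 1, 2, 5, 4), each = 8), 8, 5)
  m <- cca(Yc, X)
  expect_lt(m$inertia[["constrained"]], 1e-20)
  expect_equal(m$pseudo_f, 0)
})

test_that("rank-deficient constraints raise an error naming the columns", {
  set.seed(4)
  Y <- matrix(rpois(8 * 5, 5) + 1, 8, 5)
  X <- cbind(one = rnorm(8))
  X <- cbind(X, dup = 2 * X[, 1])
  expect_error(cca(Y, X), "dup")
  expect_silent(m <- cca(Y, X, allow_aliased = TRUE))
  expect_equal(m$q, 1L)
})

test_that("pseudo-F follows its definition", {
  expect_equal(pseudo_f(0, 3, 2, 10), 0)
  expect_equal(pseudo_f(2, 5, 2, 10), (2 / 2) / (5 / 10))
  # equal per-df explained and residual inertia gives F = 1
  expect_equal(pseudo_f(3, 15, 2, 10), 1)
  expect_error(pseudo_f(1, 1, 0, 10))
})

test_that("restricted permutations stay within blocks", {
  blocks <- factor(rep(1:4, each = 7))
  sch <- permutation_scheme("within_block", blocks = blocks)
  set.seed(5)
  for (i in 1:20) {
    idx <- perm_indices(sch, 28)
    expect_equal(sort(idx), 1:28)
    expect_equal(blocks[idx], blocks)
  }
})

test_that("period-label exchange permutes whole cells within transects", {
  meta <- expand.grid(distance_m = design_distances(),
                      period = analysis_periods(),
                      transect = paste0("T", 1:2),
                      KEEP.OUT.ATTRS = FALSE)
  sch <- permutation_scheme("within_block_plus_period_labels",
                            transect = meta$transect, period = meta$period)
  set.seed(6)
  idx <- perm_indices(sch, nrow(meta))
  expect_equal(sort(idx), seq_len(nrow(meta)))
  # samples never change transect
  expect_equal(as.character(meta$transect[idx]),
               as.character(meta$transect))
  # each destination cell is filled from exactly one source period cell
  for (t in levels(meta$transect)) {
    for (p in analysis_periods()) {
      src <- unique(meta$period[idx][meta$transect == t & meta$period == p])
      expect_equal(length(src), 1L)
    }
  }
})

test_that("Monte-Carlo permutation p matches full enumeration on a tiny design", {
  skip_if_not_installed("vegan")
  set.seed(7)
  Y <- matrix(rpois(6 * 4, 4) + 1, 6, 4)
  X <- cbind(rnorm(6))
  blocks <- factor(rep(1:2, each = 3))
  ex <- permutation_test_exact(Y, X, blocks = blocks)
  expect_equal(length(ex$f_perm), 36L)
  # independent route: vegan::cca refit for every enumerated permutation
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  f_ora <- c()
  for (p1 in perms3) for (p2 in perms3) {
    idx <- c(p1, p2 + 3L)
    Xp <- X[idx, , drop = FALSE]
    v <- vegan::cca(Y ~ Xp)
    q <- 1; dfr <- 6 - 1 - 1
    f_ora <- c(f_ora, (v$CCA$tot.chi / q) / ((v$tot.chi - v$CCA$tot.chi) / dfr))
  }
  expect_equal(sort(ex$f_perm), sort(f_ora), tolerance = 1e-10)
  expect_equal(ex$p_value, mean(f_ora >= ex$f_obs - 1e-12))
})

test_that("permutation p honours the attainable set and the block structure", {
  set.seed(8)
  meta <- expand.grid(distance_m = design_distances(),
                      transect = paste0("T", 1:4))
  # strong distance effect: p hits the floor 1/(n_perm + 1)
  lam <- outer(scale_gradient(meta$distance_m) + 0.1, c(20, 10, 5, 2))
  Y <- matrix(rpois(length(lam), lam), nrow(meta))
  Y <- cbind(Y, matrix(rpois(28 * 3, 8 * (1 - scale_gradient(meta$distance_m))), 28))
  X <- cbind(dist = as.numeric(meta$distance_m))
  sch <- permutation_scheme("within_block", blocks = meta$transect,
                            n_perm = 499, seed = 1)
  res <- permutation_test(Y, X, scheme = sch)
  expect_equal(res$p_value, 1 / 500)
  expect_equal(res$n_perm, 499L)
  # constraint constant within every block: permutations change nothing, p = 1
  Xb <- cbind(as.numeric(meta$transect == "T1" | meta$transect == "T3"))
  res2 <- permutation_test(Y, Xb, scheme = sch)
  expect_true(all(abs(res2$f_perm - res2$f_obs) < 1e-10))
  expect_equal(res2$p_value, 1)
  # reproducible under the scheme seed
  res3 <- permutation_test(Y, X, scheme = sch)
  expect_identical(res$f_perm, res3$f_perm)
})

test_that("Bray-Curtis distances match hand computation and vegan", {
  skip_if_not_installed("vegan")
  Y <- matrix(c(2, 0, 4,
                2, 0, 4,
                0, 3, 0), 3, 3, byrow = TRUE)
  D <- as.matrix(bray_curtis(Y))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)  # disjoint samples
  expect_equal(D[2, 3], (2 + 3 + 4) / (2 + 3 + 4))
  set.seed(9)
  Y2 <- matrix(runif(8 * 5, 0, 3), 8, 5)
  expect_equal(as.matrix(bray_curtis(Y2)),
               as.matrix(vegan::vegdist(Y2, "bray")), tolerance = 1e-12)
  expect_error(bray_curtis(matrix(-1)), "non-negative")
})

test_that("PCoA reconstructs Euclidean configurations and reports negatives", {
  pts <- cbind(c(0, 1, 3, 7, 2), c(1, 0, 2, 1, 5))
  D <- dist(pts)
  pc <- pcoa(D)
  expect_equal(as.matrix(dist(pc$scores)), as.matrix(D), tolerance = 1e-10)
  cm <- cmdscale(D, k = 2, eig = TRUE)
  expect_equal(sort(pc$eigenvalues[pc$positive], decreasing = TRUE)[1:2],
               cm$eig[1:2], tolerance = 1e-10)
  # Bray-Curtis is semi-metric: negative eigenvalues appear but are dropped
  set.seed(10)
  Yb <- matrix(rpois(12 * 6, 3), 12, 6)
  Yb[rowSums(Yb) == 0, 1] <- 1
  pb <- pcoa(bray_curtis(Yb))
  expect_true(any(pb$eigenvalues < 0))
  expect_equal(ncol(pb$scores), sum(pb$positive))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the ordination wrappers reproduce the design's three analyses", {
  sc <- tiny_scenario()
  g <- generate_catch_table(sc, seed = 21)
  ord <- suppressWarnings(run_ordination(g$catch, n_perm = 99, seed = 3))
  expect_setequal(ord$summary$analysis, c("spatial", "interaction", "dbrda"))
  expect_true(all(ord$summary$p_value >= 1 / 100))
  expect_true(all(ord$summary$p_value <= 1))
  expect_equal(length(ord$spatial$f_perm), 99L)
  # a strong monotone gradient in the generator is detected spatially
  expect_equal(ord$spatial$p_value, 1 / 100)
  # inertia decompositions conserve totals in all three
  for (nm in c("spatial", "interaction", "dbrda")) {
    r <- ord[[nm]]
    expect_lt(abs(sum(r$inertia[c("covariate", "constrained", "residual")]) -
                  r$inertia[["total"]]), 1e-8)
  }
  # net variance uses the covariate-adjusted total
  r <- ord$spatial
  expect_equal(r$variance_explained_pct,
               100 * r$inertia[["constrained"]] /
                 (r$inertia[["total"]] - r$inertia[["covariate"]]))
})

test_that("db-RDA matches an independent lm-based RDA oracle", {
  set.seed(11)
  sc <- tiny_scenario()
  g <- generate_catch_table(sc, seed = 22)
  pooled <- pool_traps(g$catch, warn_missing = FALSE)
  comm <- log_transform(community_matrix(filter_rare_species(pooled, 4)))
  dbr <- dbrda(comm, n_perm = 49, seed = 12)
  # oracle: PCoA scores via cmdscale, RDA sums of squares via lm()
  D <- bray_curtis(comm$abund)
  n <- nrow(comm$meta)
  cm <- suppressWarnings(cmdscale(D, k = n - 1, eig = TRUE))
  S <- cm$points[, cm$eig[seq_len(ncol(cm$points))] > 1e-8 * max(abs(cm$eig)),
                 drop = FALSE]
  d <- factor(comm$meta$distance_m); p <- factor(comm$meta$period)
  fit_full <- lm(S ~ d * p)
  fit_red <- lm(S ~ d + p)
  ss <- function(m) sum(fitted(m)^2) - sum(colMeans(S)^2) * nrow(S)
  constrained <- ss(fit_full) - ss(fit_red)
  residual <- sum(resid(fit_full)^2)
  q <- (nlevels(d) - 1) * (nlevels(p) - 1)
  dfr <- n - 1 - q - (nlevels(d) - 1 + nlevels(p) - 1)
  f_ora <- (constrained / q) / (residual / dfr)
  expect_equal(dbr$pseudo_f, f_ora, tolerance = 1e-8)
  expect_equal(dbr$q, q)
})

test_that("interaction analyses refuse degenerate single-period data", {
  g <- generate_catch_table(tiny_scenario(), seed = 23)
  one <- g$catch[g$catch$period == "summer", ]
  class(one) <- c("catch_table", "data.frame")
  comm <- log_transform(community_matrix(pool_traps(one,
                                                    warn_missing = FALSE)))
  expect_error(interaction_cca(comm), "single period")
  expect_error(dbrda(comm), "single period")
})
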