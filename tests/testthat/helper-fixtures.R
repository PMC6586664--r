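# shared fixtures, all built in code

# minimal trait table covering the toy species
toy_traits <- function() {
  as_species_traits(data.frame(
    species = c("sp open A", "sp open B", "sp forest A", "sp gen A"),
    group = c("open_habitat", "open_habitat", "forest", "generalist")
  ))
}

# one transect, one period, all 7 distances x 4 traps, deterministic counts
toy_catch <- function(counts = NULL) {
  grid <- expand.grid(trap = 1:4, distance_m = design_distances(),
                      species = c("sp open A", "sp forest A"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$transect <- "T1"
  grid$period <- "summer"
  grid$count <- if (is.null(counts)) seq_len(nrow(grid)) %% 5 else counts
  as_catch_table(grid)
}

# tiny fast scenario for pipeline plumbing tests
tiny_scenario <- function() {
  curves <- list(
    open_habitat = list(
      early_spring = hof_params("IV", a = -10, b = 20, c = 10),
      late_spring = hof_params("II", a = 3, b = -8),
      summer = hof_params("II", a = 1.5, b = -4),
      autumn = hof_params("II", a = 3, b = -8)
    ),
    forest = list(
      early_spring = hof_params("II", a = -2, b = 4),
      late_spring = hof_params("II", a = -2, b = 4),
      summer = hof_params("II", a = -3, b = 6),
      autumn = hof_params("II", a = -3, b = 6)
    ),
    generalist = list(
      early_spring = hof_params("IV", a = -6, b = 12, c = 6),
      late_spring = hof_params("IV", a = -6, b = 12, c = 6),
      summer = hof_params("IV", a = -6, b = 12, c = 6),
      autumn = hof_params("IV", a = -6, b = 12, c = 6)
    )
  )
  pool <- data.frame(
    species = c("o1", "o2", "f1", "g1"),
    group = c("open_habitat", "open_habitat", "forest", "generalist"),
    weight = c(5, 3, 2, 1), stringsAsFactors = FALSE
  )
  scenario_config(pool, curves,
                  c(summer = 300, autumn = 120, early_spring = 150,
                    late_spring = 180))
}

# scaled gradient positions of the design
x_design <- function() scale_gradient(design_distances())

# independent brute-force chi-square standardisation + projection CCA used as
# an oracle for small matrices (no shared code with the implementation)
oracle_cca <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  center_w <- function(A) {
    A <- as.matrix(A)
    sweep(A, 2, apply(A, 2, function(col) sum(col * r)))
  }
  proj <- function(B, M) B %*% solve(crossprod(B), crossprod(B, M))
  Xw <- diag(sqrt(r)) %*% center_w(X)
  total <- sum(Q^2)
  cov_in <- 0
  if (!is.null(Z)) {
    Zw <- diag(sqrt(r)) %*% center_w(Z)
    cov_in <- sum(proj(Zw, Q)^2)
    Q <- Q - proj(Zw, Q)
    Xw <- Xw - proj(Zw, Xw)
  }
  fit <- proj(Xw, Q)
  eig <- sort(eigen(crossprod(fit), symmetric = TRUE)$values,
              decreasing = TRUE)
  list(total = total, covariate = cov_in, constrained = sum(fit^2),
       residual = total - cov_in - sum(fit^2),
       eigenvalues = eig[eig > 1e-12])
}
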