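#' Huisman-Olff-Fresco (HOF) response-curve family
#'
#' A nested hierarchy of bounded logistic response shapes along a gradient
#' scaled to \eqn{[0, 1]}. With \eqn{z(x) = 1/(1 + e^{a + bx})} and
#' \eqn{w(x) = 1/(1 + e^{c - dx})}:
#' \describe{
#'   \item{I}{flat: \eqn{M / (1 + e^a)}}
#'   \item{II}{monotone sigmoid: \eqn{M z(x)}}
#'   \item{III}{plateau: \eqn{M z(x) / (1 + e^c)}}
#'   \item{IV}{symmetric unimodal: \eqn{M z(x) w(x)} with \eqn{d = b}}
#'   \item{V}{skewed unimodal: \eqn{M z(x) w(x)}}
#' }
#' Type IV has its mode at \eqn{x^* = (c - a) / (2b)} and is symmetric about
#' it; \eqn{c = a + b} gives symmetry about \eqn{x = 0.5}.
#'
#' @param type one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param a,b,c,d shape parameters (only those used by `type` are required;
#'   type IV stores `d = b`).
#' @param M response ceiling (1 for relative data).
#' @return `hof_params`: a parameter list. `hof_curve`: the curve values.
#' @export
hof_params <- function(type, a, b = NA_real_, c = NA_real_, d = NA_real_,
                       M = 1) {
  type <- match.arg(type, c("I", "II", "III", "IV", "V"))
  need <- switch(type, I = "a", II = c("a", "b"), III = c("a", "b", "c"),
                 IV = c("a", "b", "c"), V = c("a", "b", "c", "d"))
  vals <- list(a = a, b = b, c = c, d = d)
  if (any(vapply(vals[need], function(v) !is.finite(v), logical(1)))) {
    stop("type ", type, " requires finite parameter(s) ",
         paste(need, collapse = ", "))
  }
  if (type == "IV") d <- b
  structure(list(type = type, a = a, b = b, c = c, d = d, M = M),
            class = "hof_params")
}

#' @rdname hof_params
#' @param params a `hof_params` object.
#' @param x gradient positions, normally in \eqn{[0, 1]} (values outside are
#'   permitted, e.g. for plotting extrapolated curves).
#' @export
hof_curve <- function(params, x) {
  stopifnot(inherits(params, "hof_params"))
  p <- params
  z <- stats::plogis(-(p$a + p$b * x))
  switch(p$type,
    I = rep(p$M * stats::plogis(-p$a), length(x)),
    II = p$M * z,
    III = p$M * z * stats::plogis(-p$c),
    IV = p$M * z * stats::plogis(p$b * x - p$c),
    V = p$M * z * stats::plogis(p$d * x - p$c)
  )
}

hof_npar <- function(type) {
  c(I = 1L, II = 2L, III = 3L, IV = 3L, V = 4L)[[type]]
}

## parameter vector <-> hof_params for the optimiser
hof_par_to_params <- function(type, par, M = 1) {
  switch(type,
    I = hof_params("I", par[1], M = M),
    II = hof_params("II", par[1], par[2], M = M),
    III = hof_params("III", par[1], par[2], par[3], M = M),
    IV = hof_params("IV", par[1], par[2], par[3], M = M),
    V = hof_params("V", par[1], par[2], par[3], par[4], M = M)
  )
}

## binomial deviance of proportions y with trial counts n about mean mu;
## 0*log(0) terms are zero, mu clamped away from {0, 1}
binomial_deviance <- function(y, mu, n) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  t1 <- y * log(y / mu)
  t1[y <= 0] <- 0
  t2 <- (1 - y) * log((1 - y) / (1 - mu))
  t2[y >= 1] <- 0
  2 * sum(n * (t1 + t2))
}

## inverse logit without dispatch overhead; exp overflow saturates cleanly
ilogit <- function(u) 1 / (1 + exp(-u))

## fast curve evaluation from a bare parameter vector (optimiser hot path)
hof_mu <- function(type, par, x, M) {
  switch(type,
    I = rep.int(M / (1 + exp(par[1])), length(x)),
    II = M * ilogit(-(par[1] + par[2] * x)),
    III = M * ilogit(-(par[1] + par[2] * x)) / (1 + exp(par[3])),
    IV = M * ilogit(-(par[1] + par[2] * x)) * ilogit(par[2] * x - par[3]),
    V = M * ilogit(-(par[1] + par[2] * x)) * ilogit(par[4] * x - par[3])
  )
}

## n x k matrix of partial derivatives dmu/dpar
hof_mu_grad <- function(type, par, x, M) {
  z <- ilogit(-(par[1] + if (type == "I") 0 else par[2] * x))
  switch(type,
    I = cbind(-M * z * (1 - z)),
    II = cbind(-M * z * (1 - z), -M * x * z * (1 - z)),
    III = {
      q <- ilogit(-par[3])
      cbind(-M * q * z * (1 - z), -M * q * x * z * (1 - z),
            -M * z * q * (1 - q))
    },
    IV = {
      w <- ilogit(par[2] * x - par[3])
      cbind(-M * w * z * (1 - z), M * x * z * w * (z - w),
            -M * z * w * (1 - w))
    },
    V = {
      w <- ilogit(par[4] * x - par[3])
      cbind(-M * w * z * (1 - z), -M * x * w * z * (1 - z),
            -M * z * w * (1 - w), M * x * z * w * (1 - w))
    }
  )
}

hof_objective <- function(type, x, y, n, family, M) {
  force(type)
  if (family == "binomial") {
    ## deviance = saturated part (constant) - 2 * log-likelihood kernel
    sat <- {
      t1 <- y * log(y)
      t1[y <= 0] <- 0
      t2 <- (1 - y) * log(1 - y)
      t2[y >= 1] <- 0
      2 * sum(n * (t1 + t2))
    }
    ny <- n * y
    n1y <- n * (1 - y)
    function(par) {
      mu <- hof_mu(type, par, x, M)
      mu[mu < 1e-12] <- 1e-12
      mu[mu > 1 - 1e-12] <- 1 - 1e-12
      sat - 2 * sum(ny * log(mu) + n1y * log1p(-mu))
    }
  } else {
    function(par) sum((y - hof_mu(type, par, x, M))^2)
  }
}

hof_gradient <- function(type, x, y, n, family, M) {
  force(type)
  function(par) {
    mu <- hof_mu(type, par, x, M)
    dmu <- hof_mu_grad(type, par, x, M)
    ddev <- if (family == "binomial") {
      mu[mu < 1e-12] <- 1e-12
      mu[mu > 1 - 1e-12] <- 1 - 1e-12
      2 * n * (mu - y) / (mu * (1 - mu))
    } else {
      -2 * (y - mu)
    }
    as.numeric(crossprod(dmu, ddev))
  }
}

## deterministic start grid; `warm` is a list of parameter vectors (e.g. the
## optimum of a nested sub-model embedded at an exact boundary), tried as-is
hof_starts <- function(type, x, y, n, bound, warm = list(), fast = FALSE) {
  mbar <- min(max(sum(n * y) / sum(n), 1e-6), 1 - 1e-6)
  a0 <- -stats::qlogis(mbar)
  xms <- if (fast) 0.5 else c(0.25, 0.5, 0.75)
  st <- switch(type,
    I = list(a0),
    II = lapply(if (fast) c(-6, 6) else c(-8, -3, 3, 8),
                function(b) c(a0 + b / 2, b)),
    III = if (fast) list() else list(c(a0 + 4, 8, 0), c(a0 - 4, -8, 0)),
    IV = {
      out <- list()
      for (b in c(10, -10)) {
        for (xm in xms) {
          a <- -2 - b * xm
          out[[length(out) + 1L]] <- c(a, b, a + 2 * b * xm)
        }
      }
      out
    },
    V = if (fast) list() else list(c(-4, 8, 4, 2), c(4, -8, -4, -2))
  )
  st <- c(warm, st)
  lapply(st, function(p) pmin(pmax(p, -bound), bound))
}

#' Fit one HOF model type to gradient data
#'
#' Fits the chosen response shape by minimising the binomial deviance (the
#' default for relative data with known integer denominators) or the residual
#' sum of squares (gaussian), using bounded quasi-Newton optimisation from a
#' deterministic grid of starting values. Starting values include exact
#' embeddings of nested sub-model optima, so deviance is monotone over the
#' nesting hierarchy (V <= IV <= II <= I, and V <= III <= II).
#'
#' @param x gradient positions scaled to \eqn{[0, 1]} (see
#'   [scale_gradient()]).
#' @param y observed relative values in \eqn{[0, 1]}.
#' @param trials integer denominators (binomial trials) per observation;
#'   required for the binomial family.
#' @param type HOF type, one of `"I"`..`"V"`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param M response ceiling (default 1).
#' @param bound box constraint \eqn{|a|,|b|,|c|,|d| \le} `bound` on the scaled
#'   gradient.
#' @param gradient_range the metre range mapped onto \eqn{[0, 1]}, stored for
#'   inverse mapping.
#' @return a `hof_fit`: list with `type`, `params` (`hof_params`), `deviance`,
#'   `aicc`, `k` (free parameters), `n_obs`, `family`, `converged`,
#'   `gradient_range` and the fitting data.
#' @export
fit_hof <- function(x, y, trials = NULL,
                    type = c("II", "I", "III", "IV", "V"),
                    family = c("binomial", "gaussian"), M = 1, bound = 50,
                    gradient_range = c(-20, 20)) {
  type <- match.arg(type)
  family <- match.arg(family)
  n <- hof_validate(x, y, trials, family, M, type)
  if (all(y == 0)) {
    warning("all-zero profile: returning boundary flat fit")
    type <- "I"
  }
  hof_chain(x, y, n, type, family, M, bound, gradient_range)[[type]]
}

hof_validate <- function(x, y, trials, family, M, type = "V") {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (any(y < 0 | y > M)) stop("profile values must lie in [0, M]")
  if (length(unique(x)) < 2L && type != "I") {
    stop("need >= 2 distinct gradient positions to fit type ", type)
  }
  if (family == "binomial") {
    if (is.null(trials)) stop("binomial fitting requires 'trials' denominators")
    stopifnot(length(trials) == length(y), all(trials > 0))
    as.numeric(trials)
  } else {
    rep(1, length(y))
  }
}

## fit types up to `want` in nesting order, seeding each type with the exact
## embedding of its nested sub-model optimum: I -> II (b = 0), II -> III and
## IV (c = -bound, i.e. the saturating factor equals 1 in double precision),
## IV -> V (d = b) and III -> V (d = 0). This both speeds up fitting and
## guarantees deviance monotonicity across the hierarchy.
hof_chain <- function(x, y, n, want, family, M, bound, gradient_range,
                      fast = FALSE) {
  want <- unique(want)
  fits <- list()
  fits$I <- hof_fit_one("I", x, y, n, family, M, bound, gradient_range)
  fo <- fast
  if (any(c("II", "III", "IV", "V") %in% want)) {
    fits$II <- hof_fit_one("II", x, y, n, family, M, bound, gradient_range,
                           warm = list(c(fits$I$par, 0)), fast = fo)
  }
  if (any(c("III", "V") %in% want)) {
    fits$III <- hof_fit_one("III", x, y, n, family, M, bound, gradient_range,
                            warm = list(c(fits$II$par, -bound)), fast = fo)
  }
  if (any(c("IV", "V") %in% want)) {
    fits$IV <- hof_fit_one("IV", x, y, n, family, M, bound, gradient_range,
                           warm = list(c(fits$II$par, -bound)), fast = fo)
  }
  if ("V" %in% want) {
    fits$V <- hof_fit_one("V", x, y, n, family, M, bound, gradient_range,
                          warm = list(c(fits$IV$par, fits$IV$par[2]),
                                      c(fits$III$par, 0)), fast = fo)
  }
  fits
}

hof_fit_one <- function(type, x, y, n, family, M, bound, gradient_range,
                        warm = list(), fast = FALSE) {
  k <- hof_npar(type)
  obj <- hof_objective(type, x, y, n, family, M)

  if (type == "I") {
    mbar <- sum(n * y) / sum(n)
    a <- -stats::qlogis(min(max(mbar / M, 1e-12), 1 - 1e-12))
    a <- min(max(a, -bound), bound)
    best <- list(par = a, objective = obj(a), convergence = 0L)
  } else {
    grd <- hof_gradient(type, x, y, n, family, M)
    starts <- hof_starts(type, x, y, n, bound, warm, fast)
    best <- NULL
    for (s in starts) {
      fs <- obj(s)
      res <- tryCatch(
        stats::nlminb(s, obj, gradient = grd,
                      lower = rep(-bound, k), upper = rep(bound, k),
                      control = list(iter.max = 200L)),
        error = function(e) NULL)
      cand <- if (!is.null(res) && is.finite(res$objective) &&
                  res$objective <= fs) {
        list(par = res$par, objective = res$objective,
             convergence = res$convergence)
      } else {
        list(par = s, objective = fs, convergence = 1L)
      }
      if (is.null(best) || cand$objective < best$objective) best <- cand
    }
  }

  dev <- best$objective
  n_obs <- length(y)
  structure(list(
    type = type,
    params = hof_par_to_params(type, best$par, M),
    par = best$par,
    deviance = dev,
    aicc = hof_aicc(dev, k, n_obs, family),
    k = k, n_obs = n_obs, family = family, M = M,
    converged = identical(best$convergence, 0L),
    gradient_range = gradient_range,
    data = list(x = x, y = y, trials = if (family == "binomial") n else NULL)
  ), class = "hof_fit")
}

## small-sample corrected AIC; for the binomial family the deviance differs
## from -2 logLik by a model-independent saturated term, so comparisons of
## aicc across types are unaffected
hof_aicc <- function(dev, k, n, family) {
  if (family == "gaussian") {
    k <- k + 1L  # residual variance
    base <- n * log(max(dev, 1e-300) / n)
  } else {
    base <- dev
  }
  if (n - k - 1 <= 0) return(Inf)
  base + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname fit_hof
#' @param object a `hof_fit`.
#' @param newx gradient positions on the scaled \eqn{[0, 1]} axis (or in
#'   metres when `metres = TRUE`).
#' @param metres interpret `newx` in metres using the stored gradient range.
#' @param ... unused.
#' @export
predict.hof_fit <- function(object, newx, metres = FALSE, ...) {
  if (metres) newx <- scale_gradient(newx, object$gradient_range)
  hof_curve(object$params, newx)
}

#' @export
print.hof_fit <- function(x, ...) {
  cat("HOF type ", x$type, " (", x$family, "), deviance ",
      format(x$deviance, digits = 5), ", AICc ",
      format(x$aicc, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Map signed distances (metres) onto the scaled \eqn{[0, 1]} gradient
#'
#' @param distance_m signed distances from the boundary (woodlot negative).
#' @param gradient_range metre range mapped to \eqn{[0, 1]}.
#' @return positions on \eqn{[0, 1]} (woodlot interior 0, field interior 1).
#' @export
scale_gradient <- function(distance_m, gradient_range = c(-20, 20)) {
  (distance_m - gradient_range[1]) / diff(gradient_range)
}

#' Fit all candidate HOF types and select one
#'
#' Candidates are fitted with nested warm starts (type I closed form; II
#' seeded from I; III and IV from II; V from IV and III) and the winner chosen
#' either by small-sample corrected AIC (`"aicc"`, the default: under literal
#' deviance minimisation the most complex type always wins by nesting) or by
#' raw deviance (`"deviance"`); ties within `tol` go to the type with fewer
#' parameters.
#'
#' @inheritParams fit_hof
#' @param types candidate types.
#' @param criterion `"aicc"` or `"deviance"`.
#' @param tol tie tolerance for criterion comparisons.
#' @param fast use a reduced multistart grid (the nested warm-start chain plus
#'   a few generic starts); intended for bootstrap refits where thousands of
#'   fits are made to perturbed versions of the same profile.
#' @return the selected `hof_fit`, with a `candidates` data frame
#'   (type, k, deviance, aicc) attached.
#' @export
select_hof <- function(x, y, trials = NULL,
                       types = c("I", "II", "III", "IV", "V"),
                       criterion = c("aicc", "deviance"),
                       family = c("binomial", "gaussian"), M = 1, bound = 50,
                       tol = 1e-6, gradient_range = c(-20, 20),
                       fast = FALSE) {
  criterion <- match.arg(criterion)
  family <- match.arg(family)
  types <- match.arg(types, c("I", "II", "III", "IV", "V"),
                     several.ok = TRUE)
  n <- hof_validate(x, y, trials, family, M)
  if (all(y == 0)) {
    fit <- hof_fit_one("I", x, y, n, family, M, bound, gradient_range)
    warning("all-zero profile: flat boundary fit selected")
    fit$candidates <- data.frame(type = "I", k = 1L, deviance = fit$deviance,
                                 aicc = fit$aicc)
    return(fit)
  }

  fits <- hof_chain(x, y, n, types, family, M, bound, gradient_range, fast)
  fits <- fits[intersect(c("I", "II", "III", "IV", "V"), types)]

  cand <- data.frame(
    type = names(fits),
    k = vapply(fits, function(f) f$k, integer(1)),
    deviance = vapply(fits, function(f) f$deviance, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  score <- if (criterion == "aicc") cand$aicc else cand$deviance
  ## ties within tol -> fewest parameters
  ord <- order(score)
  best_score <- score[ord[1]]
  tied <- which(score <= best_score + tol)
  pick <- tied[which.min(cand$k[tied])]
  out <- fits[[cand$type[pick]]]
  out$criterion <- criterion
  out$candidates <- cand
  out
}
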