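#' Spherical variogram model
#'
#' The bounded spherical model used throughout the package, with
#' semivariance
#' \deqn{\gamma(h) = c_0 + c \left(1.5\,h/a - 0.5\,(h/a)^3\right), \quad h \le a,}
#' and \eqn{\gamma(h) = c_0 + c} beyond the range \eqn{a}, where \eqn{c_0}
#' is the nugget and \eqn{c = \mathrm{sill} - c_0} the partial sill. The
#' stratum-map interpolation of the Norwegian NFI uses this model with a
#' zero nugget, sill 0.73 and range 5600 m on the logit-elevation scale.
#'
#' @param nugget non-negative nugget variance \eqn{c_0}.
#' @param sill total sill (nugget + partial sill); must be `>= nugget`.
#' @param range range \eqn{a} in m, `> 0`.
#' @return an object of class `variogram_model`.
#' @export
spherical_variogram <- function(nugget = 0, sill = 0.73, range = 5600) {
  stopifnot(nugget >= 0, sill >= nugget, range > 0)
  structure(list(kind = "spherical", nugget = nugget, sill = sill,
                 range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> spherical: nugget %.4g, sill %.4g, range %.6g m\n",
              x$nugget, x$sill, x$range))
  invisible(x)
}

#' Semivariance and covariance of a spherical model
#'
#' `semivariance()` evaluates \eqn{\gamma(h)}; `model_covariance()` the
#' corresponding stationary covariance \eqn{C(h) = \mathrm{sill} - \gamma(h)}
#' (so that \eqn{C(0)} equals the full sill including the nugget).
#'
#' @param model a [spherical_variogram()].
#' @param h non-negative lag distances (m).
#' @export
semivariance <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  c0 <- model$nugget
  c1 <- model$sill - model$nugget
  a <- model$range
  u <- pmin(h / a, 1)
  g <- c0 + c1 * (1.5 * u - 0.5 * u^3)
  g[h == 0] <- 0
  g
}

#' @rdname semivariance
#' @export
model_covariance <- function(model, h) {
  model$sill - semivariance(model, h)
}

#' Empirical semivariogram from point data
#'
#' Classical (Matheron) estimator binned on distance.
#'
#' @param coords two-column matrix of point coordinates (m).
#' @param values numeric vector of observations at `coords`.
#' @param cutoff maximum lag considered; default one third of the maximum
#'   pairwise distance.
#' @param n_bins number of equal-width lag bins.
#' @return data.frame with columns `lag` (mean pair distance in the bin),
#'   `gamma` (semivariance) and `n` (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(coords, values, cutoff = NULL, n_bins = 15) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(values), nrow(coords) >= 2)
  d <- as.vector(stats::dist(coords))
  if (is.null(cutoff)) cutoff <- max(d) / 3
  dv <- as.vector(stats::dist(values))^2 / 2
  keep <- d > 0 & d <= cutoff
  d <- d[keep]; dv <- dv[keep]
  bin <- pmin(floor(d / (cutoff / n_bins)) + 1L, n_bins)
  lag <- tapply(d, bin, mean)
  gamma <- tapply(dv, bin, mean)
  n <- tapply(dv, bin, length)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gamma),
                    n = as.integer(n))
  out[order(out$lag), , drop = FALSE]
}

#' Weighted least-squares fit of a spherical variogram
#'
#' Fits nugget, partial sill and range to empirical semivariances by
#' minimising \eqn{\sum_j n_j (\hat\gamma_j - \gamma(h_j))^2} (pair-count
#' weights) over non-negative parameters.
#'
#' @param ev data.frame as returned by [empirical_variogram()] (columns
#'   `lag`, `gamma`, and optionally `n`; missing `n` means unit weights).
#' @param weights `"npairs"` (default) or `"equal"`.
#' @return a [spherical_variogram()] model. If all semivariances are zero a
#'   degenerate sill-0 model is returned with a warning.
#' @export
fit_spherical_variogram <- function(ev, weights = c("npairs", "equal")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(ev), all(c("lag", "gamma") %in% names(ev)))
  ev <- ev[is.finite(ev$gamma) & is.finite(ev$lag), , drop = FALSE]
  if (nrow(ev) < 3) stop("need at least 3 lag bins with finite semivariance")
  w <- if (weights == "npairs" && !is.null(ev$n)) ev$n else rep(1, nrow(ev))
  if (all(ev$gamma == 0)) {
    warning("all semivariances are zero; returning degenerate sill-0 model")
    return(spherical_variogram(0, 0, max(ev$lag)))
  }
  # profile fit: for fixed range the model is linear in (nugget, psill),
  # solved by non-negative weighted least squares; range by grid + refine
  profile <- function(a) {
    u <- pmin(ev$lag / a, 1)
    x <- 1.5 * u - 0.5 * u^3
    fit2 <- function() {
      sw <- sqrt(w)
      qr_fit <- stats::lm.fit(cbind(sw, sw * x), sw * ev$gamma)
      qr_fit$coefficients
    }
    b <- fit2()
    if (any(is.na(b))) b[is.na(b)] <- 0
    if (b[1] < 0 || b[2] < 0) {
      # clamp the offending coefficient at zero, refit the other
      cand <- list(
        c(0, max(0, sum(w * x * ev$gamma) / sum(w * x^2))),
        c(max(0, sum(w * ev$gamma) / sum(w)), 0)
      )
      sse <- vapply(cand, function(p)
        sum(w * (ev$gamma - p[1] - p[2] * x)^2), numeric(1))
      b <- cand[[which.min(sse)]]
    }
    list(par = b, sse = sum(w * (ev$gamma - b[1] - b[2] * x)^2))
  }
  a_grid <- exp(seq(log(min(ev$lag) / 4), log(10 * max(ev$lag)),
                    length.out = 250))
  sse <- vapply(a_grid, function(a) profile(a)$sse, numeric(1))
  k <- which.min(sse)
  lo <- a_grid[max(1, k - 1)]; hi <- a_grid[min(length(a_grid), k + 1)]
  opt <- stats::optimize(function(a) profile(a)$sse, c(lo, hi))
  a_best <- if (opt$objective <= sse[k]) opt$minimum else a_grid[k]
  p <- unname(profile(a_best)$par)
  spherical_variogram(nugget = p[1], sill = p[1] + p[2], range = a_best)
}

# spherical semivariance without constructing a model object (hot path)
gamma_sph <- function(h, nugget, psill, range) {
  u <- pmin(h / range, 1)
  out <- nugget + psill * (1.5 * u - 0.5 * u^3)
  out[h == 0] <- 0
  out
}

#' Simulate a Gaussian random field at arbitrary points
#'
#' Draws one mean-zero Gaussian realization with the covariance implied by a
#' spherical variogram model, by dense Cholesky factorisation of the
#' covariance matrix. Intended for the moderate point counts (a few
#' thousand) used in design simulations.
#'
#' @param coords two-column matrix of point coordinates (m).
#' @param model a [spherical_variogram()].
#' @param seed optional integer seed (local RNG use).
#' @return numeric vector of field values at `coords`.
#' @export
simulate_gaussian_field <- function(coords, model, seed = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!is.null(seed)) set.seed(seed)
  if (model$sill <= 0) return(rep(0, n))
  Sigma <- model_covariance(model, as.matrix(stats::dist(coords)))
  diag(Sigma) <- model$sill + 1e-10 * model$sill  # numerical jitter
  L <- chol(Sigma)
  as.vector(crossprod(L, stats::rnorm(n)))
}

#' Universal kriging with a spherical covariance
#'
#' Solves the universal-kriging system with a linear trend in the supplied
#' covariate(s): for prediction point \eqn{s_0},
#' \deqn{\begin{pmatrix} K & X \\ X' & 0 \end{pmatrix}
#'       \begin{pmatrix} \lambda \\ \mu \end{pmatrix} =
#'       \begin{pmatrix} k_0 \\ x_0 \end{pmatrix}}
#' with \eqn{K} the observation covariance matrix, \eqn{X = (1, f(s))} the
#' trend basis and \eqn{k_0} the covariances to \eqn{s_0}. With a zero
#' nugget the predictor interpolates the data exactly.
#'
#' Duplicate observation locations are averaged (first-listed coordinates
#' kept) before the system is assembled. With more than `max_global`
#' observations each point is predicted from its `n_local` nearest
#' observations.
#'
#' @param obs_coords two-column matrix of observation locations (m).
#' @param obs_values observations.
#' @param obs_covariate trend covariate at the observations (vector or
#'   matrix, one column per covariate).
#' @param pred_coords two-column matrix of prediction locations.
#' @param pred_covariate trend covariate at the prediction locations.
#' @param model a [spherical_variogram()].
#' @param max_global use the full observation set when `n <= max_global`.
#' @param n_local neighbourhood size beyond that.
#' @return numeric vector of predictions.
#' @export
krige_universal <- function(obs_coords, obs_values, obs_covariate,
                            pred_coords, pred_covariate, model,
                            max_global = 2000, n_local = 500) {
  obs_coords <- as.matrix(obs_coords)
  pred_coords <- as.matrix(pred_coords)
  obs_covariate <- as.matrix(obs_covariate)
  pred_covariate <- as.matrix(pred_covariate)
  stopifnot(nrow(obs_coords) == length(obs_values),
            nrow(obs_covariate) == length(obs_values),
            nrow(pred_covariate) == nrow(pred_coords))
  if (nrow(obs_coords) < 2) stop("need at least 2 observations")

  key <- paste(obs_coords[, 1], obs_coords[, 2], sep = "_")
  if (anyDuplicated(key)) {
    agg <- tapply(obs_values, key, mean)
    first <- !duplicated(key)
    ord <- key[first]
    obs_values <- as.numeric(agg[ord])
    obs_coords <- obs_coords[first, , drop = FALSE]
    obs_covariate <- obs_covariate[first, , drop = FALSE]
  }

  n <- nrow(obs_coords)
  if (n <= max_global) {
    kuk_solve(obs_coords, obs_values, obs_covariate,
              pred_coords, pred_covariate, model)
  } else {
    out <- numeric(nrow(pred_coords))
    for (i in seq_len(nrow(pred_coords))) {
      d2 <- (obs_coords[, 1] - pred_coords[i, 1])^2 +
        (obs_coords[, 2] - pred_coords[i, 2])^2
      idx <- order(d2)[seq_len(min(n_local, n))]
      out[i] <- kuk_solve(obs_coords[idx, , drop = FALSE], obs_values[idx],
                          obs_covariate[idx, , drop = FALSE],
                          pred_coords[i, , drop = FALSE],
                          pred_covariate[i, , drop = FALSE], model)
    }
    out
  }
}

kuk_solve <- function(oc, ov, ox, pc, px, model) {
  n <- nrow(oc)
  X <- cbind(1, ox)
  p <- ncol(X)
  K <- model_covariance(model, as.matrix(stats::dist(oc)))
  diag(K) <- model$sill
  A <- rbind(cbind(K, X), cbind(t(X), matrix(0, p, p)))
  # covariances observation -> prediction points
  dx <- outer(oc[, 1], pc[, 1], "-")
  dy <- outer(oc[, 2], pc[, 2], "-")
  k0 <- model_covariance(model, sqrt(dx^2 + dy^2))
  B <- rbind(k0, t(cbind(1, px)))
  lam <- tryCatch(solve(A, B), error = function(e) {
    # ridge on the covariance block for near-singular systems
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8 * model$sill
    solve(A, B)
  })
  as.vector(crossprod(lam[seq_len(n), , drop = FALSE], ov))
}

#' Kriged stratum-probability map
#'
#' Interpolates a binary stratum indicator observed at grid plot locations
#' onto a fine raster by universal kriging with a linear trend in the
#' logit-transformed elevation covariate, mirroring how the NFI derives its
#' alpine/lowland stratum map from the 3 km plot grid. Predictions are
#' clipped to \[0, 1\]; `threshold` turns them into a 0/1 stratum map.
#'
#' @param obs_coords plot locations (two-column matrix, m).
#' @param obs_indicator 0/1 stratum indicator at the plots.
#' @param covariate_raster elevation [nfi_raster()] (m a.s.l.).
#' @param model a [spherical_variogram()]; the NFI model is
#'   `spherical_variogram(0, 0.73, 5600)`.
#' @param elev_max scale used in the logit transform
#'   `qlogis(clamp(elev/elev_max))`.
#' @param threshold classification threshold on the probability scale.
#' @param ... passed to [krige_universal()].
#' @return list with `probability` and `stratum` rasters (same grid as
#'   `covariate_raster`).
#' @export
krige_stratum_probability <- function(obs_coords, obs_indicator,
                                      covariate_raster, model,
                                      elev_max = 1500, threshold = 0.5, ...) {
  stopifnot(all(obs_indicator %in% 0:1))
  logit_elev <- function(e) {
    p <- pmin(pmax(e / elev_max, 1e-6), 1 - 1e-6)
    stats::qlogis(p)
  }
  obs_cov <- logit_elev(raster_interpolate(covariate_raster, obs_coords[, 1],
                                           obs_coords[, 2]))
  xy <- raster_xy(covariate_raster)
  pred <- krige_universal(obs_coords, obs_indicator, obs_cov,
                          cbind(xy$x, xy$y), logit_elev(xy$value), model, ...)
  pred <- pmin(pmax(pred, 0), 1)
  d <- dim(covariate_raster$values)
  prob <- nfi_raster(matrix(pred, nrow = d[1], ncol = d[2], byrow = TRUE),
                     covariate_raster$xmin, covariate_raster$ymin,
                     covariate_raster$cellsize)
  strat <- prob
  strat$values <- (prob$values >= threshold) * 1
  list(probability = prob, stratum = strat)
}
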