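#' Scalar time series container
#'
#' @param values Numeric vector (at least 2 finite samples).
#' @param dt_ps Sampling step in ps (default 1, the trajectory write-out
#'   interval the analysis assumes).
#' @param label Optional label.
#' @return Object of class `scalar_series`.
#' @export
scalar_series <- function(values, dt_ps = 1, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values)))
    stop("series must hold at least 2 finite samples")
  stopifnot(dt_ps > 0)
  structure(list(values = values, dt_ps = dt_ps, label = label),
            class = "scalar_series")
}

#' Auto-/cross-covariance of uniformly sampled series via FFT
#'
#' Biased (1/N) estimator of g(tau) = cov(x(t), y(t - tau)) after per-series
#' mean removal, computed with zero-padded FFTs; identical (to rounding) to
#' the direct double-loop sum.
#'
#' @param x,y [scalar_series()] objects with equal length and step. For an
#'   autocovariance pass the same series twice (the default `y = x`).
#' @param max_lag_ns Maximum lag in ns; must be below the series span.
#' @param normalize If TRUE, divide by the zero-lag value.
#' @return Object of class `cov_curve`: `lags_ns`, `values`, `sigma2`
#'   (zero-lag covariance, in squared series units), `normalized`.
#' @export
series_covariance <- function(x, y = x, max_lag_ns, normalize = FALSE) {
  stopifnot(inherits(x, "scalar_series"), inherits(y, "scalar_series"))
  if (length(x$values) != length(y$values) || x$dt_ps != y$dt_ps)
    stop("series length or sampling step mismatch")
  N <- length(x$values)
  dt_ns <- x$dt_ps * 1e-3
  nlag <- floor(max_lag_ns / dt_ns)
  if (nlag >= N) stop("max_lag exceeds the series span")
  xc <- x$values - mean(x$values)
  yc <- y$values - mean(y$values)
  nfft <- stats::nextn(N + nlag + 1, 2)
  fx <- fft(c(xc, rep(0, nfft - N)))
  fy <- fft(c(yc, rep(0, nfft - N)))
  # cross-correlation sum_t x_{t} y_{t-k}, k >= 0
  cc <- Re(fft(fx * Conj(fy), inverse = TRUE)) / nfft
  vals <- cc[1:(nlag + 1)] / N
  sigma2 <- vals[1]
  if (normalize) {
    if (sigma2 == 0) stop("cannot normalize a zero-variance covariance curve")
    vals <- vals / sigma2
  }
  structure(list(lags_ns = (0:nlag) * dt_ns, values = vals,
                 sigma2 = sigma2, normalized = normalize,
                 label = paste(x$label, y$label, sep = "|")),
            class = "cov_curve")
}

#' Distinct tensor-component correlation pairs
#'
#' Partitions the 81 ordered pairs of 3x3 tensor component labels into
#' equivalence classes under (optionally) tensor symmetry A_ab = A_ba and
#' always under exchange g(alpha, beta) = g(beta, alpha), returning one
#' representative per class. For a symmetric tensor there are 21 distinct
#' correlation functions (6 unique components, 6*7/2 unordered pairs); without
#' tensor symmetry, 45.
#'
#' @param symmetric Apply tensor-component symmetry? Default TRUE.
#' @return Data frame with columns `alpha`, `beta` (canonical labels) and
#'   `n_members` (class size among the 81 ordered pairs).
#' @export
distinct_component_pairs <- function(symmetric = TRUE) {
  ax <- c("x", "y", "z")
  comp <- as.vector(outer(ax, ax, paste0))     # xx, yx, zx, xy, ...
  canon <- function(s) {
    a <- substr(s, 1, 1); b <- substr(s, 2, 2)
    if (symmetric && a > b) paste0(b, a) else s
  }
  pairs <- expand.grid(alpha = comp, beta = comp, stringsAsFactors = FALSE)
  key <- apply(pairs, 1, function(p) {
    ca <- canon(p[["alpha"]]); cb <- canon(p[["beta"]])
    paste(sort(c(ca, cb)), collapse = ":")
  })
  tab <- table(key)
  reps <- do.call(rbind, strsplit(names(tab), ":"))
  out <- data.frame(alpha = reps[, 1], beta = reps[, 2],
                    n_members = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$alpha, out$beta), , drop = FALSE]
}

#' Fixed logarithmic lag grid for multiexponential fits
#'
#' 50 lag times spaced logarithmically between 0.5 ps and 100 ns (endpoints
#' exact).
#'
#' @return Numeric vector of length 50, in ns.
#' @export
tau_grid <- function() {
  g <- exp(seq(log(5e-4), log(100), length.out = 50))
  g[1] <- 5e-4
  g[50] <- 100
  g
}

#' Fit a covariance curve with 50 exponential decays
#'
#' Models g(tau) ~ cov * sum_j c_j exp(-tau / tau_j) on the fixed grid of
#' [tau_grid()]. The curve is normalized by its zero-lag value, fitted by
#' non-negative least squares (the 50-exponential basis is severely
#' ill-conditioned, and non-negativity is the stabilizing constraint), and
#' the weights are renormalized to sum to 1; the prefactor is the zero-lag
#' covariance. Fitting uses a logarithmic subsample of the lag axis (dense at
#' short lags where the curve carries information, sparse at long lags where
#' estimator noise dominates).
#'
#' @param curve A `cov_curve` from [series_covariance()].
#' @param max_fit_lag_ns Longest lag entering the fit (default 50 ns, half
#'   the longest grid time); the curve must extend at least `min_span_ns`.
#' @param min_span_ns Required lag coverage (default 10 ns).
#' @param n_fit_lags Size of the logarithmic lag subsample (default 400).
#' @param weighting "bartlett" (default) scales residuals by the inverse
#'   Bartlett standard error of the covariance estimator, which grows like
#'   sqrt(lag); this stabilizes the ill-conditioned long-time weights
#'   against estimator noise at long lags. "none" fits unweighted. Noiseless
#'   curves are fitted identically under both choices.
#' @param pair Optional component-pair label, e.g. c("xx", "xx").
#' @return Object of class `cov_model`: `prefactor` (zero-lag covariance),
#'   `weights` (50, non-negative, summing to 1), `tau_ns` (the grid),
#'   `residual_rms` (RMS of the normalized-curve fit residual), `pair`,
#'   `degenerate` flag.
#' @export
fit_cov_model <- function(curve, max_fit_lag_ns = 50, min_span_ns = 10,
                          n_fit_lags = 400,
                          weighting = c("bartlett", "none"),
                          pair = c("", "")) {
  stopifnot(inherits(curve, "cov_curve"))
  weighting <- match.arg(weighting)
  span <- max(curve$lags_ns)
  if (span < min_span_ns)
    stop(sprintf("curve spans %.3g ns; at least %g ns of lag required",
                 span, min_span_ns))
  taus <- tau_grid()
  if (curve$sigma2 == 0 || all(curve$values == 0)) {
    return(structure(list(prefactor = 0, weights = rep(1 / 50, 50),
                          tau_ns = taus, residual_rms = 0,
                          pair = pair, degenerate = TRUE),
                     class = "cov_model"))
  }
  g <- if (curve$normalized) curve$values else curve$values / curve$sigma2
  lags <- curve$lags_ns
  keep <- lags <= min(max_fit_lag_ns, span)
  g <- g[keep]; lags <- lags[keep]
  # log-spaced subsample of lag indices (always keeps lag 0)
  if (length(lags) > n_fit_lags) {
    idx <- unique(c(1L, round(exp(seq(log(2), log(length(lags)),
                                      length.out = n_fit_lags - 1)))))
    g <- g[idx]; lags <- lags[idx]
  }
  # Identifiability cutoff: decay times beyond half the fitted lag span are
  # indistinguishable from a constant baseline over the window and would
  # only ever fit estimator noise; their weights stay zero.
  usable <- taus <= max(lags) / 2
  if (!any(usable)) usable <- taus <= taus[1]
  basis <- exp(-outer(lags, taus[usable], "/"))
  dt <- if (length(curve$lags_ns) > 1) curve$lags_ns[2] - curve$lags_ns[1] else 1e-3
  rw <- if (weighting == "bartlett") 1 / sqrt(lags + dt) else rep(1, length(lags))
  fit <- pracma::lsqnonneg(basis * rw, g * rw)
  w <- numeric(50)
  w[usable] <- fit$x
  if (sum(w) <= 0) {
    return(structure(list(prefactor = curve$sigma2, weights = rep(1 / 50, 50),
                          tau_ns = taus, residual_rms = sqrt(mean(g^2)),
                          pair = pair, degenerate = TRUE),
                     class = "cov_model"))
  }
  resid <- g - as.numeric(basis %*% fit$x)
  w <- w / sum(w)
  structure(list(prefactor = curve$sigma2, weights = w, tau_ns = taus,
                 residual_rms = sqrt(mean(resid^2)), pair = pair,
                 degenerate = FALSE,
                 fit_lags_ns = lags, fit_values = g),
            class = "cov_model")
}

#' @export
print.cov_model <- function(x, ...) {
  cat(sprintf("Multiexponential covariance model (%s,%s)%s\n",
              x$pair[1], x$pair[2],
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat(sprintf("  prefactor    = %.6g (units^2)\n", x$prefactor))
  cat(sprintf("  tau_eff      = %.4g ns\n", effective_correlation_time(x)))
  cat(sprintf("  residual RMS = %.3g (normalized curve)\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.cov_model <- function(object, ...) {
  stats::setNames(object$weights, sprintf("tau=%.4gns", object$tau_ns))
}

#' @export
predict.cov_model <- function(object, lags_ns, normalized = FALSE, ...) {
  v <- as.numeric(exp(-outer(lags_ns, object$tau_ns, "/")) %*% object$weights)
  if (normalized) v else object$prefactor * v
}

#' @export
residuals.cov_model <- function(object, ...) {
  if (is.null(object$fit_lags_ns)) return(numeric(0))
  object$fit_values - predict(object, object$fit_lags_ns, normalized = TRUE)
}

#' @export
plot.cov_model <- function(x, ...) {
  if (is.null(x$fit_lags_ns)) stop("degenerate model has no stored fit data")
  graphics::plot(x$fit_lags_ns, x$fit_values, log = "x", pch = 16, cex = 0.4,
                 xlab = "lag (ns)", ylab = "normalized covariance", ...)
  graphics::lines(x$fit_lags_ns, predict(x, x$fit_lags_ns, normalized = TRUE),
                  col = 2, lwd = 2)
  invisible(x)
}

#' Effective correlation time of a fitted covariance model
#'
#' tau_eff = sum_j c_j tau_j, the integral of the normalized fitted curve.
#'
#' @param model A `cov_model`.
#' @return Effective correlation time in ns.
#' @export
effective_correlation_time <- function(model) {
  stopifnot(inherits(model, "cov_model"))
  sum(model$weights * model$tau_ns)
}

#' Zero-frequency spectral density of a fitted covariance model
#'
#' J(0) = cov * sum_j c_j tau_j, the one-sided integral of the fitted
#' covariance function at omega = 0 (no factor of 2; imaginary parts, i.e.
#' dynamic frequency shifts, are discarded). For g-tensor components the
#' field factor (mu_B Bz / hbar)^2 is *not* applied here; it enters when the
#' relaxation superoperator is built, so the model stays field-independent.
#'
#' @param model A `cov_model`.
#' @return J(0) in prefactor-units * ns (rad^2/ns for hyperfine models).
#' @export
spectral_density_zero <- function(model) {
  model$prefactor * effective_correlation_time(model)
}

# Integrated autocorrelation time (ns) with a self-consistent window:
# tau_int(W) = dt * (rho_0/2 + sum_{k=1..W} rho_k), W the smallest lag with
# W >= c * tau_int(W)/dt. Robust against long-lag estimator noise; used for
# internal calibration of the synthetic dynamics.
tau_int_windowed <- function(x, dt_ns, c_win = 8) {
  x <- x - mean(x)
  N <- length(x)
  nfft <- stats::nextn(2 * N, 2)
  f <- fft(c(x, rep(0, nfft - N)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[1:N] / nfft / N
  if (ac[1] <= 0) return(0)
  rho <- ac / ac[1]
  csum <- 0.5 + cumsum(rho[-1])
  k <- seq_along(csum)
  w <- which(k >= c_win * csum)[1]
  if (is.na(w)) w <- length(csum)
  dt_ns * csum[w]
}

# Lorentzian spectral density at angular frequency omega (rad/ns):
# J(omega) = cov * sum_j c_j tau_j / (1 + (omega tau_j)^2).
spectral_density <- function(model, omega) {
  vapply(omega, function(w)
    model$prefactor * sum(model$weights * model$tau_ns /
                            (1 + (w * model$tau_ns)^2)), 0)
}

#' Serialize / read a covariance model
#'
#' Structured-text (YAML) round trip of the component pair, prefactor, 50
#' weights, grid endpoints and residual RMS.
#'
#' @param model A `cov_model`.
#' @param path File path.
#' @return `read_cov_model()` returns the `cov_model`.
#' @export
write_cov_model <- function(model, path) {
  yaml::write_yaml(list(pair = as.character(model$pair),
                        prefactor = model$prefactor,
                        weights = as.numeric(model$weights),
                        tau_start_ns = model$tau_ns[1],
                        tau_end_ns = model$tau_ns[length(model$tau_ns)],
                        residual_rms = model$residual_rms,
                        degenerate = isTRUE(model$degenerate)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_cov_model
#' @export
read_cov_model <- function(path) {
  x <- yaml::read_yaml(path)
  taus <- tau_grid()
  if (abs(x$tau_start_ns - taus[1]) > 1e-12 ||
      abs(x$tau_end_ns - taus[50]) > 1e-9)
    stop("covariance model grid endpoints do not match the fixed lag grid")
  structure(list(prefactor = x$prefactor, weights = as.numeric(x$weights),
                 tau_ns = taus, residual_rms = x$residual_rms,
                 pair = as.character(x$pair),
                 degenerate = isTRUE(x$degenerate)),
            class = "cov_model")
}

#' Construct a covariance model with a prescribed effective time
#'
#' Helper for configuration-driven relaxation inputs: places weight on the
#' two grid points bracketing `tau_ns` so that the effective correlation time
#' is exact.
#'
#' @param prefactor Zero-lag covariance (units^2).
#' @param tau_ns Target effective correlation time (ns), within the grid.
#' @param pair Component-pair label.
#' @return A `cov_model`.
#' @export
cov_model_simple <- function(prefactor, tau_ns, pair = c("", "")) {
  taus <- tau_grid()
  if (tau_ns < taus[1] || tau_ns > taus[50])
    stop("tau_ns outside the fixed lag grid")
  w <- numeric(50)
  hi <- which(taus >= tau_ns)[1]
  if (taus[hi] == tau_ns) {
    w[hi] <- 1
  } else {
    lo <- hi - 1
    f <- (tau_ns - taus[lo]) / (taus[hi] - taus[lo])
    w[lo] <- 1 - f; w[hi] <- f
  }
  structure(list(prefactor = prefactor, weights = w, tau_ns = taus,
                 residual_rms = 0, pair = pair, degenerate = FALSE),
            class = "cov_model")
}

#' Write a covariance curve as two-column TSV
#'
#' Columns `lag_ns`, `value`.
#'
#' @param curve A `cov_curve`.
#' @param path Output path.
#' @export
write_cov_curve <- function(curve, path) {
  df <- data.frame(lag_ns = curve$lags_ns, value = curve$values)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
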