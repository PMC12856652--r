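test_that("FFT covariance equals the direct double-loop sum", {
  set.seed(101)
  x <- rnorm(2000); y <- 0.5 * x + rnorm(2000)
  sx <- scalar_series(x, 1); sy <- scalar_series(y, 1)
  cv <- series_covariance(sx, sy, max_lag_ns = 0.5)
  expect_equal(cv$values, cov_direct(x, y, 500), tolerance = 1e-10)
  # autocovariance too
  cva <- series_covariance(sx, sx, max_lag_ns = 0.3)
  expect_equal(cva$values, cov_direct(x, x, 300), tolerance = 1e-10)
  expect_error(series_covariance(sx, scalar_series(y[1:100], 1), 0.1),
               "mismatch")
  expect_error(series_covariance(sx, sy, max_lag_ns = 3), "span")
})

test_that("degenerate series give the expected covariance curves", {
  const <- scalar_series(rep(2.5, 500), 1)
  cv <- series_covariance(const, const, max_lag_ns = 0.1)
  expect_true(all(cv$values == 0))
  alt <- scalar_series(rep(c(1, -1), 250), 1)
  cva <- series_covariance(alt, alt, max_lag_ns = 0.01, normalize = TRUE)
  # biased 1/N estimator: (-1)^k up to the (N-k)/N taper
  expect_equal(cva$values, (-1)^(0:10) * (500 - 0:10) / 500, tolerance = 1e-12)
  expect_equal(cva$values, (-1)^(0:10), tolerance = 0.025)
})

test_that("distinct component pairs follow tensor and exchange symmetry", {
  p21 <- distinct_component_pairs(symmetric = TRUE)
  expect_equal(nrow(p21), 21L)
  expect_equal(sum(p21$n_members), 81L)
  expect_equal(sum(p21$alpha == p21$beta), 6L)   # pure autocovariances
  p45 <- distinct_component_pairs(symmetric = FALSE)
  expect_equal(nrow(p45), 45L)
  expect_equal(sum(p45$n_members), 81L)
})

test_that("the lag grid is logarithmic from 0.5 ps to 100 ns", {
  g <- tau_grid()
  expect_length(g, 50)
  expect_equal(g[1], 5e-4)
  expect_equal(g[50], 100)
  expect_true(all(diff(g) > 0))
  expect_equal(sd(diff(log(g))), 0, tolerance = 1e-12)
})

make_curve <- function(f, t_max = 60, dt = 1e-3, sigma2 = 1) {
  lags <- seq(0, t_max, by = dt)
  structure(list(lags_ns = lags, values = sigma2 * f(lags), sigma2 = sigma2,
                 normalized = FALSE),
            class = "cov_curve")
}

test_that("multiexponential fit recovers known mixtures", {
  m1 <- fit_cov_model(make_curve(function(t) exp(-t)))
  expect_equal(effective_correlation_time(m1), 1, tolerance = 0.02)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-6)
  expect_true(all(m1$weights >= 0))

  # white noise: delta spike at lag zero
  mw <- fit_cov_model(make_curve(function(t) as.numeric(t == 0)))
  expect_lte(effective_correlation_time(mw), 2 * 5e-4)

  m2 <- fit_cov_model(make_curve(function(t) 0.5 * exp(-t / 0.1) +
                                               0.5 * exp(-t / 2)))
  expect_equal(effective_correlation_time(m2), 1.05, tolerance = 0.05)

  # all-zero curve: degenerate model
  m0 <- fit_cov_model(make_curve(function(t) 0 * t, sigma2 = 0))
  expect_true(m0$degenerate)
  expect_equal(m0$prefactor, 0)
  expect_error(fit_cov_model(make_curve(function(t) exp(-t), t_max = 5)),
               "at least")
})

test_that("fits of grid-exponential mixtures are exact within noise floor", {
  set.seed(7)
  taus <- tau_grid()
  usable <- which(taus <= 25)  # identifiable within the default 50 ns window
  for (rep in 1:8) {
    k <- sample(usable, 3)
    w <- runif(3); w <- w / sum(w)
    f <- function(t) colSums(w * exp(-outer(taus[k], t, function(a, b) b / a)))
    m <- fit_cov_model(make_curve(f, sigma2 = 2.7))
    expect_lt(m$residual_rms, 0.02)
    expect_equal(effective_correlation_time(m), sum(w * taus[k]),
                 tolerance = 0.05)
    expect_equal(m$prefactor, 2.7, tolerance = 1e-9)
  }
})

test_that("effective correlation time matches its quadrature oracle", {
  w <- numeric(50); w[c(10, 30)] <- c(0.4, 0.6)
  m <- structure(list(prefactor = 3, weights = w, tau_ns = tau_grid(),
                      residual_rms = 0, pair = c("xx", "xx"),
                      degenerate = FALSE),
                 class = "cov_model")
  expect_equal(effective_correlation_time(m), sum(w * tau_grid()))
  expect_equal(effective_correlation_time(m), model_integral_numeric(m),
               tolerance = 0.01)
  # all weight on one grid point
  w1 <- numeric(50); w1[25] <- 1
  m1 <- m; m1$weights <- w1
  expect_equal(effective_correlation_time(m1), tau_grid()[25])
  # uniform weights -> arithmetic mean of the grid
  mu <- m; mu$weights <- rep(1 / 50, 50)
  expect_equal(effective_correlation_time(mu), mean(tau_grid()))
  # invariance under curve rescaling
  m2 <- fit_cov_model(make_curve(function(t) exp(-t / 0.5)))
  m3 <- fit_cov_model(make_curve(function(t) exp(-t / 0.5), sigma2 = 40))
  expect_equal(effective_correlation_time(m2), effective_correlation_time(m3),
               tolerance = 1e-9)
})

test_that("zero-frequency spectral density is cov times effective time", {
  w <- numeric(50); w[20] <- 1
  m <- structure(list(prefactor = 4, weights = w, tau_ns = tau_grid(),
                      residual_rms = 0, pair = c("zz", "zz"),
                      degenerate = FALSE),
                 class = "cov_model")
  m$weights <- numeric(50)
  m$weights[which.min(abs(tau_grid() - 0.5))] <- 1
  tau_pt <- tau_grid()[which.min(abs(tau_grid() - 0.5))]
  expect_equal(spectral_density_zero(m), 4 * tau_pt)
  m0 <- m; m0$prefactor <- 0
  expect_equal(spectral_density_zero(m0), 0)
  # one-sided Fourier transform at omega = 0 (numeric quadrature oracle)
  expect_equal(spectral_density_zero(m),
               4 * model_integral_numeric(m), tolerance = 0.01)
  # bilinearity: J(0) linear in prefactor and in effective time
  m2 <- m; m2$prefactor <- 8
  expect_equal(spectral_density_zero(m2), 2 * spectral_density_zero(m))
})

test_that("covariance models serialize and round-trip", {
  m <- fit_cov_model(make_curve(function(t) exp(-t / 1.3), sigma2 = 0.02),
                     pair = c("xx", "xy"))
  f <- tempfile(fileext = ".yaml")
  write_cov_model(m, f)
  m2 <- read_cov_model(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$prefactor, m$prefactor, tolerance = 1e-12)
  expect_equal(m2$pair, c("xx", "xy"))
  expect_equal(effective_correlation_time(m2), effective_correlation_time(m),
               tolerance = 1e-10)
})

test_that("cov_model_simple hits the requested effective time exactly", {
  for (tau in c(0.92, 1.21, 0.0005, 100)) {
    m <- cov_model_simple(2, tau)
    expect_equal(effective_correlation_time(m), tau, tolerance = 1e-12)
    expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  }
  expect_error(cov_model_simple(1, 1e-5), "grid")
})
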