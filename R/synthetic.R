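# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Parameters of the synthetic-dynamics generator
#'
#' The generator emulates the statistical structure of molecular-dynamics
#' input the spin-relaxation analysis assumes: a peroxide-group dihedral
#' angle with a multimodal stationary density containing a hard excluded
#' window and a cos(Omega) correlation time near 1 ns; slower rigid-fragment
#' reorientation; and dihedral-dependent hyperfine/g tensors whose
#' fluctuations derive entirely from the dihedral rotation and fragment
#' tumbling.
#'
#' @param n_frames Trajectory length in frames (default 1,360,000 at 1 ps,
#'   the trajectory size the analysis is designed for). Must be at least 10
#'   target correlation times.
#' @param dt_ps Frame spacing in ps (default 1).
#' @param target_tau_ns Target effective correlation time of cos(Omega), ns.
#' @param mode_centers_deg,mode_kappas,mode_weights Circular (von
#'   Mises-like) mixture defining the stationary dihedral density.
#' @param excluded_center_deg,excluded_width_deg Hard excluded window (the
#'   dihedral range the dynamics never samples); width in (0, 180), default
#'   60 degrees. The width is a free parameter of the emulation, not a
#'   measured value.
#' @param rot_step_rad Per-frame Gaussian step scale of the isotropic
#'   orientation walk (radians); default 0.015 gives rank-2 reorientation
#'   times of a few ns, slower than the dihedral rotation.
#' @param a_iso_rad_ns Isotropic hyperfine magnitude of the dominant proton
#'   (rad/ns); default 0.3 places the low-field regime near 1 mT.
#' @param a_aniso_rad_ns Axial hyperfine anisotropy amplitude (rad/ns),
#'   small by construction (the dominant coupling is mostly isotropic).
#' @param g_eigen g-tensor eigenvalues (peroxyl-like defaults).
#' @param g_omega_amp Scale of the dihedral dependence of the tensor
#'   orientation (1 = tensors rigidly follow the dihedral rotation).
#' @param seed Mandatory integer seed; all stochastic generation is
#'   reproducible given (params, seed).
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_frames = 1360000L, dt_ps = 1,
                             target_tau_ns = 1.0,
                             mode_centers_deg = c(-100, 100),
                             mode_kappas = c(2, 2),
                             mode_weights = c(0.5, 0.5),
                             excluded_center_deg = 0,
                             excluded_width_deg = 60,
                             rot_step_rad = 0.015,
                             a_iso_rad_ns = 0.3,
                             a_aniso_rad_ns = 0.03,
                             g_eigen = c(2.0023, 2.0072, 2.0329),
                             g_omega_amp = 1,
                             seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory for synthetic generation")
  stopifnot(n_frames >= 2, dt_ps > 0, target_tau_ns > 0)
  if (excluded_width_deg <= 0 || excluded_width_deg >= 180)
    stop("excluded window width must lie in (0, 180) degrees")
  if (n_frames < 10 * target_tau_ns * 1000 / dt_ps)
    stop("trajectory must span at least 10 target correlation times")
  stopifnot(length(mode_centers_deg) == length(mode_kappas),
            length(mode_centers_deg) == length(mode_weights),
            all(mode_weights > 0), all(mode_kappas >= 0))
  structure(list(n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 target_tau_ns = target_tau_ns,
                 mode_centers_deg = mode_centers_deg,
                 mode_kappas = mode_kappas,
                 mode_weights = mode_weights / sum(mode_weights),
                 excluded_center_deg = excluded_center_deg,
                 excluded_width_deg = excluded_width_deg,
                 rot_step_rad = rot_step_rad,
                 a_iso_rad_ns = a_iso_rad_ns,
                 a_aniso_rad_ns = a_aniso_rad_ns,
                 g_eigen = g_eigen, g_omega_amp = g_omega_amp,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Stationary dihedral density on the 1-degree grid
#'
#' Von Mises mixture with a hard zero inside the excluded window,
#' normalized over the integer grid -180..179 degrees.
#'
#' @param params A [synthetic_params()].
#' @return List with `omega_deg` (-180..179) and normalized `density`.
#' @export
dihedral_density <- function(params) {
  om <- -180:179
  th <- om * pi / 180
  dens <- numeric(360)
  for (k in seq_along(params$mode_centers_deg)) {
    mu <- params$mode_centers_deg[k] * pi / 180
    dens <- dens + params$mode_weights[k] *
      exp(params$mode_kappas[k] * (cos(th - mu) - 1))
  }
  excl <- abs(wrap_angle(om - params$excluded_center_deg)) <
    params$excluded_width_deg / 2
  dens[excl] <- 0
  list(omega_deg = om, density = dens / sum(dens), excluded = excl)
}

#' Sample a dihedral-angle trajectory
#'
#' Metropolis random walk on the periodic 1-degree grid with
#' nearest-neighbor proposals and the stationary density of
#' [dihedral_density()] (hard zero in the excluded window). The number of
#' hop attempts per frame is calibrated by an automated pre-run so that the
#' measured effective correlation time of cos(Omega) hits the target; the
#' initial state is drawn from the stationary density, so the chain is
#' stationary from frame one.
#'
#' @param params A [synthetic_params()].
#' @param attempts_per_frame Skip calibration and use this attempt rate.
#' @param calib_frames Pre-run length for calibration (default 400,000, or
#'   the trajectory length if shorter).
#' @return A [scalar_series()] of angles in degrees, with attributes
#'   `attempts_per_frame` and `calibration` (data frame of pre-run history).
#' @export
sample_dihedral_trajectory <- function(params, attempts_per_frame = NULL,
                                       calib_frames = 400000L) {
  stopifnot(inherits(params, "synthetic_params"))
  dd <- dihedral_density(params)
  logd <- ifelse(dd$density > 0, log(dd$density), -Inf)
  tau_frames <- params$target_tau_ns * 1000 / params$dt_ps
  history <- NULL
  with_seed(params$seed, {
    if (is.null(attempts_per_frame)) {
      # The chain is diffusive, so attempts * tau is nearly constant. A
      # coarse pass (windowed integrated-autocorrelation estimator on a
      # short pre-run) brackets the rate; refinement pre-runs then use the
      # full trajectory length and the same covariance-fit estimator that
      # consumers of the trajectory use, so estimator bias cancels, with
      # updates averaging the measured attempts*tau product in log space.
      attempts <- 2 / (tau_frames * (pi / 180)^2 * 0.7)
      n_coarse <- as.integer(min(params$n_frames,
                                 max(calib_frames, 100 * tau_frames)))
      measure_once <- function(n, att, coarse) {
        start <- sample.int(360, 1, prob = dd$density)
        idx <- cpp_dihedral_metropolis(logd, n, att, start - 1L)
        x <- cos(dd$omega_deg[idx + 1L] * pi / 180)
        if (coarse) return(tau_int_windowed(x, params$dt_ps * 1e-3))
        span <- n * params$dt_ps * 1e-3
        cv <- series_covariance(scalar_series(x, params$dt_ps),
                                max_lag_ns = min(50, span / 4))
        effective_correlation_time(fit_cov_model(cv, min_span_ns = 0))
      }
      # fine measurements take the median of 3 independent trajectories:
      # single multiexponential fits are heavy-tailed
      measure <- function(n, att, coarse) {
        if (coarse) return(measure_once(n, att, TRUE))
        stats::median(vapply(1:3, function(k) measure_once(n, att, FALSE), 0))
      }
      for (it in 1:5) {
        if (attempts > 5000 || attempts < 0.02)
          stop(sprintf(paste0("calibration diverged: %.3g attempts/frame ",
                              "needed for target %.3g ns at this step/length\n%s"),
               attempts, params$target_tau_ns,
               paste(utils::capture.output(print(history)), collapse = "\n")))
        coarse <- it <= 2
        tau_hat <- measure(if (coarse) n_coarse else params$n_frames,
                           attempts, coarse)
        history <- rbind(history,
                         data.frame(iter = it, coarse = coarse,
                                    attempts = attempts,
                                    tau_hat_ns = tau_hat))
        fine <- history[!history$coarse, , drop = FALSE]
        src <- if (nrow(fine) >= 1) fine else history
        prod_hat <- exp(mean(log(src$attempts * src$tau_hat_ns)))
        attempts <- prod_hat / params$target_tau_ns
      }
      attempts_per_frame <- attempts
    }
    start <- sample.int(360, 1, prob = dd$density)
    idx <- cpp_dihedral_metropolis(logd, params$n_frames,
                                   attempts_per_frame, start - 1L)
    out <- scalar_series(dd$omega_deg[idx + 1L], params$dt_ps, "omega_deg")
    attr(out, "attempts_per_frame") <- attempts_per_frame
    attr(out, "calibration") <- history
    out
  })
}

#' Ensemble measurement of the dihedral correlation time
#'
#' Mirrors the ensemble design of the membrane analysis: several independent
#' dihedral trajectories (one per "lipid") are generated at the same
#' calibrated hop rate, the cos(Omega) autocovariance of each is fitted with
#' the 50-exponential model, and the per-trajectory effective correlation
#' times are combined. Combining effective times (rather than pooling
#' weights) follows the convention of reporting an ensemble effective time
#' over the radical population; the median is used as the location estimate
#' because single multiexponential fits have heavy-tailed noise, and the
#' plain mean is returned alongside.
#'
#' @param params A [synthetic_params()]; `params$seed + k` seeds replicate k.
#' @param replicates Number of independent trajectories (default 12, the
#'   radical count the analysis emulates).
#' @param attempts_per_frame Optional pre-calibrated hop rate; calibrated
#'   from `params` if NULL.
#' @param max_lag_ns Covariance lag span entering each fit (default 50).
#' @return List with `tau_median_ns`, `tau_mean_ns`, `tau_ns` (per
#'   replicate) and `attempts_per_frame`.
#' @export
measure_dihedral_tau <- function(params, replicates = 12,
                                 attempts_per_frame = NULL,
                                 max_lag_ns = 50) {
  stopifnot(inherits(params, "synthetic_params"))
  if (is.null(attempts_per_frame)) {
    tr <- sample_dihedral_trajectory(params)
    attempts_per_frame <- attr(tr, "attempts_per_frame")
  }
  span <- params$n_frames * params$dt_ps * 1e-3
  ml <- min(max_lag_ns, span / 4)
  taus <- vapply(seq_len(replicates), function(k) {
    pk <- params
    pk$seed <- params$seed + k
    trk <- sample_dihedral_trajectory(pk, attempts_per_frame = attempts_per_frame)
    s <- scalar_series(cos(trk$values * pi / 180), params$dt_ps, "cos_omega")
    effective_correlation_time(fit_cov_model(series_covariance(s, max_lag_ns = ml),
                                             min_span_ns = 0))
  }, 0)
  list(tau_median_ns = stats::median(taus), tau_mean_ns = mean(taus),
       tau_ns = taus, attempts_per_frame = attempts_per_frame)
}

#' Sample an isotropic orientation random walk
#'
#' Per frame the fragment rotates by a Gaussian angle of scale
#' `rot_step_rad` about a uniformly random axis; the long-run orientation
#' distribution is uniform on rotations.
#'
#' @param params A [synthetic_params()].
#' @param seed_offset Added to `params$seed` so the walk is independent of
#'   the dihedral chain (default 1).
#' @return An [orientation_trajectory()].
#' @export
sample_orientation_trajectory <- function(params, seed_offset = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$rot_step_rad >= pi / 2)
    stop("orientation step scale must be below 90 degrees per frame")
  q <- with_seed(params$seed + seed_offset,
                 cpp_orientation_walk(params$n_frames, params$rot_step_rad,
                                      c(1, 0, 0, 0)))
  orientation_trajectory(q, params$dt_ps)
}

#' Build a synthetic dihedral-to-tensor mapping table
#'
#' Fragment-frame tensors as functions of the dihedral angle: the hyperfine
#' tensor is a_iso * I plus an axial traceless part of amplitude
#' `a_aniso_rad_ns` whose principal frame rotates about the bond (x) axis
#' with Omega; the g-tensor is the fixed-eigenvalue tensor diag(g_eigen)
#' rotated the same way. Eigenvalues are therefore Omega-independent by
#' construction, and all lab-frame fluctuation comes from the dihedral
#' rotation plus fragment reorientation.
#'
#' @param params A [synthetic_params()].
#' @return A [mapping_table()] covering the non-excluded angles at 1 degree.
#' @export
make_synthetic_table <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  dd <- dihedral_density(params)
  keep <- which(!dd$excluded)
  om <- dd$omega_deg[keep]
  Aan <- diag(c(-params$a_aniso_rad_ns / 2, params$a_aniso_rad_ns,
                -params$a_aniso_rad_ns / 2))
  G <- diag(params$g_eigen)
  A <- matrix(0, length(om), 9)
  g <- matrix(0, length(om), 9)
  for (k in seq_along(om)) {
    th <- params$g_omega_amp * om[k] * pi / 180
    Rb <- matrix(c(1, 0, 0,
                   0, cos(th), -sin(th),
                   0, sin(th), cos(th)), 3, 3, byrow = TRUE)
    A[k, ] <- as.vector(t(params$a_iso_rad_ns * diag(3) + Rb %*% Aan %*% t(Rb)))
    g[k, ] <- as.vector(t(Rb %*% G %*% t(Rb)))
  }
  mapping_table(om, A, g)
}

#' Generate a complete synthetic dataset
#'
#' End-to-end fixture: dihedral and orientation trajectories, the synthetic
#' mapping table, the mapped lab-frame tensor trajectory and a manifest of
#' ground-truth parameters for recovery tests. With a directory argument
#' the bundle is written to disk (dihedral.tsv, orientation.tsv, table.txt,
#' tensors.txt, manifest.yaml).
#'
#' @param params A [synthetic_params()].
#' @param dir Optional output directory (created if needed).
#' @param map Also map tensors (default TRUE; FALSE skips the tensor
#'   trajectory when only the dihedral statistics are needed).
#' @return List of class `synthetic_bundle` with `dihedral`, `orientation`,
#'   `table`, `tensors` (or NULL) and `manifest`.
#' @export
make_synthetic_dataset <- function(params, dir = NULL, map = TRUE) {
  dihedral <- sample_dihedral_trajectory(params)
  orientation <- sample_orientation_trajectory(params)
  table <- make_synthetic_table(params)
  tensors <- if (map) map_trajectory(dihedral, orientation, table) else NULL
  manifest <- list(
    seed = params$seed,
    n_frames = params$n_frames,
    dt_ps = params$dt_ps,
    target_tau_ns = params$target_tau_ns,
    attempts_per_frame = as.numeric(attr(dihedral, "attempts_per_frame")),
    excluded_center_deg = params$excluded_center_deg,
    excluded_width_deg = params$excluded_width_deg,
    rot_step_rad = params$rot_step_rad,
    a_iso_rad_ns = params$a_iso_rad_ns,
    a_aniso_rad_ns = params$a_aniso_rad_ns,
    g_eigen = as.numeric(params$g_eigen))
  bundle <- structure(list(dihedral = dihedral, orientation = orientation,
                           table = table, tensors = tensors,
                           manifest = manifest),
                      class = "synthetic_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    n <- params$n_frames
    t_ps <- (seq_len(n) - 1) * params$dt_ps
    write.table(data.frame(t_ps = t_ps, omega_deg = dihedral$values),
                file.path(dir, "dihedral.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    qdf <- data.frame(t_ps = t_ps, qw = orientation$quat[, 1],
                      qx = orientation$quat[, 2], qy = orientation$quat[, 3],
                      qz = orientation$quat[, 4])
    write.table(format(qdf, digits = 12, trim = TRUE),
                file.path(dir, "orientation.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_mapping_table(table, file.path(dir, "table.txt"))
    if (!is.null(tensors))
      write_tensor_trajectory(tensors, file.path(dir, "tensors.txt"))
    write_manifest(manifest, file.path(dir, "manifest.yaml"))
  }
  bundle
}

#' Write / read a synthetic-dataset manifest
#'
#' @param manifest Named list of ground-truth generator parameters.
#' @param path File path (YAML).
#' @return `read_manifest()` returns the list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
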