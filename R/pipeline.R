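#' Field/lifetime scan configuration
#'
#' @param system A [spin_system()] (its `kST` and `B` are overridden per
#'   scan point) or the path of a spin-system YAML file.
#' @param relax A [relaxation_inputs()] or the path of a relaxation YAML
#'   file; may be NULL for purely static scans.
#' @param fields_mT Field grid in mT, positive increasing; default 60
#'   logarithmic points from 0.01 to 100 mT (resolving both the ~1 mT
#'   low-field region and the high-field decade).
#' @param kST_per_s Propagation rate constants in 1/s; the defaults span
#'   radical-pair lifetimes 1 ns to 10 us.
#' @param channel_sets Named list of channel subsets; each entry is a
#'   character vector drawn from c("hf", "g", "sr") (empty = static).
#' @param initial Initial electronic state for every point.
#' @param mode Spectral-density mode for the BRW channels.
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(system, relax = NULL,
                        fields_mT = 10^seq(log10(0.01), log10(100),
                                           length.out = 60),
                        kST_per_s = c(1e9, 1e8, 1e7, 3.16e6, 1e6, 1e5),
                        channel_sets = list(static = character(0),
                                            hf = "hf", g = "g", sr = "sr",
                                            all = c("hf", "g", "sr")),
                        initial = "triplet",
                        mode = "zero_frequency") {
  if (is.character(system)) system <- read_spin_system(system)
  stopifnot(inherits(system, "spin_system"))
  if (is.character(relax)) relax <- read_relaxation_config(relax)
  if (!is.null(relax)) stopifnot(inherits(relax, "relaxation_inputs"))
  fields_mT <- as.numeric(fields_mT)
  if (length(fields_mT) < 1 || any(fields_mT <= 0) || is.unsorted(fields_mT, strictly = TRUE))
    stop("field grid must be positive and strictly increasing")
  if (length(kST_per_s) < 1) stop("at least one kST is required")
  used <- unique(unlist(channel_sets))
  if (length(used) > 0 && is.null(relax))
    stop(sprintf("channel set(s) need relaxation inputs (%s) but none were supplied",
                 paste(used, collapse = ", ")))
  structure(list(system = system, relax = relax, fields_mT = fields_mT,
                 kST_per_s = kST_per_s, channel_sets = channel_sets,
                 initial = initial, mode = mode),
            class = "scan_config")
}

#' Run a triplet-yield field scan
#'
#' For every combination of field strength, propagation rate constant and
#' relaxation channel set, assembles the Liouvillian and computes the yield
#' breakdown by the exact Liouville-space solve; a zero-field reference
#' point is always included per (kST, channel set) series. The Hamiltonian
#' is linear in Bz at fixed tensors, and the g-fluctuation superoperator
#' scales exactly as Bz^2, so both are built once and rescaled per point.
#'
#' @param config A [scan_config()].
#' @param quiet Suppress per-series progress messages.
#' @return Object of class `field_scan`: a data frame of records
#'   (`Bz_mT`, `kST_per_s`, `channels`, `phi_T`, `phi_S_prop`,
#'   `phi_recomb`) with the config as attribute.
#' @export
run_field_scan <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  sys <- config$system
  ops <- build_spin_operators(sys)
  proj <- singlet_triplet_projectors(sys)
  if (ops$dim != nrow(proj$PS)) stop("inconsistent spin dimensions")
  H0 <- build_hamiltonian(sys, ops, B = c(0, 0, 0))
  Hz_unit <- build_hamiltonian(sys, ops, B = c(0, 0, 1)) - H0
  d2 <- ops$dim^2
  needs <- unique(unlist(config$channel_sets))
  Rhf <- if ("hf" %in% needs)
    hyperfine_redfield(config$relax, ops, H0, config$mode) else NULL
  Rsr <- if ("sr" %in% needs)
    spin_rotational_superoperator(
      spin_rotational_rate(config$relax$delta_g, config$relax$tau_omega_ns),
      ops) else NULL
  Rg_unit <- if ("g" %in% needs)
    g_redfield(config$relax, 1, ops, sys$constants, H0, config$mode) else NULL
  KS <- sys$kS * sop_anticomm_half(proj$PS)
  Idd <- diag(d2) + 0i
  rho0 <- initial_density(sys, proj, mode = config$initial)
  fields <- c(0, config$fields_mT)
  rows <- vector("list", 0)
  for (kst_s in config$kST_per_s) {
    kst <- rate_per_s_to_per_ns(kst_s)
    syspt <- sys; syspt$kST <- kst
    K <- KS + kst * Idd
    for (cs in names(config$channel_sets)) {
      set <- config$channel_sets[[cs]]
      if (!quiet)
        message(sprintf("scan: kST = %.3g /s, channels = %s",
                        kst_s, if (length(set)) paste(set, collapse = "+")
                               else "static"))
      Rfix <- list()
      if ("hf" %in% set) Rfix <- c(Rfix, list(Rhf))
      if ("sr" %in% set) Rfix <- c(Rfix, list(Rsr))
      for (Bz in fields) {
        H <- H0 + Bz * Hz_unit
        Rl <- Rfix
        if ("g" %in% set && Bz > 0) Rl <- c(Rl, list(Bz^2 * Rg_unit))
        L <- assemble_liouvillian(H, K, Rl)
        y <- channel_yields(L, rho0, syspt, proj)
        rows[[length(rows) + 1L]] <-
          data.frame(Bz_mT = Bz, kST_per_s = kst_s, channels = cs,
                     phi_T = y$phi_T, phi_S_prop = y$phi_S_prop,
                     phi_recomb = y$phi_recomb)
      }
    }
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("field_scan", "data.frame"), config = config)
}

#' Magnetic field effect metric
#'
#' Adds the MFE column delta_phi_T(B) = phi_T(B) - phi_T(0) per
#' (kST, channel set) series; the zero-field reference must be present.
#'
#' @param result A `field_scan`.
#' @return Data frame with the scan records plus `delta_phi_T`.
#' @export
mfe_metric <- function(result) {
  stopifnot(inherits(result, "field_scan"))
  df <- as.data.frame(result)
  key <- interaction(df$kST_per_s, df$channels, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(s) {
    ref <- s$phi_T[s$Bz_mT == 0]
    if (length(ref) != 1)
      stop("missing zero-field reference for a scan series")
    s$delta_phi_T <- s$phi_T - ref
    s
  }))
  rownames(out) <- NULL
  out[order(out$kST_per_s, out$channels, out$Bz_mT), , drop = FALSE]
}

#' @export
print.field_scan <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Field scan: %d records (%d fields x %d lifetimes x %d channel sets)\n",
              nrow(df), length(unique(df$Bz_mT)) - 1,
              length(unique(df$kST_per_s)),
              length(unique(df$channels))))
  cat("yield ranges by channel set:\n")
  for (cs in unique(df$channels)) {
    s <- df[df$channels == cs, ]
    cat(sprintf("  %-8s phi_T in [%.4f, %.4f]\n", cs,
                min(s$phi_T), max(s$phi_T)))
  }
  invisible(x)
}

#' @export
summary.field_scan <- function(object, ...) {
  m <- mfe_metric(object)
  agg <- do.call(rbind, lapply(
    split(m[m$Bz_mT > 0, ], interaction(m$kST_per_s[m$Bz_mT > 0],
                                        m$channels[m$Bz_mT > 0], drop = TRUE)),
    function(s) data.frame(kST_per_s = s$kST_per_s[1],
                           channels = s$channels[1],
                           phi_T_B0 = s$phi_T[1] - s$delta_phi_T[1],
                           max_delta = max(s$delta_phi_T),
                           min_delta = min(s$delta_phi_T),
                           B_at_extremum_mT = s$Bz_mT[which.max(abs(s$delta_phi_T))])))
  rownames(agg) <- NULL
  agg[order(agg$kST_per_s, agg$channels), ]
}

#' @export
plot.field_scan <- function(x, kST_per_s = NULL, ...) {
  df <- as.data.frame(x)
  if (is.null(kST_per_s)) kST_per_s <- df$kST_per_s[1]
  df <- df[df$kST_per_s == kST_per_s & df$Bz_mT > 0, ]
  sets <- unique(df$channels)
  cols <- seq_along(sets)
  graphics::plot(NA, xlim = range(df$Bz_mT), ylim = range(df$phi_T),
                 log = "x", xlab = "Bz (mT)", ylab = expression(Phi[T]),
                 main = sprintf("kST = %.3g /s", kST_per_s), ...)
  for (i in seq_along(sets)) {
    s <- df[df$channels == sets[i], ]
    graphics::lines(s$Bz_mT, s$phi_T, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = sets, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Write / read field-scan records
#'
#' Columnar TSV: Bz_mT, kST_per_s, channels_enabled, phi_T, phi_S_prop,
#' phi_recomb.
#'
#' @param result A `field_scan`.
#' @param path File path.
#' @return `read_field_scan()` returns a `field_scan` (without config).
#' @export
write_field_scan <- function(result, path) {
  df <- as.data.frame(result)
  names(df)[names(df) == "channels"] <- "channels_enabled"
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_scan
#' @export
read_field_scan <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  names(df)[names(df) == "channels_enabled"] <- "channels"
  structure(df, class = c("field_scan", "data.frame"))
}

#' Read a relaxation-input configuration file
#'
#' YAML layout: `tau_omega_ns`; `delta_g` (3 eigenvalue deviations);
#' `hyperfine` with `tau_ns` and `cov` (map from component-pair keys such as
#' "xx" or "xx:yy" to covariances in rad^2/ns^2; unlisted cross pairs
#' default to 0); `g_tensor` with `tau_ns` and `cov` over the \{zx, zy, zz\}
#' pairs. Both radicals receive the same models (the shipped reference
#' system is a symmetric pair).
#'
#' @param path File path.
#' @return A [relaxation_inputs()].
#' @export
read_relaxation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  expand_models <- function(block, keys) {
    cov <- block$cov
    models <- list()
    for (k in keys) {
      parts <- strsplit(k, ":")[[1]]
      a <- parts[1]; b <- parts[length(parts)]
      v <- cov[[k]]
      if (is.null(v) && a == b) v <- cov[[a]]
      if (is.null(v)) v <- 0
      models[[pair_key(a, b)]] <-
        cov_model_simple(as.numeric(v), as.numeric(block$tau_ns), c(a, b))
    }
    models
  }
  hf_keys <- apply(distinct_component_pairs(TRUE)[, 1:2], 1,
                   paste, collapse = ":")
  g_keys <- c("zx:zx", "zy:zy", "zz:zz", "zx:zy", "zx:zz", "zy:zz")
  hfm <- if (!is.null(cfg$hyperfine)) expand_models(cfg$hyperfine, hf_keys) else NULL
  gm <- if (!is.null(cfg$g_tensor)) expand_models(cfg$g_tensor, g_keys) else NULL
  relaxation_inputs(hf = list(hfm, hfm), g = list(gm, gm),
                    tau_omega_ns = as.numeric(cfg$tau_omega_ns),
                    delta_g = as.numeric(unlist(cfg$delta_g)))
}

#' Shipped reference radical pair
#'
#' Two peroxyl-like radicals, one spin-1/2 proton each with an isotropic
#' hyperfine coupling: the minimal system whose spin dynamics carries the
#' low-field effect and the high-field relaxation behavior of the membrane
#' radical pair. Loaded from the packaged configuration files.
#'
#' @param kST_per_s Propagation rate constant in 1/s (default 1e6, a 1 us
#'   lifetime).
#' @return List with `system` (a [spin_system()]) and `relax`
#'   (a [relaxation_inputs()]).
#' @export
reference_system <- function(kST_per_s = 1e6) {
  sysfile <- system.file("extdata", "reference_system.yaml",
                         package = "spinmfe", mustWork = TRUE)
  relfile <- system.file("extdata", "reference_relaxation.yaml",
                         package = "spinmfe", mustWork = TRUE)
  list(system = read_spin_system(sysfile, kST_per_s = kST_per_s),
       relax = read_relaxation_config(relfile))
}
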