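#' Mapping table: dihedral angle to fragment-frame tensors
#'
#' Tabulates, on a 1-degree grid over the sampled dihedral range, the
#' fragment-frame hyperfine tensor (rad/ns) and g-tensor of the radical as
#' functions of the peroxide-group dihedral angle. The grid may exclude the
#' window of angles the dynamics never samples.
#'
#' @param omega_deg Integer grid angles in degrees, within [-180, 179],
#'   strictly increasing, step resolution 1 degree.
#' @param A Matrix n x 9 of row-major hyperfine tensors (rad/ns); each row
#'   must be a symmetric tensor.
#' @param g Matrix n x 9 of row-major g-tensors.
#' @return Object of class `mapping_table`.
#' @export
mapping_table <- function(omega_deg, A, g) {
  omega_deg <- as.integer(round(omega_deg))
  A <- as.matrix(A); g <- as.matrix(g)
  stopifnot(ncol(A) == 9, ncol(g) == 9,
            nrow(A) == length(omega_deg), nrow(g) == length(omega_deg))
  if (any(duplicated(omega_deg)) || is.unsorted(omega_deg))
    stop("omega grid must be strictly increasing integers (1-degree steps)")
  if (!all(is.finite(A)) || !all(is.finite(g)))
    stop("tensor entries must be finite")
  asym <- abs(A[, c(2, 3, 6)] - A[, c(4, 7, 8)])
  if (max(asym) > 1e-8) stop("hyperfine table entries must be symmetric")
  structure(list(omega_deg = omega_deg, A = A, g = g),
            class = "mapping_table")
}

# Wrap an angle in degrees to [-180, 180).
wrap_angle <- function(x) ((x + 180) %% 360) - 180

# Nearest 1-degree grid angle with ties broken toward the lower angle.
nearest_grid_angle <- function(x) {
  r <- ceiling(wrap_angle(x) - 0.5)
  ifelse(r >= 180, r - 360L, r)
}

#' Look up fragment-frame tensors for a dihedral angle
#'
#' Nearest-grid-point lookup (ties toward the lower angle) after periodic
#' wrapping of the input angle. Angles falling in a window not covered by
#' the table are an error naming that window.
#'
#' @param omega Dihedral angle in degrees (any real value; wrapped).
#' @param table A [mapping_table()].
#' @return List with 3x3 matrices `A` (rad/ns) and `g`.
#' @export
lookup_tensors <- function(omega, table) {
  stopifnot(inherits(table, "mapping_table"), length(omega) == 1)
  key <- nearest_grid_angle(omega)
  i <- match(key, table$omega_deg)
  if (is.na(i)) {
    gaps <- setdiff(-180:179, table$omega_deg)
    stop(sprintf(
      "dihedral angle %.2f deg maps to %d deg, inside the excluded window [%d, %d] deg not covered by the table",
      omega, key, min(gaps), max(gaps)))
  }
  list(A = matrix(table$A[i, ], 3, 3, byrow = TRUE),
       g = matrix(table$g[i, ], 3, 3, byrow = TRUE))
}

# Vectorized table-row lookup used by map_trajectory().
lookup_rows <- function(omega, table) {
  keys <- nearest_grid_angle(omega)
  idx <- match(keys, table$omega_deg)
  if (anyNA(idx)) {
    gaps <- setdiff(-180:179, table$omega_deg)
    bad <- keys[which(is.na(idx))[1]]
    stop(sprintf(
      "dihedral angle %d deg lies in the excluded window [%d, %d] deg not covered by the table",
      bad, min(gaps), max(gaps)))
  }
  idx
}

#' Orientation trajectory (unit quaternions per frame)
#'
#' @param quat Matrix n x 4, columns (w, x, y, z); unit norm within 1e-8 and
#'   continuous (no frame-to-frame rotation above 90 degrees).
#' @param dt_ps Frame spacing in ps.
#' @return Object of class `orientation_trajectory`.
#' @export
orientation_trajectory <- function(quat, dt_ps = 1) {
  quat <- as.matrix(quat)
  stopifnot(ncol(quat) == 4, nrow(quat) >= 1)
  nrm <- sqrt(rowSums(quat^2))
  if (max(abs(nrm - 1)) > 1e-8) stop("quaternions must have unit norm")
  if (nrow(quat) > 1) {
    dots <- abs(rowSums(quat[-1, , drop = FALSE] *
                          quat[-nrow(quat), , drop = FALSE]))
    if (min(dots) < cos(pi / 4) - 1e-12)
      stop("orientation trajectory discontinuous: frame-to-frame rotation exceeds 90 degrees")
  }
  structure(list(quat = quat, dt_ps = dt_ps),
            class = "orientation_trajectory")
}

#' Rotation matrix of a unit quaternion (active convention)
#'
#' @param q Numeric length-4 (w, x, y, z).
#' @return 3x3 rotation matrix R with lab = R %*% frag %*% t(R).
#' @export
quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Map dihedral + orientation trajectories to lab-frame tensor trajectories
#'
#' Per frame, the fragment-frame tensors at the (nearest-grid) dihedral
#' angle are rotated into the lab frame as T_lab = R T_frag t(R), with R the
#' fragment rotation of that frame. Rotations preserve tensor eigenvalues,
#' so the mapping adds no fluctuation beyond table-entry changes and
#' reorientation.
#'
#' @param dihedral A [scalar_series()] of dihedral angles in degrees.
#' @param orientations An [orientation_trajectory()] with the same frame
#'   count, or NULL for identity orientations.
#' @param table A [mapping_table()].
#' @return Object of class `tensor_trajectory`: `A` and `g` are n x 9
#'   matrices of row-major lab-frame tensors, plus `dt_ps`.
#' @export
map_trajectory <- function(dihedral, orientations, table) {
  stopifnot(inherits(dihedral, "scalar_series"))
  n <- length(dihedral$values)
  if (is.null(orientations)) {
    quat <- cbind(rep(1, n), 0, 0, 0)
  } else {
    stopifnot(inherits(orientations, "orientation_trajectory"))
    quat <- orientations$quat
    if (nrow(quat) != n) stop("frame count mismatch between dihedral and orientation trajectories")
  }
  idx <- lookup_rows(dihedral$values, table)
  Alab <- cpp_rotate_tensor_trajectory(idx, quat, table$A)
  glab <- cpp_rotate_tensor_trajectory(idx, quat, table$g)
  structure(list(A = Alab, g = glab, dt_ps = dihedral$dt_ps),
            class = "tensor_trajectory")
}

#' Extract one tensor component as a scalar series
#'
#' @param traj A `tensor_trajectory`.
#' @param which "A" or "g".
#' @param component Two-letter component label, e.g. "xx", "zy".
#' @return A [scalar_series()].
#' @export
tensor_component_series <- function(traj, which = c("A", "g"), component) {
  which <- match.arg(which)
  labs <- component_labels()
  k <- match(component, labs)
  if (is.na(k)) stop("unknown tensor component label")
  scalar_series(traj[[which]][, k], dt_ps = traj$dt_ps,
                label = paste0(which, "_", component))
}

#' Read / write a mapping-table file
#'
#' Plain-text format: comment header lines (grid start/stop/step and units),
#' then one row per grid point with `omega_deg`, 9 hyperfine components
#' (rad/ns, row-major) and 9 g components (row-major).
#'
#' @param table A [mapping_table()] (for writing).
#' @param path File path.
#' @return `read_mapping_table()` returns the `mapping_table`.
#' @export
write_mapping_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mapping table: omega %d..%d deg, step 1 deg",
                       min(table$omega_deg), max(table$omega_deg)),
               "# columns: omega_deg, A[9] (rad/ns, row-major), g[9] (row-major)"),
             con)
  df <- cbind(table$omega_deg, table$A, table$g)
  write.table(format(df, digits = 12, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  df <- read.table(path, comment.char = "#")
  mapping_table(df[[1]], as.matrix(df[, 2:10]), as.matrix(df[, 11:19]))
}

#' Write a tensor trajectory file
#'
#' One row per frame: `t_ps`, 9 hyperfine components, 9 g components
#' (row-major lab-frame tensors).
#'
#' @param traj A `tensor_trajectory`.
#' @param path File path.
#' @export
write_tensor_trajectory <- function(traj, path) {
  n <- nrow(traj$A)
  df <- cbind((seq_len(n) - 1) * traj$dt_ps, traj$A, traj$g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: t_ps, A[9] (rad/ns), g[9]", con)
  write.table(format(df, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tensor_trajectory
#' @export
read_tensor_trajectory <- function(path) {
  df <- as.matrix(read.table(path, comment.char = "#"))
  dt <- if (nrow(df) > 1) df[2, 1] - df[1, 1] else 1
  structure(list(A = df[, 2:10, drop = FALSE], g = df[, 11:19, drop = FALSE],
                 dt_ps = dt),
            class = "tensor_trajectory")
}
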