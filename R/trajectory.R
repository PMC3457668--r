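#' Construct a coordinate trajectory
#'
#' A trajectory is an ordered set of frames of atomic coordinates with
#' per-frame times. Coordinates are stored as a `frames x atoms x 3` array;
#' times are in picoseconds, lengths in the unit recorded in `unit`
#' (Angstrom by default).
#'
#' @param coords numeric array of dimension `frames x atoms x 3`, or a list
#'   of `atoms x 3` matrices (one per frame).
#' @param times numeric vector of per-frame times in ps, strictly
#'   increasing. Exactly one of `times` and `frame_spacing_ps` must be
#'   given.
#' @param frame_spacing_ps uniform frame spacing in ps; times are then
#'   synthesized as `(0, dt, 2 dt, ...)`.
#' @param atom_labels character vector of per-atom identifiers (e.g. PDB
#'   atom names). Defaults to `"CA"` for every atom.
#' @param weights optional positive per-atom masses/weights used by
#'   downstream RMSD computations.
#' @param unit length-unit tag carried through to all derived quantities.
#' @return an object of class `md_trajectory`.
#' @seealso [read_trajectory()], [generate_ou_trajectory()]
#' @export
new_trajectory <- function(coords, times = NULL, frame_spacing_ps = NULL,
                           atom_labels = NULL, weights = NULL, unit = "A") {
  if (is.list(coords)) {
    n <- length(coords)
    if (n < 1L) stop("trajectory needs at least one frame")
    na <- nrow(coords[[1L]])
    for (i in seq_len(n)) {
      fr <- as.matrix(coords[[i]])
      if (ncol(fr) != 3L)
        stop("frame ", i, ": coordinates must have 3 columns")
      if (nrow(fr) != na)
        stop("frame ", i, ": atom count ", nrow(fr),
             " differs from frame 1 (", na, ")")
    }
    arr <- array(0, c(n, na, 3L))
    for (i in seq_len(n)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  n <- dim(coords)[1L]
  na <- dim(coords)[2L]
  if (na < 1L) stop("trajectory needs at least one atom")
  if (is.null(times)) {
    if (is.null(frame_spacing_ps))
      stop("either times or frame_spacing_ps must be given")
    if (!is.numeric(frame_spacing_ps) || length(frame_spacing_ps) != 1L ||
        frame_spacing_ps <= 0)
      stop("frame_spacing_ps must be a positive scalar")
    times <- (seq_len(n) - 1) * frame_spacing_ps
  }
  if (length(times) != n) stop("times must have one entry per frame")
  if (n > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(atom_labels)) atom_labels <- rep("CA", na)
  if (length(atom_labels) != na)
    stop("atom_labels must have one entry per atom")
  if (!is.null(weights)) {
    if (length(weights) != na) stop("weights must have one entry per atom")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be positive and finite")
  }
  structure(list(coords = coords, times = as.numeric(times),
                 atom_labels = as.character(atom_labels),
                 weights = weights, unit = unit),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$coords)[1L], "frames,",
      dim(x$coords)[2L], "atoms\n")
  cat("  times:", format(x$times[1L]), "..",
      format(x$times[length(x$times)]), "ps;  unit:", x$unit, "\n")
  if (!is.null(x$weights)) cat("  per-atom weights set\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1L]
n_atoms <- function(traj) dim(traj$coords)[2L]

## frames x (3 N) view; columns ordered x1..xN, y1..yN, z1..zN so that
## matrix(X[i, ], N, 3) reproduces coords[i, , ] exactly.
flatten_coords <- function(traj) {
  d <- dim(traj$coords)
  matrix(traj$coords, d[1L], d[2L] * 3L)
}

## check declared-uniform spacing; returns the spacing
frame_spacing <- function(times) {
  if (length(times) < 2L) return(NA_real_)
  dts <- diff(times)
  med <- median(dts)
  if (max(abs(dts - med)) > 1e-6 * med)
    stop("frame times are not uniformly spaced (needed for lag analysis)")
  med
}

#' Construct an all-vs-all RMSD matrix object
#'
#' @param values square symmetric nonnegative matrix of configuration
#'   distances with zero diagonal; asymmetries up to `1e-9` relative are
#'   tolerated (and symmetrized), larger ones are an error.
#' @param times per-frame times in ps, strictly increasing.
#' @param unit length-unit tag (same unit as the coordinates the values
#'   were computed from).
#' @return an object of class `rmsd_matrix_obj`.
#' @seealso [rmsd_matrix()], [read_rmsd_matrix()]
#' @export
new_rmsd_matrix <- function(values, times, unit = "A") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("RMSD matrix must be square")
  if (length(times) != n) stop("times must have one entry per frame")
  if (n > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("RMSD matrix contains non-finite entries")
  if (any(values < 0)) stop("RMSD matrix entries must be nonnegative")
  scale <- max(values, 1e-300)
  if (max(abs(values - t(values))) > 1e-9 * scale)
    stop("RMSD matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > 1e-9 * max(scale, 1))
    stop("RMSD matrix diagonal must be zero")
  diag(values) <- 0
  structure(list(values = values, times = as.numeric(times), unit = unit),
            class = "rmsd_matrix_obj")
}

#' @export
print.rmsd_matrix_obj <- function(x, ...) {
  cat("rmsd_matrix:", nrow(x$values), "x", ncol(x$values),
      "frames;  unit:", x$unit, "\n")
  cat("  max pairwise RMSD:", format(max(x$values)), "\n")
  invisible(x)
}
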