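## normalized per-atom weights (sum to 1); default uniform
norm_weights <- function(weights, na) {
  if (is.null(weights)) return(NULL)
  if (length(weights) != na) stop("weights must have one entry per atom")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  weights / sum(weights)
}

## weighted mean squared deviation summed column-major, matching the
## accumulation order used by the streaming lag path (bit-for-bit)
pair_msd <- function(d, wn) {
  if (is.null(wn)) sum(d * d) / nrow(d) else sum(wn * (d * d))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1; reflections excluded) and
#' translation minimizing the weighted mean squared deviation of `mobile`
#' from `reference`. For fewer than 3 non-collinear atoms the rotation is
#' not unique and the SVD solution is returned as the best-found rotation.
#'
#' @param reference,mobile `atoms x 3` coordinate matrices with equal atom
#'   counts.
#' @param weights optional positive per-atom weights (normalized
#'   internally).
#' @return an object of class `superposition`: list with `rotation` (3x3,
#'   orthogonal, det +1), `translation` (length-3; the aligned mobile is
#'   `mobile %*% t(rotation) + translation`) and `rmsd_after`.
#' @export
kabsch <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)))
    stop("atom counts differ: ", nrow(reference), " vs ", nrow(mobile))
  na <- nrow(reference)
  if (na < 1L) stop("need at least one atom")
  wn <- norm_weights(weights, na)
  wv <- if (is.null(wn)) rep(1 / na, na) else wn
  cr <- colSums(reference * wv)
  cm <- colSums(mobile * wv)
  A <- sweep(reference, 2L, cr)
  B <- sweep(mobile, 2L, cm)
  H <- crossprod(B * wv, A)            # 3x3 weighted cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  resid <- A - B %*% t(R)
  rmsd_after <- sqrt(max(0, pair_msd(resid, wn)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd_after = rmsd_after),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: rmsd_after =", format(x$rmsd_after), "\n")
  invisible(x)
}

#' RMSD between two configurations
#'
#' Root mean square deviation
#' \deqn{\mathrm{RMSD} = \left[\frac{1}{N}\sum_{i=1}^{N}
#'   \lVert x_i^{(b)} - x_i^{(a)}\rVert^2\right]^{1/2}}
#' optionally after weighted Kabsch superposition of `frame_b` onto
#' `frame_a`. With weights, both the superposition and the mean use
#' normalized weights. The RMSD of a configuration to itself is zero by
#' definition; the aligned path short-circuits identical frames so that
#' rotation round-off cannot surface as a spurious nonzero self-distance.
#'
#' @param frame_a,frame_b `atoms x 3` coordinate matrices.
#' @param align superpose `frame_b` onto `frame_a` first (default); with
#'   `align = FALSE` the raw definition above is evaluated as printed.
#' @param weights optional positive per-atom weights.
#' @return nonnegative scalar in the coordinate unit.
#' @export
rmsd_pair <- function(frame_a, frame_b, align = TRUE, weights = NULL) {
  frame_a <- as.matrix(frame_a)
  frame_b <- as.matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("atom counts differ: ", nrow(frame_a), " vs ", nrow(frame_b))
  if (nrow(frame_a) < 1L) stop("need at least one atom")
  if (align) {
    if (identical(dim(frame_a), dim(frame_b)) && all(frame_a == frame_b))
      return(0)
    kabsch(frame_a, frame_b, weights)$rmsd_after
  } else {
    wn <- norm_weights(weights, nrow(frame_a))
    sqrt(pair_msd(frame_b - frame_a, wn))
  }
}

#' All-vs-all RMSD matrix of a trajectory
#'
#' Computes `rmsd_pair()` for every unordered frame pair. Each pair is
#' evaluated once and mirrored, so the result is exactly symmetric with a
#' zero diagonal. Without alignment the computation is vectorized one
#' reference frame at a time (bounded memory independent of `n`), and
#' every entry is bit-identical to the corresponding `rmsd_pair()` call.
#'
#' @param traj an [new_trajectory()] object with at least 2 frames.
#' @param align superpose every pair before the deviation (default).
#' @param weights optional per-atom weights; defaults to `traj$weights`.
#' @return an [new_rmsd_matrix()] object.
#' @export
rmsd_matrix <- function(traj, align = TRUE, weights = traj$weights) {
  n <- n_frames(traj)
  na <- n_atoms(traj)
  if (n < 2L) stop("need at least 2 frames")
  vals <- matrix(0, n, n)
  if (align) {
    for (i in seq_len(n - 1L)) {
      fi <- traj$coords[i, , , drop = TRUE]
      if (na == 1L) fi <- matrix(fi, 1L, 3L)
      for (j in (i + 1L):n) {
        fj <- traj$coords[j, , , drop = TRUE]
        if (na == 1L) fj <- matrix(fj, 1L, 3L)
        v <- rmsd_pair(fi, fj, align = TRUE, weights = weights)
        vals[i, j] <- v
        vals[j, i] <- v
      }
    }
  } else {
    X <- flatten_coords(traj)
    wn <- norm_weights(weights, na)
    wflat <- if (is.null(wn)) NULL else rep(wn, 3L)
    for (i in seq_len(n - 1L)) {
      m <- n - i
      d <- X[(i + 1L):n, , drop = FALSE] -
        matrix(X[i, ], m, ncol(X), byrow = TRUE)
      e <- d * d
      row <- if (is.null(wflat)) sqrt(rowSums(e) / na)
             else sqrt(rowSums(e * rep(wflat, each = m)))
      vals[(i + 1L):n, i] <- row
      vals[i, (i + 1L):n] <- row
    }
  }
  new_rmsd_matrix(vals, times = traj$times, unit = traj$unit)
}

#' Reference-configuration RMSD curves
#'
#' For each frame, the mean RMSD to all other frames is computed. The
#' frame maximizing that mean is the "maximum outlier" ever seen in the
#' trajectory; the frame minimizing it is the "most central"
#' configuration. The RMSD curves of every frame against the first, the
#' maximum-outlier and the most-central reference are returned; each curve
#' is zero at its own reference frame. Ties are broken towards the
#' smallest frame index.
#'
#' @param matrix an [new_rmsd_matrix()] object with at least 2 frames.
#' @return an object of class `reference_curves`: list with
#'   `per_frame_mean`, `idx_max`, `idx_min` (1-based frame indices),
#'   `curve_first`, `curve_max`, `curve_min` and `times`.
#' @export
reference_curves <- function(matrix) {
  v <- matrix$values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 frames")
  per_frame_mean <- colSums(v) / (n - 1L)
  idx_max <- which.max(per_frame_mean)
  idx_min <- which.min(per_frame_mean)
  structure(list(per_frame_mean = per_frame_mean,
                 idx_max = idx_max, idx_min = idx_min,
                 curve_first = v[1L, ], curve_max = v[idx_max, ],
                 curve_min = v[idx_min, ], times = matrix$times),
            class = "reference_curves")
}

#' @export
print.reference_curves <- function(x, ...) {
  cat("reference_curves over", length(x$per_frame_mean), "frames\n")
  cat("  maximum outlier: frame", x$idx_max,
      "(mean RMSD", format(x$per_frame_mean[x$idx_max]), ")\n")
  cat("  most central:    frame", x$idx_min,
      "(mean RMSD", format(x$per_frame_mean[x$idx_min]), ")\n")
  invisible(x)
}
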