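#' Build a dense-then-sparse lag schedule
#'
#' The schedule places an arithmetic head of closely spaced lags over the
#' initial rise of the lagged-RMSD curve, followed by a geometric tail up
#' to the maximum admissible lag of half the analysis window. Sampling the
#' initial phase densely puts increased weight on those points in the
#' subsequent (unweighted) Hill fit; the long-lag plateau still anchors
#' the fit through the geometric tail.
#'
#' @param window_frames number of frames in the analysis window (>= 4).
#' @param dense_upto largest lag (in frames) of the arithmetic head; must
#'   be below `floor(window_frames / 2)`. Default: 5\% of the window
#'   (at least one step).
#' @param dense_step arithmetic step of the head, in frames.
#' @param sparse_count number of geometrically spaced lags between
#'   `dense_upto` and `floor(window_frames / 2)`.
#' @return an object of class `lag_schedule`: list with strictly
#'   increasing integer `lag_indices` (always ending at
#'   `floor(window_frames / 2)`) and `window_frames`.
#' @export
build_lag_schedule <- function(window_frames, dense_upto = NULL,
                               dense_step = 1L, sparse_count = 40L) {
  if (!is.numeric(window_frames) || window_frames < 4L)
    stop("window too small: need window_frames >= 4, got ", window_frames)
  window_frames <- as.integer(window_frames)
  half <- window_frames %/% 2L
  if (is.null(dense_upto))
    dense_upto <- max(dense_step, min(half - 1L,
                                      floor(0.05 * window_frames)))
  dense_upto <- as.integer(dense_upto)
  dense_step <- as.integer(dense_step)
  sparse_count <- as.integer(sparse_count)
  if (dense_step < 1L) stop("dense_step must be >= 1")
  if (sparse_count < 1L) stop("sparse_count must be >= 1")
  if (dense_upto >= half)
    stop("dense_upto must be below floor(window_frames / 2) = ", half)
  dense <- if (dense_upto >= dense_step)
    seq.int(dense_step, dense_upto, by = dense_step) else integer(0)
  lo <- max(dense_upto, 1L)
  sparse <- unique(as.integer(round(exp(
    seq(log(lo), log(half), length.out = sparse_count + 1L)))))
  lags <- sort(unique(c(dense, sparse, half)))
  lags <- lags[lags >= 1L & lags <= half]
  if (length(lags) == 0L) stop("schedule parameters produce no lags")
  structure(list(lag_indices = lags, window_frames = window_frames),
            class = "lag_schedule")
}

#' @export
print.lag_schedule <- function(x, ...) {
  cat("lag_schedule:", length(x$lag_indices), "lags over a",
      x$window_frames, "frame window (max lag",
      max(x$lag_indices), "frames)\n")
  invisible(x)
}

## analysis-window frame indices for a given start offset, shared by the
## matrix and streaming paths
lag_window <- function(times, t_offset_ps) {
  if (t_offset_ps < 0) stop("t_offset_ps must be nonnegative")
  rel <- times - times[1L]
  t_max <- rel[length(rel)]
  if (t_offset_ps > t_max / 2 + 1e-9 * max(t_max, 1))
    stop("t_offset_ps = ", t_offset_ps,
         " is beyond half the trajectory (t_max/2 = ", t_max / 2, ")")
  idx <- which(rel >= t_offset_ps - 1e-9 * max(t_max, 1))
  if (length(idx) < 4L)
    stop("window too small: only ", length(idx),
         " frames at t_offset_ps = ", t_offset_ps)
  idx
}

new_lag_curve <- function(lags_ps, mean_rmsd, sd_rmsd, n_pairs,
                          t_offset_ps, unit, lag_indices, window_frames) {
  structure(list(lags_ps = lags_ps, mean_rmsd = mean_rmsd,
                 sd_rmsd = sd_rmsd, n_pairs = n_pairs,
                 t_offset_ps = t_offset_ps, unit = unit,
                 lag_indices = lag_indices, window_frames = window_frames),
            class = "lag_curve")
}

#' Mean RMSD as a function of time lag
#'
#' For every lag `k` of the schedule, averages the RMSD over *all* frame
#' pairs `(i, i + k)` whose first member lies at or after `t_offset_ps`
#' (so `n_pairs = window_frames - k` at each lag). The input may be a
#' precomputed [rmsd_matrix()] or a trajectory; the streaming trajectory
#' path never materializes the full matrix and produces bit-identical
#' means for unaligned RMSD. Frame times must be uniformly spaced.
#'
#' @param x an [new_rmsd_matrix()] or [new_trajectory()] object.
#' @param schedule a [build_lag_schedule()] for the analysis window;
#'   defaults to the standard schedule of that window.
#' @param t_offset_ps start of the analysis window in ps (relative to the
#'   first frame); must not exceed half the trajectory duration.
#' @param align for trajectory input: superpose each pair (slow; loops
#'   over pairs). Default `FALSE`, the vectorized raw-deviation path.
#' @param weights for trajectory input: optional per-atom weights;
#'   defaults to the trajectory's own.
#' @return an object of class `lag_curve`: list with `lags_ps`,
#'   `mean_rmsd`, `sd_rmsd`, `n_pairs`, `t_offset_ps`, `unit`.
#' @export
lagged_mean_rmsd <- function(x, schedule = NULL, t_offset_ps = 0,
                             align = FALSE, weights = NULL) {
  UseMethod("lagged_mean_rmsd")
}

lag_curve_from_values <- function(value_fn, times, idx, schedule,
                                  t_offset_ps, unit) {
  W <- length(idx)
  dt <- frame_spacing(times)
  if (is.null(schedule)) schedule <- build_lag_schedule(W)
  lags <- schedule$lag_indices
  if (max(lags) > W %/% 2L)
    stop("schedule max lag ", max(lags),
         " exceeds half the analysis window (", W %/% 2L, " frames)")
  means <- sds <- numeric(length(lags))
  for (j in seq_along(lags)) {
    vals <- value_fn(lags[j])
    means[j] <- mean(vals)
    sds[j] <- if (length(vals) > 1L) sd(vals) else NA_real_
  }
  new_lag_curve(lags_ps = lags * dt, mean_rmsd = means, sd_rmsd = sds,
                n_pairs = W - lags, t_offset_ps = t_offset_ps, unit = unit,
                lag_indices = lags, window_frames = W)
}

#' @rdname lagged_mean_rmsd
#' @export
lagged_mean_rmsd.rmsd_matrix_obj <- function(x, schedule = NULL,
                                             t_offset_ps = 0, align = FALSE,
                                             weights = NULL) {
  idx <- lag_window(x$times, t_offset_ps)
  W <- length(idx)
  lag_curve_from_values(function(k) {
    i <- idx[seq_len(W - k)]
    x$values[cbind(i, i + k)]
  }, x$times, idx, schedule, t_offset_ps, x$unit)
}

#' @rdname lagged_mean_rmsd
#' @export
lagged_mean_rmsd.md_trajectory <- function(x, schedule = NULL,
                                           t_offset_ps = 0, align = FALSE,
                                           weights = NULL) {
  if (is.null(weights)) weights <- x$weights
  idx <- lag_window(x$times, t_offset_ps)
  W <- length(idx)
  na <- n_atoms(x)
  if (align) {
    value_fn <- function(k) {
      vapply(seq_len(W - k), function(p) {
        fi <- matrix(x$coords[idx[p], , ], na, 3L)
        fj <- matrix(x$coords[idx[p] + k, , ], na, 3L)
        rmsd_pair(fi, fj, align = TRUE, weights = weights)
      }, numeric(1L))
    }
  } else {
    X <- flatten_coords(x)[idx, , drop = FALSE]
    wn <- norm_weights(weights, na)
    wflat <- if (is.null(wn)) NULL else rep(wn, 3L)
    value_fn <- function(k) {
      m <- W - k
      d <- X[(k + 1L):W, , drop = FALSE] - X[seq_len(m), , drop = FALSE]
      e <- d * d
      if (is.null(wflat)) sqrt(rowSums(e) / na)
      else sqrt(rowSums(e * rep(wflat, each = m)))
    }
  }
  lag_curve_from_values(value_fn, x$times, idx, schedule, t_offset_ps,
                        x$unit)
}

#' @export
print.lag_curve <- function(x, ...) {
  cat("lag_curve at t_offset =", x$t_offset_ps, "ps:",
      length(x$lags_ps), "lags,",
      "window", x$window_frames, "frames\n")
  cat("  mean RMSD range:", format(min(x$mean_rmsd)), "..",
      format(max(x$mean_rmsd)), x$unit, "\n")
  invisible(x)
}

#' @export
as.data.frame.lag_curve <- function(x, ...) {
  data.frame(lag_ps = x$lags_ps, mean_rmsd = x$mean_rmsd,
             sd_rmsd = x$sd_rmsd, n_pairs = x$n_pairs,
             t_offset_ps = x$t_offset_ps)
}

#' Plot a lagged-RMSD curve and optional Hill fit
#'
#' @param x a `lag_curve`.
#' @param fit optional [fit_hill()] result drawn as a solid line, with
#'   horizontal/vertical guides at the fitted plateau and half-saturation
#'   lag.
#' @param ... passed to [plot()].
#' @export
plot.lag_curve <- function(x, fit = NULL, ...) {
  plot(x$lags_ps, x$mean_rmsd, pch = 1, col = "red3",
       xlab = expression(Delta * t ~ "(ps)"),
       ylab = paste0("mean RMSD (", x$unit, ")"), ...)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    dd <- seq(0, max(x$lags_ps), length.out = 300L)
    lines(dd, hill_eval(fit$a, fit$tau, fit$gamma, dd))
    abline(h = fit$a, lty = 2)
    abline(v = fit$tau, lty = 2)
  }
  invisible(x)
}
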