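new_offset_sweep <- function(offsets_ps, fits, curves, unit,
                             decay = NULL, verdict = NULL,
                             verdict_metrics = NULL) {
  structure(list(offsets_ps = offsets_ps, fits = fits, curves = curves,
                 unit = unit, decay = decay, verdict = verdict,
                 verdict_metrics = verdict_metrics),
            class = "offset_sweep")
}

#' Repeat the lag analysis and Hill fit over an offset grid
#'
#' Offsets are evenly spaced on `[0, t_max/2]` (inclusive endpoints),
#' where `t_max` is the trajectory duration. For each offset the lag
#' schedule is rebuilt on the remaining window (so the maximum lag is
#' half the *windowed* frame count), the lagged-RMSD curve is computed
#' and the Hill model fitted. Failed fits are retained with
#' `converged = FALSE` so the sweep always has one entry per offset.
#'
#' @param x an [new_rmsd_matrix()] or [new_trajectory()] object.
#' @param n_offsets number of offsets (>= 4).
#' @param schedule_args list of arguments (`dense_upto`, `dense_step`,
#'   `sparse_count`) passed to [build_lag_schedule()] per window.
#' @param align,weights passed to [lagged_mean_rmsd()] for trajectory
#'   input.
#' @param weighted_fit passed to [fit_hill()].
#' @return an object of class `offset_sweep` with `offsets_ps`, `fits`
#'   (list of `hill_fit`), `curves` (list of `lag_curve`), and empty
#'   `decay`/`verdict` slots (see [extrapolate_plateau()],
#'   [assess_stationarity()]).
#' @export
sweep_offsets <- function(x, n_offsets = 11L, schedule_args = list(),
                          align = FALSE, weights = NULL,
                          weighted_fit = FALSE) {
  if (n_offsets < 4L) stop("need n_offsets >= 4, got ", n_offsets)
  times <- x$times
  rel <- times - times[1L]
  t_max <- rel[length(rel)]
  offsets <- seq(0, t_max / 2, length.out = n_offsets)
  last_window <- sum(rel >= offsets[n_offsets] - 1e-9 * max(t_max, 1))
  if (last_window < 8L)
    stop("trajectory too short: largest offset window retains ",
         last_window, " frames (need >= 8)")
  fits <- vector("list", n_offsets)
  curves <- vector("list", n_offsets)
  for (i in seq_len(n_offsets)) {
    res <- tryCatch({
      idx <- lag_window(times, offsets[i])
      schedule <- do.call(build_lag_schedule,
                          c(list(window_frames = length(idx)),
                            schedule_args))
      curve <- lagged_mean_rmsd(x, schedule = schedule,
                                t_offset_ps = offsets[i], align = align,
                                weights = weights)
      list(curve = curve, fit = fit_hill(curve, weighted = weighted_fit))
    }, error = function(e)
      list(curve = NULL,
           fit = new_hill_fit(converged = FALSE,
                              diagnostics = conditionMessage(e))))
    curves[[i]] <- res$curve
    fits[[i]] <- res$fit
  }
  new_offset_sweep(offsets, fits, curves, unit = x$unit)
}

converged_idx <- function(sweep) {
  which(vapply(sweep$fits, function(f) isTRUE(f$converged), logical(1L)))
}

#' @export
as.data.frame.offset_sweep <- function(x, ...) {
  tab <- do.call(rbind, lapply(x$fits, as.data.frame))
  cbind(data.frame(t_offset_ps = x$offsets_ps), tab)
}

#' Extrapolate the fitted plateau to infinite offset
#'
#' Fits the monoexponential decay [exp_offset_eval()] to the
#' `(t_offset, a)` pairs of the converged Hill fits of a sweep, weighting
#' by the plateaus' asymptotic standard errors when all are finite. The
#' resulting `a0` estimates the RMSD between two totally unrelated
#' configurations of the visited phase-space region, free of
#' initial-phase bias.
#'
#' @param sweep a [sweep_offsets()] result with at least 4 converged
#'   fits.
#' @param weighted use `se_a`-based inverse-variance weights when
#'   available (default).
#' @return an `offset_decay_fit` (see [fit_offset_decay()]).
#' @export
extrapolate_plateau <- function(sweep, weighted = TRUE) {
  conv <- converged_idx(sweep)
  if (length(conv) < 4L)
    stop("need at least 4 converged Hill fits, got ", length(conv))
  a <- vapply(sweep$fits[conv], `[[`, numeric(1L), "a")
  se <- vapply(sweep$fits[conv], `[[`, numeric(1L), "se_a")
  ses <- if (weighted && all(is.finite(se)) && all(se > 0)) se else NULL
  fit_offset_decay(sweep$offsets_ps[conv], a, plateau_ses = ses)
}

#' Stationarity verdict for an offset sweep
#'
#' Operational test of whether the lagged-RMSD curve's fitted parameters
#' have stopped changing with the offset: over the final `tail_fraction`
#' of the converged fits, the maximum relative deviation of the plateau
#' `a` and of the half-saturation lag `tau` from their tail medians is
#' computed. The verdict is `"stationary"` iff both drifts are below
#' `rel_tol`, `"not_stationary"` if either reaches it, and
#' `"indeterminate"` whenever fewer than 4 fits converged. Metrics are
#' always reported alongside the verdict.
#'
#' @param sweep a [sweep_offsets()] result.
#' @param rel_tol relative drift tolerance (default 0.05).
#' @param tail_fraction fraction of converged fits forming the assessed
#'   tail (default 0.5).
#' @return list with `verdict` and `metrics` (`rel_drift_a`,
#'   `rel_drift_tau`, `n_converged`, `rel_tol`, `tail_fraction`).
#' @export
assess_stationarity <- function(sweep, rel_tol = 0.05,
                                tail_fraction = 0.5) {
  if (rel_tol <= 0) stop("rel_tol must be positive")
  conv <- converged_idx(sweep)
  metrics <- list(rel_drift_a = NA_real_, rel_drift_tau = NA_real_,
                  n_converged = length(conv), rel_tol = rel_tol,
                  tail_fraction = tail_fraction)
  if (length(conv) >= 2L) {
    a <- vapply(sweep$fits[conv], `[[`, numeric(1L), "a")
    tau <- vapply(sweep$fits[conv], `[[`, numeric(1L), "tau")
    nt <- max(2L, ceiling(tail_fraction * length(conv)))
    tl <- seq.int(length(conv) - nt + 1L, length(conv))
    drift <- function(v) {
      med <- median(v[tl])
      max(abs(v[tl] - med)) / med
    }
    metrics$rel_drift_a <- drift(a)
    metrics$rel_drift_tau <- drift(tau)
  }
  verdict <- if (length(conv) < 4L) "indeterminate"
  else if (metrics$rel_drift_a < rel_tol &&
           metrics$rel_drift_tau < rel_tol) "stationary"
  else "not_stationary"
  list(verdict = verdict, metrics = metrics)
}

#' Full convergence analysis of a trajectory or RMSD matrix
#'
#' Runs [sweep_offsets()], attaches the plateau extrapolation
#' ([extrapolate_plateau()]; skipped with a note when fewer than 4 fits
#' converge) and the stationarity verdict ([assess_stationarity()]).
#'
#' @inheritParams sweep_offsets
#' @inheritParams assess_stationarity
#' @return a completed `offset_sweep` with `decay`, `verdict` and
#'   `verdict_metrics` filled in.
#' @export
analyze_convergence <- function(x, n_offsets = 11L, schedule_args = list(),
                                align = FALSE, weights = NULL,
                                weighted_fit = FALSE, rel_tol = 0.05,
                                tail_fraction = 0.5) {
  sweep <- sweep_offsets(x, n_offsets = n_offsets,
                         schedule_args = schedule_args, align = align,
                         weights = weights, weighted_fit = weighted_fit)
  sweep$decay <- tryCatch(extrapolate_plateau(sweep),
                          error = function(e)
                            new_offset_decay_fit(converged = FALSE,
                                                 diagnostics = conditionMessage(e)))
  assessment <- assess_stationarity(sweep, rel_tol = rel_tol,
                                    tail_fraction = tail_fraction)
  sweep$verdict <- assessment$verdict
  sweep$verdict_metrics <- assessment$metrics
  sweep
}

#' @export
print.offset_sweep <- function(x, ...) {
  nc <- length(converged_idx(x))
  cat("offset_sweep:", length(x$offsets_ps), "offsets on [0, ",
      format(max(x$offsets_ps)), "] ps;", nc, "converged fits\n")
  if (!is.null(x$verdict)) {
    cat("  verdict:", x$verdict, "\n")
    m <- x$verdict_metrics
    cat(sprintf("  tail drifts: a %.3g, tau %.3g (tol %.3g)\n",
                m$rel_drift_a, m$rel_drift_tau, m$rel_tol))
  }
  if (!is.null(x$decay) && isTRUE(x$decay$converged))
    cat(sprintf("  extrapolated plateau a0 = %.6g %s\n", x$decay$a0,
                x$unit))
  invisible(x)
}

#' Plot fitted plateau versus offset with its decay fit
#'
#' @param x an `offset_sweep`.
#' @param ... passed to [plot()].
#' @export
plot.offset_sweep <- function(x, ...) {
  conv <- converged_idx(x)
  a <- vapply(x$fits[conv], `[[`, numeric(1L), "a")
  se <- vapply(x$fits[conv], `[[`, numeric(1L), "se_a")
  off <- x$offsets_ps[conv]
  plot(off, a, pch = 19, col = "red3",
       xlab = expression(t[offset] ~ "(ps)"),
       ylab = paste0("fitted plateau a (", x$unit, ")"), ...)
  if (all(is.finite(se)))
    arrows(off, a - se, off, a + se, angle = 90, code = 3,
           length = 0.03, col = "red3")
  if (!is.null(x$decay) && isTRUE(x$decay$converged)) {
    tt <- seq(0, max(off), length.out = 300L)
    lines(tt, exp_offset_eval(x$decay$a0, x$decay$beta,
                              max(x$decay$lam, 1e-12), tt), col = "blue3")
    abline(h = x$decay$a0, col = "blue3", lty = 2)
  }
  invisible(x)
}
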