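#' Evaluate the Hill saturation model
#'
#' \deqn{f(\Delta t) = \frac{a\,\Delta t^{\gamma}}
#'   {\tau^{\gamma} + \Delta t^{\gamma}}}
#' where `a` is the plateau the curve is asymptotic to, `tau` the lag at
#' which half-saturation `f(tau) = a/2` is reached, and `gamma` the Hill
#' coefficient setting the level of sigmoidicity. Internally the
#' algebraically equivalent form `a / (1 + (tau/dt)^gamma)` is used for
#' `dt > 0`: it makes the half-saturation identity exact in floating
#' point and cannot overflow for large `gamma`. `f(0) = 0`.
#'
#' @param a,tau,gamma positive scalars (plateau, half-saturation lag in
#'   ps, Hill coefficient).
#' @param dt nonnegative lag(s) in ps; vectorized.
#' @return nonnegative value(s) of the model.
#' @export
hill_eval <- function(a, tau, gamma, dt) {
  for (p in c(a = a, tau = tau, gamma = gamma))
    if (!is.finite(p) || p <= 0)
      stop("Hill parameters a, tau, gamma must be positive")
  if (any(dt < 0)) stop("dt must be nonnegative")
  ifelse(dt == 0, 0, a / (1 + (tau / dt)^gamma))
}

#' Evaluate the monoexponential offset-decay model
#'
#' \deqn{a(t_{\mathrm{offset}}) = a_0 + \beta\,
#'   e^{-\lambda t_{\mathrm{offset}}}}
#' `a0` is the limiting plateau at infinite offset, `beta` the amplitude
#' of the initial-phase bias and `lam` the decay rate in 1/ps.
#'
#' @param a0,beta real scalars.
#' @param lam positive decay rate (1/ps).
#' @param t_offset nonnegative offset(s) in ps; vectorized.
#' @return value(s) of the model.
#' @export
exp_offset_eval <- function(a0, beta, lam, t_offset) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be positive")
  if (any(t_offset < 0)) stop("t_offset must be nonnegative")
  a0 + beta * exp(-lam * t_offset)
}

new_hill_fit <- function(a = NA_real_, tau = NA_real_, gamma = NA_real_,
                         se_a = NA_real_, se_tau = NA_real_,
                         se_gamma = NA_real_, rss = NA_real_,
                         converged = FALSE, n_points = NA_integer_,
                         diagnostics = "") {
  structure(list(a = a, tau = tau, gamma = gamma, se_a = se_a,
                 se_tau = se_tau, se_gamma = se_gamma, rss = rss,
                 converged = converged, n_points = n_points,
                 diagnostics = diagnostics),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("hill_fit: a = %.6g (se %.3g), tau = %.6g ps (se %.3g), gamma = %.6g (se %.3g)\n",
                x$a, x$se_a, x$tau, x$se_tau, x$gamma, x$se_gamma))
    cat(sprintf("  rss = %.6g over %d points\n", x$rss, x$n_points))
  } else {
    cat("hill_fit: NOT converged")
    if (nzchar(x$diagnostics)) cat(" (", x$diagnostics, ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
as.data.frame.hill_fit <- function(x, ...) {
  data.frame(a = x$a, tau = x$tau, gamma = x$gamma, se_a = x$se_a,
             se_tau = x$se_tau, se_gamma = x$se_gamma, rss = x$rss,
             converged = x$converged, n_points = x$n_points)
}

#' Fit the Hill model to a lagged-RMSD curve
#'
#' Least-squares fit of [hill_eval()] to `mean_rmsd` versus `lags_ps`
#' using bounded Levenberg-Marquardt ([minpack.lm::nlsLM()]) with all
#' three parameters constrained positive. Initial-phase emphasis comes
#' from the lag schedule, not residual weights, so the fit is unweighted
#' by default; `weighted = TRUE` applies inverse-variance weights from
#' `sd_rmsd`. Asymptotic standard errors follow the Jacobian-based
#' covariance `rss/(n-3) * (J'J)^-1`. Degenerate inputs (flat curve) and
#' optimizer failures return a flagged non-converged fit instead of
#' raising, so that offset sweeps survive individual failures.
#'
#' @param curve a [lagged_mean_rmsd()] result with at least 4 distinct
#'   lags and two distinct values.
#' @param init optional named start values `c(a=, tau=, gamma=)`.
#'   Defaults: `a = max(mean_rmsd)`, `tau` = first lag where the curve
#'   exceeds half its maximum, `gamma = 1`.
#' @param lower,upper optional bounds (positive boxes) on
#'   `(a, tau, gamma)`.
#' @param weighted use inverse-variance weights from per-lag standard
#'   deviations.
#' @return an object of class `hill_fit`.
#' @export
fit_hill <- function(curve, init = NULL, lower = NULL, upper = NULL,
                     weighted = FALSE) {
  dt <- curve$lags_ps
  y <- curve$mean_rmsd
  np <- length(dt)
  if (length(unique(dt)) < 4L)
    stop("need at least 4 distinct lags, got ", length(unique(dt)))
  if (length(unique(y)) < 2L)
    return(new_hill_fit(converged = FALSE, n_points = np,
                        diagnostics = "flat curve: all mean RMSD values equal"))
  if (is.null(init)) {
    a0 <- max(y)
    above <- which(y >= a0 / 2)
    tau0 <- if (length(above)) dt[min(above)] else median(dt)
    init <- c(a = a0, tau = max(tau0, min(dt[dt > 0])), gamma = 1)
  }
  if (is.null(lower)) lower <- c(a = 1e-8, tau = 1e-8, gamma = 1e-3)
  if (is.null(upper)) upper <- c(a = Inf, tau = Inf, gamma = 1e3)
  w <- NULL
  if (weighted && !is.null(curve$sd_rmsd) &&
      all(is.finite(curve$sd_rmsd)) && all(curve$sd_rmsd > 0))
    w <- 1 / curve$sd_rmsd^2
  dat <- data.frame(dt = dt, y = y)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      y ~ hill_eval(a, tau, gamma, dt), data = dat,
      start = as.list(init), lower = lower, upper = upper,
      weights = if (is.null(w)) rep(1, np) else w,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxfev = 10000L, maxiter = 1000L))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_hill_fit(converged = FALSE, n_points = np,
                        diagnostics = conditionMessage(fit)))
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(vcov(fit)))),
                 error = function(e) rep(NA_real_, 3L))
  new_hill_fit(a = cf[["a"]], tau = cf[["tau"]], gamma = cf[["gamma"]],
               se_a = se[[1L]], se_tau = se[[2L]], se_gamma = se[[3L]],
               rss = sum(residuals(fit)^2), converged = TRUE,
               n_points = np)
}

new_offset_decay_fit <- function(a0 = NA_real_, beta = NA_real_,
                                 lam = NA_real_, se_a0 = NA_real_,
                                 se_beta = NA_real_, se_lam = NA_real_,
                                 rss = NA_real_, converged = FALSE,
                                 n_points = NA_integer_,
                                 diagnostics = "") {
  structure(list(a0 = a0, beta = beta, lam = lam, se_a0 = se_a0,
                 se_beta = se_beta, se_lam = se_lam, rss = rss,
                 converged = converged, n_points = n_points,
                 diagnostics = diagnostics),
            class = "offset_decay_fit")
}

#' @export
print.offset_decay_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("offset_decay_fit: a0 = %.6g (se %.3g), beta = %.6g (se %.3g), lambda = %.6g 1/ps (se %.3g)\n",
                x$a0, x$se_a0, x$beta, x$se_beta, x$lam, x$se_lam))
  } else cat("offset_decay_fit: NOT converged\n")
  if (nzchar(x$diagnostics)) cat("  note:", x$diagnostics, "\n")
  invisible(x)
}

#' @export
as.data.frame.offset_decay_fit <- function(x, ...) {
  data.frame(a0 = x$a0, beta = x$beta, lam = x$lam, se_a0 = x$se_a0,
             se_beta = x$se_beta, se_lam = x$se_lam, rss = x$rss,
             converged = x$converged, n_points = x$n_points)
}

#' Fit the monoexponential decay of plateau versus offset
#'
#' Least-squares fit of [exp_offset_eval()] to fitted plateau values over
#' an increasing offset grid, extrapolating the limiting plateau `a0` at
#' infinite offset. Defaults: `a0` = last plateau, `beta` = first - last,
#' `lam` = 1 / offset range. Optionally inverse-variance weighted by the
#' plateaus' standard errors. Non-decaying (increasing) data yield a
#' converged fit with `beta < 0`, flagged in `diagnostics` rather than
#' clamped; exactly constant plateaus return `beta = 0`, `a0` = the
#' constant.
#'
#' @param offsets_ps increasing nonnegative offsets in ps (>= 4 points).
#' @param plateaus positive fitted plateau values, one per offset.
#' @param plateau_ses optional positive standard errors for weighting.
#' @return an object of class `offset_decay_fit`.
#' @export
fit_offset_decay <- function(offsets_ps, plateaus, plateau_ses = NULL) {
  np <- length(offsets_ps)
  if (np < 4L) stop("need at least 4 offset points, got ", np)
  if (length(plateaus) != np)
    stop("offsets_ps and plateaus lengths differ")
  if (any(diff(offsets_ps) <= 0)) stop("offsets_ps must be increasing")
  rng <- diff(range(offsets_ps))
  if (length(unique(plateaus)) == 1L)
    return(new_offset_decay_fit(a0 = plateaus[1L], beta = 0, lam = 1 / rng,
                                rss = 0, converged = TRUE, n_points = np,
                                diagnostics = "constant plateaus: beta fixed at 0"))
  w <- rep(1, np)
  if (!is.null(plateau_ses) && all(is.finite(plateau_ses)) &&
      all(plateau_ses > 0))
    w <- 1 / plateau_ses^2
  sw <- sqrt(w)
  resid_fn <- function(p)
    sw * (plateaus - (p[["a0"]] + p[["beta"]] * exp(-p[["lam"]] * offsets_ps)))
  ## identifiability: a decay slower than twice the observed offset range
  ## is indistinguishable from baseline drift (the lam -> 0 ridge leaves
  ## a0 - beta unconstrained), so lam is bounded below accordingly; and
  ## decays faster than the grid spacing make lam weakly identified, so a
  ## ladder of rate starts is tried and the best minimum kept
  lam_min <- 0.5 / rng
  spacing <- min(diff(offsets_ps))
  starts <- unique(pmax(lam_min, c(1 / rng, 10 / rng, 1 / spacing,
                                   5 / spacing)))
  best <- NULL
  for (lam0 in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = list(a0 = plateaus[np],
                   beta = plateaus[1L] - plateaus[np], lam = lam0),
        fn = resid_fn, lower = c(-Inf, -Inf, lam_min),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, maxfev = 10000L, maxiter = 1000L))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$deviance) &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    return(new_offset_decay_fit(converged = FALSE, n_points = np,
                                diagnostics = "optimizer failed from every start"))
  cf <- as.numeric(best$par)
  se <- tryCatch(suppressWarnings(
    sqrt(diag(solve(best$hessian)) * best$deviance / (np - 3L))),
    error = function(e) rep(NA_real_, 3L))
  diag_msg <- if (cf[2L] < 0)
    "negative amplitude: plateaus increase with offset" else ""
  new_offset_decay_fit(a0 = cf[1L], beta = cf[2L], lam = cf[3L],
                       se_a0 = se[[1L]], se_beta = se[[2L]],
                       se_lam = se[[3L]],
                       rss = sum((plateaus - exp_offset_eval(
                         cf[1L], cf[2L], max(cf[3L], 1e-12),
                         offsets_ps))^2),
                       converged = TRUE, n_points = np,
                       diagnostics = diag_msg)
}
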