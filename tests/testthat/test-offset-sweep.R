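# one moderately sized stationary and one transient sweep are shared by
# several assertions to keep the suite fast
stationary_sweep <- local({
  tr <- generate_ou_trajectory(50, 10000, sigma = 1, tau_c = 100,
                               dt_ps = 1, seed = 51)
  sweep_offsets(tr, n_offsets = 8,
                schedule_args = list(dense_upto = 60, dense_step = 3,
                                     sparse_count = 25))
})

transient_sweep <- local({
  tr <- generate_ou_trajectory(100, 3000, sigma = 1, tau_c = 75,
                               dt_ps = 1, seed = 52,
                               init_displacement = 5)
  sweep_offsets(tr, n_offsets = 9,
                schedule_args = list(dense_upto = 40, dense_step = 2,
                                     sparse_count = 25))
})

test_that("offset grids are evenly spaced with inclusive endpoints", {
  tr <- generate_ou_trajectory(5, 60, sigma = 1, tau_c = 10, dt_ps = 1,
                               seed = 53)
  sw <- sweep_offsets(tr, n_offsets = 4,
                      schedule_args = list(dense_upto = 2, dense_step = 1,
                                           sparse_count = 3))
  t_max <- 59
  expect_equal(sw$offsets_ps,
               c(0, t_max / 6, t_max / 3, t_max / 2))
  expect_length(sw$fits, 4)
  expect_length(sw$curves, 4)
  expect_error(sweep_offsets(traj_1d(rnorm(10)), n_offsets = 4),
               "too short")
})

test_that("a stationary process yields stable fits across offsets", {
  a <- vapply(stationary_sweep$fits, `[[`, numeric(1), "a")
  expect_true(all(vapply(stationary_sweep$fits, `[[`, logical(1),
                         "converged")))
  expect_lt((max(a) - min(a)) / mean(a), 0.05)
  v <- assess_stationarity(stationary_sweep)
  expect_identical(v$verdict, "stationary")

  d <- extrapolate_plateau(stationary_sweep)
  expect_true(d$converged)
  # already-decayed case: plateau essentially flat
  expect_lt(abs(d$a0 - mean(a)) / mean(a), 0.05)
})

test_that("an equilibration transient reproduces the expected offset pattern", {
  a <- vapply(transient_sweep$fits, `[[`, numeric(1), "a")
  tau <- vapply(transient_sweep$fits, `[[`, numeric(1), "tau")
  g <- vapply(transient_sweep$fits, `[[`, numeric(1), "gamma")
  # plateau and half-saturation lag inflated at offset 0, decaying after
  expect_true(all(a[1] > a[-1]))
  expect_true(all(tau[1] > tau[-1]))
  # shape parameter comparatively constant
  expect_lt(sd(g) / mean(g), sd(a) / mean(a))

  d <- extrapolate_plateau(transient_sweep)
  expect_true(d$converged)
  expect_lt(abs(d$a0 - sqrt(6)) / sqrt(6), 0.1)
})

test_that("plateau extrapolation requires four converged fits", {
  broken <- stationary_sweep
  for (i in seq_along(broken$fits)[-(1:3)])
    broken$fits[[i]]$converged <- FALSE
  expect_error(extrapolate_plateau(broken), "got 3")
  v <- assess_stationarity(broken)
  expect_identical(v$verdict, "indeterminate")
})

test_that("verdicts cover stationary, drifting and degenerate inputs", {
  drift <- generate_ou_trajectory(50, 2000, sigma = 1, tau_c = 50,
                                  dt_ps = 1, seed = 54,
                                  drift_velocity = 0.005)
  swd <- sweep_offsets(drift, n_offsets = 7,
                       schedule_args = list(dense_upto = 30,
                                            dense_step = 2,
                                            sparse_count = 20))
  expect_identical(assess_stationarity(swd)$verdict, "not_stationary")

  swc <- sweep_offsets(constant_traj(60, 10), n_offsets = 4,
                       schedule_args = list(dense_upto = 3, dense_step = 1,
                                            sparse_count = 3))
  vc <- assess_stationarity(swc)
  expect_identical(vc$verdict, "indeterminate")
  expect_identical(vc$metrics$n_converged, 0L)
})

test_that("extrapolation is insensitive to offset-grid density", {
  dense8 <- seq(0, 2000, length.out = 8)
  dense16 <- seq(0, 2000, length.out = 16)
  f8 <- fit_offset_decay(dense8, exp_offset_eval(2.4, 0.6, 0.003, dense8))
  f16 <- fit_offset_decay(dense16,
                          exp_offset_eval(2.4, 0.6, 0.003, dense16))
  expect_lt(abs(f8$a0 - f16$a0) / f8$a0, 0.02)
})

test_that("stationary plateaus show no systematic offset trend", {
  # fitted plateaus from overlapping windows are strongly correlated, so
  # the trend is assessed across seeded replicates: the mean fitted slope,
  # expressed as plateau change over the whole offset range, must be a
  # negligible fraction of the plateau itself
  rel_change <- vapply(1:25, function(s) {
    tr <- generate_ou_trajectory(20, 1500, sigma = 1, tau_c = 25,
                                 dt_ps = 1, seed = 600 + s)
    sw <- sweep_offsets(tr, n_offsets = 6,
                        schedule_args = list(dense_upto = 20,
                                             dense_step = 2,
                                             sparse_count = 15))
    conv <- which(vapply(sw$fits, `[[`, logical(1), "converged"))
    a <- vapply(sw$fits[conv], `[[`, numeric(1), "a")
    off <- sw$offsets_ps[conv]
    unname(coef(lm(a ~ off))[2]) * diff(range(off)) / mean(a)
  }, numeric(1))
  expect_lt(abs(mean(rel_change)), 0.02)
})

test_that("the full analysis attaches decay fit, verdict and metrics", {
  tr <- generate_ou_trajectory(40, 2000, sigma = 1, tau_c = 30, dt_ps = 1,
                               seed = 55)
  res <- analyze_convergence(tr, n_offsets = 6,
                             schedule_args = list(dense_upto = 20,
                                                  dense_step = 2,
                                                  sparse_count = 15))
  expect_s3_class(res$decay, "offset_decay_fit")
  expect_true(res$verdict %in%
                c("stationary", "not_stationary", "indeterminate"))
  expect_identical(res$verdict_metrics$rel_tol, 0.05)
  tab <- as.data.frame(res)
  expect_identical(nrow(tab), 6L)
  expect_true(all(c("t_offset_ps", "a", "tau", "gamma") %in% names(tab)))
})
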