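make_track <- function(t, x, y, id = "trk00001") {
  data.frame(track_id = id, frame = seq_along(t) - 1L, t_s = t,
             x_um = x, y_um = y)
}

test_that("MSD is exact for ballistic motion and fits recover input slopes", {
  u <- 3.2
  t <- seq(0, 50, by = 0.2)
  tr <- make_track(t, u * t, 0 * t)
  msd <- compute_msd(tr, max_lag = 20)
  expect_equal(msd$msd, u^2 * msd$lag_s^2, tolerance = 1e-12)

  # exact synthetic lines through fit_diffusivity
  lag <- seq(0.2, 30, by = 0.2)
  m1 <- structure(data.frame(lag_s = lag, msd = 8 * lag, n_pairs = 100),
                  class = c("msd_result", "data.frame"))
  f1 <- suppressWarnings(fit_diffusivity(m1, c(2, 20)))
  expect_equal(f1$D_eff, 2.0, tolerance = 1e-10)
  expect_equal(f1$intercept, 0, tolerance = 1e-8)
  m2 <- structure(data.frame(lag_s = lag, msd = 4 * 0.7 * lag + 0.9,
                             n_pairs = 100),
                  class = c("msd_result", "data.frame"))
  f2 <- suppressWarnings(fit_diffusivity(m2, c(2, 20)))
  expect_equal(f2$D_eff, 0.7, tolerance = 1e-10)
  expect_equal(f2$intercept, 0.9, tolerance = 1e-8)
  expect_error(fit_diffusivity(m1, c(2, 2.1)), "3 lag points")
})

test_that("MSD-based diffusivity is unbiased on Brownian ensembles", {
  for (D in c(0.1, 0.4, 2.0)) {
    p <- model_params(D0 = D)
    sim <- simulate_ensemble(p, sim_config(n_tracks = 60, duration = 120,
                                           N_c = 0, dt = 0.01, save_every = 4,
                                           seed = round(1000 * D)))
    fit <- fit_diffusivity(compute_msd(sim$tracks, 20,
                                       lags = seq(0.4, 20, by = 0.4)),
                           c(2, 20))
    est <- direct_deff(sim$tracks)  # independent route for the honest s.e.
    expect_lt(abs(fit$D_eff - D), 3 * max(est["se"], fit$stderr))
  }
})

test_that("a single inserted ballistic segment is detected with its length", {
  set.seed(77)
  dtf <- 0.04
  t <- seq(0, 200, by = dtf)
  n <- length(t)
  x <- cumsum(c(0, rnorm(n - 1, sd = sqrt(2 * 0.4 * dtf))))
  y <- cumsum(c(0, rnorm(n - 1, sd = sqrt(2 * 0.4 * dtf))))
  # ballistic insert: 15 um over 1.7 s starting at t = 100
  i0 <- which.min(abs(t - 100))
  nseg <- round(1.7 / dtf)
  vstep <- 15 / nseg
  dx <- rep(0, n); dx[(i0 + 1):(i0 + nseg)] <- vstep
  x <- x + cumsum(dx)
  ev <- detect_jumps(make_track(t, x, y))
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$length_um - 15), 1.5)
  expect_lt(abs(ev$t_start_s - 100), 1)
})

test_that("the detector is quiet on pure Brownian tracks", {
  p <- model_params()
  sim <- simulate_ensemble(p, sim_config(n_tracks = 200, duration = 200,
                                         N_c = 0, dt = 0.04, save_every = 1,
                                         seed = 101))
  ev <- detect_jumps(sim$tracks)
  expect_lt(nrow(ev) / 200, 0.05)  # false positives per track
})

test_that("detection is invariant under translation and rotation", {
  p <- model_params()
  sim <- simulate_ensemble(p, sim_config(n_tracks = 4, duration = 200, N_c = 3,
                                         dt = 0.004, save_every = 10,
                                         seed = 19))
  ev0 <- detect_jumps(sim$tracks)
  th <- 0.83
  rot <- sim$tracks
  x <- rot$x_um; y <- rot$y_um
  rot$x_um <- cos(th) * x - sin(th) * y + 120
  rot$y_um <- sin(th) * x + cos(th) * y - 45
  ev1 <- detect_jumps(rot)
  expect_equal(ev0$t_start_s, ev1$t_start_s)
  expect_equal(ev0$length_um, ev1$length_um, tolerance = 1e-9)
})

test_that("jump statistics recover the shifted-exponential parameters", {
  p <- model_params()
  set.seed(5)
  L <- draw_jump_length(p, 1e5)
  ev <- data.frame(track_id = "a", t_start_s = seq_along(L),
                   t_end_s = seq_along(L) + 1.7, length_um = L,
                   duration_s = 1.7, theta_rad = 0)
  js <- jump_statistics(ev, L_T = 7.5)
  expect_lt(abs(js$L_J_hat - 7.5), 3 * 7.5 / sqrt(js$n_above))
  # censoring invariance: a higher cut leaves the excess mean unchanged
  js10 <- jump_statistics(ev, L_T = 10)
  expect_lt(abs(js10$L_J_hat - js$L_J_hat),
            3 * 7.5 / sqrt(js10$n_above))

  # plain arithmetic on a degenerate event set
  ev2 <- data.frame(track_id = "a", t_start_s = 1:3, t_end_s = 1:3 + 2,
                    length_um = 10, duration_s = 2, theta_rad = 0)
  js2 <- jump_statistics(ev2, L_T = 7.5)
  expect_equal(js2$mean_L, 10)
  expect_equal(js2$mean_tau, 2)
  expect_equal(js2$L_J_hat, 2.5)
  expect_warning(jump_statistics(ev2, L_T = 99), "L_J_hat")
  expect_error(jump_statistics(ev2[0, ]), "no events")
})

test_that("waiting-time estimators behave as renewal theory predicts", {
  set.seed(8)
  # unbiased estimator on long tracks
  ev <- poisson_event_tables(1 / 68.2, 2000, 400)
  trk <- skeleton_tracks(400, 2000)
  w <- waiting_time_stats(trk, ev)
  expect_lt(abs(w$mean_unbiased - 68.2), 3 * 68.2 / sqrt(w$n_events))
  expect_lte(w$tau_exp_fit, w$mean_unbiased)  # censoring can only shorten gaps

  # censoring bias on short windows matches the analytic conditioned-gap mean
  set.seed(9)
  rate <- 1.56 / 68.2
  ev2 <- poisson_event_tables(rate, 200, 3000)
  w2 <- waiting_time_stats(skeleton_tracks(3000, 200), ev2)
  oracle <- censored_gap_mean(rate, 200)
  expect_lt(abs(w2$tau_exp_fit - oracle),
            3 * sd(w2$gaps) / sqrt(length(w2$gaps)))
  expect_lt(oracle, 1 / rate)  # biased below the true 43.7 s

  # one event per track: no gaps, but the unbiased mean is still defined
  ev3 <- data.frame(track_id = c("w00001", "w00002"), t_start_s = c(5, 9),
                    t_end_s = c(5, 9), length_um = 10, duration_s = 0,
                    theta_rad = 0)
  w3 <- waiting_time_stats(skeleton_tracks(2, 100), ev3)
  expect_length(w3$gaps, 0)
  expect_true(is.finite(w3$mean_unbiased))
  expect_warning(waiting_time_stats(skeleton_tracks(2, 100), ev3[0, ]),
                 "no events")
})

test_that("displacement histograms are normalized and Gaussian for Brownian input", {
  p <- model_params()
  # frames at the lag itself, so the pooled displacements are independent
  # and the Kolmogorov-Smirnov reference distribution applies
  sim <- simulate_ensemble(p, sim_config(n_tracks = 30, duration = 100,
                                         N_c = 0, dt = 0.04, save_every = 25,
                                         seed = 3))
  pdf1 <- displacement_pdf(sim$tracks, dt_lag = 1)
  expect_equal(sum(pdf1$density * diff(pdf1$breaks)), 1, tolerance = 1e-12)
  expect_gt(stats::ks.test(pdf1$displacements, "pnorm", 0,
                           sqrt(2 * 0.4 * 1))$p.value, 0.01)
  # exclusion is a no-op on jump-free tracks
  pdf2 <- displacement_pdf(sim$tracks, dt_lag = 1, exclude_jumps = TRUE,
                           events = sim$events)
  expect_identical(pdf1$density, pdf2$density)
  expect_identical(pdf1$displacements, pdf2$displacements)
  expect_error(displacement_pdf(sim$tracks, dt_lag = 0.013), "multiple")
})

test_that("modified kurtosis is zero for Gaussian and one for Laplace data", {
  set.seed(12)
  g <- rnorm(1e5)
  expect_lt(abs(modified_kurtosis(g)), 3 * sqrt(24 / length(g)) / 3)
  lap <- rexp(5e5) * sample(c(-1, 1), 5e5, replace = TRUE)
  expect_lt(abs(modified_kurtosis(lap) - 1), 0.05)
  expect_error(modified_kurtosis(rep(1, 10)), "variance")
  expect_error(modified_kurtosis(1:3), "at least 4")
})

test_that("speed rescaling is the stated ratio and an involution", {
  expect_equal(rescale_by_speed(1.0, 40.9, 81.8), 2.0)
  expect_equal(rescale_by_speed(3.3, 50, 50), 3.3)
  D <- 1.234
  expect_equal(rescale_by_speed(rescale_by_speed(D, 40.9, 81.8), 81.8, 40.9),
               D, tolerance = 1e-15)
  expect_error(rescale_by_speed(1, 0, 10), "positive")
})
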