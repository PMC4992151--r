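test_that("the Stokes settling speed has the right value and scaling", {
  expect_equal(stokes_sedimentation_speed(0, 1, 1), 0)
  expect_equal(stokes_sedimentation_speed(50, 1, 1.0), 0.02725, tolerance = 1e-6)
  expect_equal(stokes_sedimentation_speed(50, 2, 1.0),
               4 * stokes_sedimentation_speed(50, 1, 1.0))
  expect_error(stokes_sedimentation_speed(50, 1, 0), "viscosity")
})

test_that("exponential profile fits recover the decay length", {
  z <- seq(1, 180, by = 2)
  # noiseless exponential, l = 20
  prof <- data.frame(bin_center_um = z, count = 5e4 * exp(-z / 20))
  fit <- fit_sedimentation_profile(prof, min_count = 1)
  expect_equal(fit$l_g_eff, 20, tolerance = 1e-6)
  # Poisson noise at ~1e4 total counts, l = 77
  set.seed(21)
  mu <- exp(-z / 77); mu <- mu * 1e4 / sum(mu)
  prof2 <- data.frame(bin_center_um = z, count = rpois(length(z), mu))
  fit2 <- fit_sedimentation_profile(prof2, min_count = 10)
  expect_equal(fit2$l_g_eff, 77, tolerance = 0.05)
  # a flat profile has no finite decay length
  prof3 <- data.frame(bin_center_um = z, count = rep(1000, length(z)))
  expect_error(fit_sedimentation_profile(prof3), "out of range")
  expect_error(fit_sedimentation_profile(prof[1:3, ], min_count = 1),
               "at least 5 bins")
})

test_that("the Perrin product converts decay lengths to diffusivities", {
  expect_equal(deff_from_sedimentation(0.02725, 14.7), 0.4006, tolerance = 1e-3)
  expect_lt(abs(deff_from_sedimentation(0.02725, 62.8) - 1.71), 0.14)
  expect_equal(deff_from_sedimentation(0.02725, 0), 0)
})

test_that("the band model solves confined diffusion of a top-hat", {
  band <- c(2000 / 3, 4000 / 3); channel <- c(0, 2000)
  x <- seq(0, 2000, by = 1)
  # exact initial condition
  rho0 <- band_profile_model(x, 0, 2, band, channel)
  expect_equal(rho0[x > band[1] & x < band[2]],
               rep(1 / diff(band), sum(x > band[1] & x < band[2])))
  expect_equal(rho0[x < band[1] | x > band[2]],
               rep(0, sum(x < band[1] | x > band[2])))
  # mass conserved at all times (trapezoidal quadrature on a fine grid)
  for (t in c(60, 600, 6000)) {
    rho <- band_profile_model(x, t, 2, band, channel)
    mass <- sum((rho[-1] + rho[-length(rho)]) / 2)
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # equilibrium is uniform at mass / width
  rho_inf <- band_profile_model(x, 1e8, 2, band, channel)
  expect_equal(rho_inf, rep(1 / 2000, length(x)), tolerance = 1e-10)
  # before wall interaction the solution equals the free-space erf profile
  t <- 500; D <- 2
  rho <- band_profile_model(x, t, D, band, channel)
  free <- (pnorm((x - band[1]) / sqrt(2 * D * t)) -
             pnorm((x - band[2]) / sqrt(2 * D * t))) / diff(band)
  expect_lt(max(abs(rho - free)) / max(rho), 1e-6)
  expect_error(band_profile_model(x, 1, 2, c(-5, 100), channel), "inside")
})

test_that("band-spreading fits invert the diffusivity", {
  band <- c(2000 / 3, 4000 / 3); channel <- c(0, 2000)
  centers <- seq(10, 1990, by = 20)
  # noiseless profiles generated from the model itself
  profs <- do.call(rbind, lapply(c(300, 900, 1800, 3000), function(t) {
    data.frame(time_s = t, bin_center_um = centers,
               count = 1e6 * band_profile_model(centers, t, 1.6, band, channel))
  }))
  fit <- fit_band_spreading(profs, band, channel)
  expect_equal(fit$D_eff, 1.6, tolerance = 0.01)
  expect_error(fit_band_spreading(profs[profs$time_s < 400, ], band, channel),
               "3 time points")
})

test_that("band spreading of simulated jump-diffusion matches the MSD diffusivity", {
  p <- model_params()
  N_c <- 2
  times <- c(600, 1200, 1800, 2400)
  n_tr <- 1500
  sim <- simulate_ensemble(p, sim_config(n_tracks = n_tr, duration = 2400,
                                         N_c = N_c, dt = 0.02,
                                         save_every = 30000, seed = 23))
  set.seed(24)
  # both coordinates of each track give independent 1D spreading samples
  x0 <- runif(2 * n_tr, 2000 / 3, 4000 / 3)
  sp <- split(sim$tracks, sim$tracks$track_id)
  breaks <- seq(0, 2000, by = 40)
  profs <- do.call(rbind, lapply(times, function(t) {
    disp <- vapply(seq_along(sp), function(i) {
      tr <- sp[[i]]
      k <- which.min(abs(tr$t_s - t))
      c(tr$x_um[k], tr$y_um[k])
    }, numeric(2))
    h <- hist(x0 + as.numeric(disp), breaks = breaks, plot = FALSE)
    data.frame(time_s = t, bin_center_um = h$mids, count = h$counts)
  }))
  # the few-thousand-particle profile fit carries ~12% statistical error
  # (normalization correlates bin noise), so consistency is asserted at the
  # two-sigma level
  fit <- fit_band_spreading(profs)
  expect_equal(fit$D_eff, deff_jump_diffusion(p, N_c), tolerance = 0.25)
})

test_that("linear concentration fits return slope and intercept", {
  nc <- c(0.5, 1, 2, 3, 5)
  D <- 0.40 + 1.67 * nc
  fit <- suppressWarnings(fit_linear_concentration(D, nc))
  expect_equal(fit$slope, 1.67, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.40, tolerance = 1e-10)
  expect_error(fit_linear_concentration(c(1, 2), c(1, 1)), "singular")
  # two points give the analytic secant
  f2 <- suppressWarnings(fit_linear_concentration(c(1.0, 2.2), c(1, 4)))
  expect_equal(f2$slope, 1.2 / 3, tolerance = 1e-12)
  # equivariance under speed rescaling
  r <- 81.8 / 40.9
  fr <- suppressWarnings(
    fit_linear_concentration(rescale_by_speed(D, 40.9, 81.8), nc))
  expect_equal(fr$slope, r * fit$slope, tolerance = 1e-10)
  expect_equal(fr$intercept, r * fit$intercept, tolerance = 1e-10)
})

test_that("Peclet numbers compare advection to thermal diffusion", {
  expect_equal(signif(peclet_number(81.8, 10, 0.40), 2), 2000)
  expect_equal(signif(peclet_number(40.9, 10, 0.40 / 1.5), 2), 1500)
  expect_equal(peclet_number(2 * 81.8, 10, 0.40),
               2 * peclet_number(81.8, 10, 0.40))
  expect_error(peclet_number(10, 10, 0), "D0")
})
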