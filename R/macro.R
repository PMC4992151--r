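#' Stokes sedimentation speed
#'
#' Terminal settling speed of a small sphere,
#' `v_sed = g * delta_rho * d^2 / (18 * eta)`.
#'
#' @param delta_rho Density mismatch, g/l (= kg/m^3).
#' @param diameter Particle diameter, um.
#' @param viscosity Dynamic viscosity, mPa s (water at ~21 C is about 1.0).
#' @return Sedimentation speed, um/s.
#' @export
#' @examples
#' stokes_sedimentation_speed(50, 1, 1.0)  # ~ 0.0273 um/s
stokes_sedimentation_speed <- function(delta_rho, diameter, viscosity) {
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (delta_rho < 0 || diameter <= 0)
    stop("delta_rho must be nonnegative and diameter positive", call. = FALSE)
  # SI: 9.81 m/s^2 * [kg/m^3] * [m]^2 / (18 [Pa s]) -> m/s; report um/s
  9.81 * delta_rho * (diameter * 1e-6)^2 / (18 * viscosity * 1e-3) * 1e6
}

.check_profile <- function(profile) {
  req <- c("bin_center_um", "count")
  miss <- setdiff(req, names(profile))
  if (length(miss))
    stop("profile is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(profile) < 5) stop("profile needs at least 5 bins", call. = FALSE)
  d <- diff(profile$bin_center_um)
  if (any(d <= 0) || any(abs(d - d[1]) > 1e-6 * d[1]))
    stop("profile bins must be uniform and increasing", call. = FALSE)
  if (any(profile$count < 0)) stop("counts must be nonnegative", call. = FALSE)
  invisible(profile)
}

#' Fit an exponential sedimentation profile
#'
#' Weighted least squares of log-counts against height, with Poisson weights
#' (proportional to counts), returning the gravitational decay length
#' `l_g_eff = -1 / slope`.  Bins with fewer than `min_count` counts are
#' excluded to avoid log-of-small-count bias.
#'
#' @param profile Data.frame with columns `bin_center_um`, `count`.
#' @param fit_range Optional height range `(lo, hi)`, um, to fit on.
#' @param min_count Minimum count for a bin to enter the fit.
#' @return An object of class `sedimentation_fit`: list with `l_g_eff` (um),
#'   `amplitude`, `stderr` (um), `n_bins`, `residuals`.
#' @seealso [deff_from_sedimentation()]
#' @export
fit_sedimentation_profile <- function(profile, fit_range = NULL,
                                      min_count = 10) {
  .check_profile(profile)
  sel <- profile$count >= min_count
  if (!is.null(fit_range))
    sel <- sel & profile$bin_center_um >= fit_range[1] &
      profile$bin_center_um <= fit_range[2]
  if (sum(sel) < 3)
    stop("fewer than 3 usable bins in the fit range", call. = FALSE)
  z <- profile$bin_center_um[sel]
  cts <- profile$count[sel]
  fit <- stats::lm(log(cts) ~ z, weights = cts)
  co <- summary(fit)$coefficients
  slope <- unname(co["z", "Estimate"])
  if (slope >= -1e-12)
    stop("profile does not decay with height: gravitational length out of range",
         call. = FALSE)
  structure(list(l_g_eff = -1 / slope,
                 amplitude = exp(unname(co["(Intercept)", "Estimate"])),
                 stderr = unname(co["z", "Std. Error"]) / slope^2,
                 n_bins = sum(sel),
                 residuals = stats::residuals(fit)),
            class = "sedimentation_fit")
}

#' @export
print.sedimentation_fit <- function(x, ...) {
  cat(sprintf("Gravitational length l_g_eff = %.4g +/- %.2g um (%d bins)\n",
              x$l_g_eff, x$stderr, x$n_bins))
  invisible(x)
}

#' Effective diffusivity from sedimentation equilibrium
#'
#' Perrin's balance: an exponential steady-state profile of decay length
#' `l_g_eff` under settling speed `v_sed` implies `D_eff = v_sed * l_g_eff`.
#'
#' @param v_sed Sedimentation speed, um/s.
#' @param l_g_eff Gravitational decay length, um.
#' @return Effective diffusivity, um^2/s.
#' @export
deff_from_sedimentation <- function(v_sed, l_g_eff) {
  if (v_sed < 0 || l_g_eff < 0)
    stop("inputs must be nonnegative", call. = FALSE)
  v_sed * l_g_eff
}

#' Diffusive relaxation of a top-hat band between no-flux walls
#'
#' Solution of the 1D diffusion equation on a channel `[c1, c2]` with no-flux
#' walls and a top-hat initial condition of unit mass on `band`, evaluated by
#' cosine-series expansion (terms added until their bound falls below 1e-10,
#' so the truncation error is well below 1e-8).  `t = 0` returns the exact
#' top-hat; `t -> Inf` tends to the uniform density.
#'
#' @param x Positions, um.
#' @param t Time, s (nonnegative).
#' @param D Diffusivity, um^2/s.
#' @param band Initial band `(b1, b2)`, um, inside the channel.
#' @param channel Channel walls `(c1, c2)`, um.
#' @return Density values at `x`, 1/um (unit total mass).
#' @export
band_profile_model <- function(x, t, D, band = c(2000 / 3, 4000 / 3),
                               channel = c(0, 2000)) {
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  b1 <- band[1]; b2 <- band[2]; c1 <- channel[1]; c2 <- channel[2]
  if (!(c1 < b1 && b1 < b2 && b2 <= c2) || !(c1 <= b1))
    stop("band must lie inside the channel", call. = FALSE)
  W <- c2 - c1
  if (t == 0) return(ifelse(x >= b1 & x <= b2, 1 / (b2 - b1), 0))
  xi <- x - c1
  rho <- rep(1 / W, length(x))
  bound_const <- 4 / (pi * (b2 - b1))
  n <- 1
  repeat {
    decay <- exp(-D * (n * pi / W)^2 * t)
    if (bound_const / n * decay < 1e-10 || n > 200000) break
    a_n <- 2 / (n * pi * (b2 - b1)) *
      (sin(n * pi * (b2 - c1) / W) - sin(n * pi * (b1 - c1) / W))
    rho <- rho + a_n * decay * cos(n * pi * xi / W)
    n <- n + 1
  }
  rho
}

.check_band_profiles <- function(profiles) {
  req <- c("bin_center_um", "count", "time_s")
  miss <- setdiff(req, names(profiles))
  if (length(miss))
    stop("band profiles missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  times <- sort(unique(profiles$time_s))
  if (length(times) < 3) stop("need at least 3 time points", call. = FALSE)
  times
}

#' Fit a diffusivity to spreading band profiles
#'
#' Least-squares match of [band_profile_model()] to observed, per-time
#' normalized density profiles over the single parameter `D`.  Full profiles
#' are matched (rather than the variance growth) because wall confinement
#' breaks the free-space variance law at late times.  Profiles at `t = 0`
#' carry no information about `D` and are ignored.
#'
#' @param profiles Data.frame with columns `bin_center_um`, `count`, `time_s`
#'   (at least 3 distinct times).
#' @param band,channel Geometry passed to [band_profile_model()].
#' @param D_range Search interval for `D`, um^2/s.
#' @return An object of class `band_fit`: list with `D_eff`, `stderr`
#'   (um^2/s), `rss`, `n_obs`, `times`.
#' @export
fit_band_spreading <- function(profiles, band = c(2000 / 3, 4000 / 3),
                               channel = c(0, 2000), D_range = c(1e-3, 50)) {
  times <- .check_band_profiles(profiles)
  prof <- profiles[profiles$time_s > 0, ]
  if (length(unique(prof$time_s)) < 2)
    stop("need at least 2 positive-time profiles", call. = FALSE)
  parts <- split(prof, prof$time_s)
  obs <- lapply(parts, function(p) {
    p <- p[order(p$bin_center_um), ]
    bw <- diff(p$bin_center_um)[1]
    list(x = p$bin_center_um, t = p$time_s[1],
         dens = p$count / (sum(p$count) * bw))
  })
  rss <- function(D) {
    sum(vapply(obs, function(o) {
      sum((o$dens - band_profile_model(o$x, o$t, D, band, channel))^2)
    }, numeric(1)))
  }
  opt <- stats::optimize(rss, interval = D_range, tol = 1e-8)
  D_hat <- opt$minimum
  n_obs <- sum(vapply(obs, function(o) length(o$x), 1L))
  # curvature-based standard error: Var(D) ~ 2 sigma^2 / rss''(D_hat)
  h <- max(1e-4, 1e-3 * D_hat)
  d2 <- (rss(D_hat + h) - 2 * opt$objective + rss(D_hat - h)) / h^2
  sigma2 <- opt$objective / max(n_obs - 1, 1)
  stderr <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  structure(list(D_eff = D_hat, stderr = stderr, rss = opt$objective,
                 n_obs = n_obs, times = times),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("Band-spreading fit: D_eff = %.4g +/- %.2g um^2/s (%d points, %d times)\n",
              x$D_eff, x$stderr, x$n_obs, length(x$times)))
  invisible(x)
}

#' Linear fit of diffusivity against cell concentration
#'
#' Weighted least squares of `D_eff = D_0 + alpha * N_c`, the dilute-regime
#' law tying the effective diffusivity to the concentration of swimmers.
#'
#' @param D_effs Effective diffusivities, um^2/s.
#' @param N_cs Concentrations, 10^6 cells/ml (at least 2 distinct values).
#' @param errors Optional standard errors of `D_effs` (weights `1 / errors^2`).
#' @return An object of class `linear_conc_fit`: list with `intercept` (um^2/s,
#'   the thermal diffusivity), `slope` ((um^2/s)/(10^6 cells/ml)),
#'   `stderr_slope`, `stderr_intercept`.
#' @export
fit_linear_concentration <- function(D_effs, N_cs, errors = NULL) {
  if (length(D_effs) != length(N_cs))
    stop("D_effs and N_cs must have equal length", call. = FALSE)
  if (length(unique(N_cs)) < 2)
    stop("singular design: need at least 2 distinct concentrations",
         call. = FALSE)
  w <- if (is.null(errors)) NULL else 1 / errors^2
  fit <- stats::lm(D_effs ~ N_cs, weights = w)
  co <- summary(fit)$coefficients
  structure(list(intercept = unname(co["(Intercept)", "Estimate"]),
                 slope = unname(co["N_cs", "Estimate"]),
                 stderr_slope = unname(co["N_cs", "Std. Error"]),
                 stderr_intercept = unname(co["(Intercept)", "Std. Error"])),
            class = "linear_conc_fit")
}

#' @export
print.linear_conc_fit <- function(x, ...) {
  cat(sprintf("D_eff(N_c) = (%.4g +/- %.2g) + (%.4g +/- %.2g) N_c  [um^2/s]\n",
              x$intercept, x$stderr_intercept, x$slope, x$stderr_slope))
  invisible(x)
}

#' Colloidal Peclet number
#'
#' `Pe = v * L_body / D0`: ratio of advective transport by a nearby swimmer to
#' the particle's own diffusion.
#'
#' @param v Swimmer speed, um/s.
#' @param L_body Swimmer body length, um.
#' @param D0 Particle thermal diffusivity, um^2/s.
#' @return Dimensionless Peclet number.
#' @export
#' @examples
#' peclet_number(81.8, 10, 0.40)  # ~ 2000
peclet_number <- function(v, L_body, D0) {
  if (v <= 0 || L_body <= 0) stop("v and L_body must be positive", call. = FALSE)
  if (D0 <= 0) stop("D0 must be positive", call. = FALSE)
  v * L_body / D0
}
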