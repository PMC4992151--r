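#' Configuration of a synthetic experiment
#'
#' Describes one of the three emulated experiments: long-time particle
#' tracking in a thin quasi-2D chamber, steady-state sedimentation profiling,
#' or spreading of an initially tight band of particles.
#'
#' @param experiment One of `"tracking"`, `"sedimentation"`, `"spreading"`.
#' @param N_c_list Cell concentrations to generate, 10^6 cells/ml.
#' @param n_tracks Number of tracks per concentration (tracking).
#' @param n_particles Number of particles per profile (sedimentation,
#'   spreading).
#' @param track_duration Track duration, s.
#' @param frame_rate Frames per second (default 25 for tracking, 10 for
#'   sedimentation).
#' @param localization_sigma Gaussian localization noise per coordinate, um
#'   (typical sub-pixel centroid accuracy; 0 disables).
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("tracking", "sedimentation",
                                             "spreading"),
                              N_c_list = 1, n_tracks = 50,
                              n_particles = 10000, track_duration = 200,
                              frame_rate = NULL, localization_sigma = 0.05,
                              seed = 1) {
  experiment <- match.arg(experiment)
  if (is.null(frame_rate))
    frame_rate <- if (experiment == "tracking") 25 else 10
  if (any(N_c_list < 0) || n_tracks < 1 || n_particles < 1 ||
      track_duration <= 0 || frame_rate <= 0 || localization_sigma < 0)
    stop("invalid experiment configuration", call. = FALSE)
  structure(list(experiment = experiment, N_c_list = N_c_list,
                 n_tracks = as.integer(n_tracks),
                 n_particles = as.integer(n_particles),
                 track_duration = track_duration, frame_rate = frame_rate,
                 localization_sigma = localization_sigma,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

.derived_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 7368787 * as.numeric(k)) %%
               2147483647)
}

#' Generate a synthetic particle-tracking dataset
#'
#' For each concentration, simulates jump-diffusion trajectories at a fine
#' integration step, subsamples them to the camera frame rate, and adds
#' independent Gaussian localization noise to each coordinate.  Both the
#' observed tracks and the ground-truth event lists are returned, so parameter
#' recovery can be scored without re-simulation.  Fully seed-deterministic.
#'
#' @param params A [model_params()] object.
#' @param config An [experiment_config()] with `experiment = "tracking"`.
#' @param dt_sim Integration step, s.
#' @return List with `tracks` (observed, noisy), `events` (ground truth;
#'   includes an `N_c` column), and `manifest` (config, params, seed).
#' @export
generate_tracking_dataset <- function(params, config, dt_sim = 0.004) {
  stopifnot(inherits(params, "model_params"),
            inherits(config, "experiment_config"))
  if (config$experiment != "tracking")
    stop("config$experiment must be 'tracking'", call. = FALSE)
  save_every <- round(1 / (config$frame_rate * dt_sim))
  if (abs(save_every * dt_sim * config$frame_rate - 1) > 1e-6)
    stop("1 / frame_rate must be a multiple of dt_sim", call. = FALSE)
  all_tracks <- list(); all_events <- list()
  for (k in seq_along(config$N_c_list)) {
    nc <- config$N_c_list[k]
    sc <- sim_config(dt = dt_sim, duration = config$track_duration,
                     n_tracks = config$n_tracks, N_c = nc,
                     seed = .derived_seed(config$seed, 2 * k - 1),
                     record_truth = TRUE, save_every = save_every)
    sim <- simulate_ensemble(params, sc)
    sim$tracks$track_id <- paste0("nc", format(nc), "_", sim$tracks$track_id)
    if (nrow(sim$events))
      sim$events$track_id <- paste0("nc", format(nc), "_", sim$events$track_id)
    if (config$localization_sigma > 0) {
      set.seed(.derived_seed(config$seed, 2 * k))
      n <- nrow(sim$tracks)
      sim$tracks$x_um <- sim$tracks$x_um +
        stats::rnorm(n, sd = config$localization_sigma)
      sim$tracks$y_um <- sim$tracks$y_um +
        stats::rnorm(n, sd = config$localization_sigma)
    }
    sim$tracks$N_c <- nc
    sim$events$N_c <- rep(nc, nrow(sim$events))
    all_tracks[[k]] <- sim$tracks
    all_events[[k]] <- sim$events
  }
  list(tracks = as.data.frame(data.table::rbindlist(all_tracks)),
       events = as.data.frame(data.table::rbindlist(all_events)),
       manifest = list(params = unclass(params), config = unclass(config),
                       dt_sim = dt_sim))
}

#' Generate synthetic sedimentation profiles
#'
#' Samples particle heights directly from the truncated-exponential steady
#' state with gravitational length `l_g = D_eff / v_sed` on `[0, H]` (sampling
#' the analytic steady state keeps generation fast; the Langevin route is
#' available through [simulate_sedimenting_ensemble()]).  The total count is
#' Poisson-distributed, so bin counts are independent Poisson variates.
#'
#' @param params A [model_params()] object.
#' @param config An [experiment_config()] with `experiment = "sedimentation"`.
#' @param v_sed Sedimentation speed, um/s.
#' @param H Channel height, um.
#' @param D_eff Optional diffusivity override (one value, or one per
#'   concentration); default is the free-space jump-diffusion value
#'   [deff_jump_diffusion()] at each `N_c`.
#' @param bin_width Histogram bin width, um.
#' @return List with `profiles` (data.frame `N_c, bin_center_um, count`) and
#'   `truth` (data.frame `N_c, D_eff, l_g`).
#' @export
generate_sedimentation_dataset <- function(params, config, v_sed, H,
                                           D_eff = NULL, bin_width = 2) {
  stopifnot(inherits(params, "model_params"),
            inherits(config, "experiment_config"))
  if (config$experiment != "sedimentation")
    stop("config$experiment must be 'sedimentation'", call. = FALSE)
  if (H <= 0) stop("H must be positive", call. = FALSE)
  if (v_sed <= 0) stop("v_sed must be positive", call. = FALSE)
  Ds <- if (is.null(D_eff)) deff_jump_diffusion(params, config$N_c_list)
        else rep_len(D_eff, length(config$N_c_list))
  breaks <- seq(0, H, length.out = max(5, round(H / bin_width)) + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  profs <- list()
  for (k in seq_along(config$N_c_list)) {
    l <- Ds[k] / v_sed
    set.seed(.derived_seed(config$seed, k))
    n <- stats::rpois(1, config$n_particles)
    u <- stats::runif(n)
    z <- -l * log(1 - u * (1 - exp(-H / l)))  # inverse-CDF, truncated at H
    cts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
    profs[[k]] <- data.frame(N_c = config$N_c_list[k],
                             bin_center_um = centers, count = cts)
  }
  list(profiles = as.data.frame(data.table::rbindlist(profs)),
       truth = data.frame(N_c = config$N_c_list, D_eff = Ds,
                          l_g = Ds / v_sed))
}

#' Generate synthetic band-spreading profiles
#'
#' Samples particle positions from the [band_profile_model()] density at each
#' requested time (top-hat initial condition on the middle third of the
#' channel by default) and bins them; the Poisson-distributed total count makes
#' bin counts independent Poisson variates.
#'
#' @param D_eff_true Ground-truth diffusivity, um^2/s.
#' @param config An [experiment_config()] with `experiment = "spreading"`.
#' @param times Observation times, s (include 0 to record the initial band).
#' @param geometry List with `channel = c(c1, c2)` and `band = c(b1, b2)`, um.
#' @param bin_width Histogram bin width, um.
#' @return List with `profiles` (data.frame `time_s, bin_center_um, count`)
#'   and `truth` (list with `D_eff`, `geometry`).
#' @export
generate_band_dataset <- function(D_eff_true, config,
                                  times = c(0, 600, 1200, 1800, 2400),
                                  geometry = list(channel = c(0, 2000),
                                                  band = c(2000 / 3, 4000 / 3)),
                                  bin_width = 20) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$experiment != "spreading")
    stop("config$experiment must be 'spreading'", call. = FALSE)
  if (D_eff_true <= 0) stop("D_eff_true must be positive", call. = FALSE)
  ch <- geometry$channel; bd <- geometry$band
  if (is.null(ch) || is.null(bd) || !(ch[1] < bd[1] && bd[1] < bd[2] &&
                                      bd[2] <= ch[2]))
    stop("invalid geometry: band must lie inside the channel", call. = FALSE)
  breaks <- seq(ch[1], ch[2],
                length.out = max(5, round((ch[2] - ch[1]) / bin_width)) + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  grid <- seq(ch[1], ch[2], length.out = 4001)
  profs <- list()
  for (k in seq_along(times)) {
    t <- times[k]
    set.seed(.derived_seed(config$seed, k))
    n <- stats::rpois(1, config$n_particles)
    if (t == 0) {
      pos <- stats::runif(n, bd[1], bd[2])
    } else {
      dens <- band_profile_model(grid, t, D_eff_true, bd, ch)
      cdf <- cumsum(dens)
      cdf <- cdf / cdf[length(cdf)]
      pos <- stats::approx(cdf, grid, xout = stats::runif(n), rule = 2,
                           ties = "ordered")$y
    }
    cts <- graphics::hist(pos, breaks = breaks, plot = FALSE)$counts
    profs[[k]] <- data.frame(time_s = t, bin_center_um = centers, count = cts)
  }
  list(profiles = as.data.frame(data.table::rbindlist(profs)),
       truth = list(D_eff = D_eff_true, geometry = geometry))
}
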