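#' Draw entrainment jump lengths
#'
#' Jump end-to-end lengths follow a shifted exponential law: `L = L_T + E` with
#' `E` exponential of mean `L_J`, so every draw is at least `L_T` and the mean
#' is `L_T + L_J`.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of lengths, um.
#' @export
#' @examples
#' set.seed(1)
#' mean(draw_jump_length(model_params(), 1e4))  # ~ 15 um
draw_jump_length <- function(params, n = 1) {
  stopifnot(inherits(params, "model_params"))
  params$L_T + stats::rexp(n, rate = 1 / params$L_J)
}

#' Mean diffusive waiting time between jumps
#'
#' The mean time spent diffusing between consecutive entrainment events scales
#' inversely with the cell concentration (hyperbolic law `A_wait / N_c`),
#' because jump initiation is governed by the particle-swimmer encounter rate.
#'
#' @param N_c Cell concentration, 10^6 cells/ml (nonnegative).
#' @param params A [model_params()] object.
#' @return Mean waiting time in seconds; `Inf` when `N_c = 0` (no jumps, the
#'   simulator then produces pure Brownian motion).
#' @export
mean_waiting_time <- function(N_c, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(N_c) || any(N_c < 0))
    stop("N_c must be nonnegative", call. = FALSE)
  ifelse(N_c == 0, Inf, params$A_wait / N_c)
}

#' Per-cycle (renewal) effective diffusivity of the jump-diffusion process
#'
#' Long-time effective diffusivity obtained from the renewal structure of the
#' process: each cycle consists of a diffusive wait of mean `<DT_J>` (variance
#' of displacement `4 D_WJ <DT_J>` in 2D) followed by one isotropic jump of
#' mean-squared length `<L^2> = L_T^2 + 2 L_T L_J + 2 L_J^2` taking `tau_J`
#' seconds, giving
#' `D_eff = (4 D_WJ <DT_J> + <L^2>) / (4 (<DT_J> + tau_J))`.
#'
#' @inheritParams mean_waiting_time
#' @return Effective diffusivity, um^2/s (equals `D0` when `N_c = 0`).
#' @export
#' @examples
#' deff_jump_diffusion(model_params(), 1)  # ~ 1.72 um^2/s
deff_jump_diffusion <- function(params, N_c) {
  stopifnot(inherits(params, "model_params"))
  if (any(N_c < 0)) stop("N_c must be nonnegative", call. = FALSE)
  D_WJ <- params$D0 + params$alpha_WJ * N_c
  mw <- mean_waiting_time(N_c, params)
  EL2 <- params$L_T^2 + 2 * params$L_T * params$L_J + 2 * params$L_J^2
  ifelse(is.infinite(mw), D_WJ,
         (4 * D_WJ * mw + EL2) / (4 * (mw + params$tau_J)))
}

# reproducible per-track stream: seed derived from (master seed, track index)
.track_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 999983 * as.numeric(i)) %%
               2147483647)
}

.sim_one <- function(i, params, config, D_WJ, p_jump, n_steps, v_sed, H,
                     walls, prefix = "track") {
  set.seed(.track_seed(config$seed, i))
  raw <- sim_track_cpp(D_WJ, p_jump, params$L_T, params$L_J, params$tau_J,
                       config$dt, n_steps, config$save_every,
                       config$jump_mode == "instant", v_sed,
                       if (walls) H else 0, walls, config$record_truth)
  id <- sprintf("%s%05d", prefix, i)
  dt_frame <- config$dt * config$save_every
  n_save <- length(raw$x)
  track <- data.table::data.table(
    track_id = id, frame = 0:(n_save - 1L),
    t_s = (0:(n_save - 1L)) * dt_frame, x_um = raw$x, y_um = raw$y)
  if (config$record_truth)
    track$state <- c("diffusing", "jumping")[raw$state + 1L]
  events <- data.table::data.table(
    track_id = rep(id, length(raw$t_start)),
    t_start_s = raw$t_start, t_end_s = raw$t_end,
    length_um = raw$length, duration_s = raw$t_end - raw$t_start,
    theta_rad = raw$theta)
  list(track = track, events = events)
}

.simulate_core <- function(params, config, v_sed, H, walls, prefix = "track") {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  if (config$dt >= params$tau_J)
    stop("dt must be smaller than the jump duration tau_J", call. = FALSE)
  mw <- mean_waiting_time(config$N_c, params)
  p_jump <- if (is.finite(mw)) config$dt / mw else 0
  if (p_jump >= 1)
    stop("dt / <DT_J> must be below 1 for the acceptance-rejection scheme",
         call. = FALSE)
  if (v_sed < 0) stop("v_sed must be nonnegative", call. = FALSE)
  if (walls && (!is.numeric(H) || H <= 0))
    stop("H must be positive", call. = FALSE)
  D_WJ <- params$D0 + params$alpha_WJ * config$N_c
  n_steps <- round(config$duration / config$dt)
  out <- lapply(seq_len(config$n_tracks), .sim_one, params = params,
                config = config, D_WJ = D_WJ, p_jump = p_jump,
                n_steps = n_steps, v_sed = v_sed, H = H, walls = walls,
                prefix = prefix)
  tracks <- as.data.frame(data.table::rbindlist(lapply(out, `[[`, "track")))
  events <- as.data.frame(data.table::rbindlist(lapply(out, `[[`, "events")))
  list(tracks = tracks, events = events)
}

#' Simulate jump-diffusion trajectories
#'
#' Integrates the 2D jump-diffusion process: isotropic Brownian motion with
#' diffusivity `D_WJ = D0 + alpha_WJ * N_c`, interrupted by entrainment jumps.
#' At every diffusing step one uniform random number is drawn; if it falls in
#' the centred interval of width `dt / <DT_J>` the particle starts a jump of
#' length drawn from the shifted-exponential law along a uniformly random
#' direction, moving ballistically at speed `L / tau_J` for exactly `tau_J`
#' seconds with the Brownian component switched off.  A new initiation is only
#' tested after the running jump has completed.  Identical `(params, config)`
#' including the seed give bitwise-identical output.
#'
#' @param params A [model_params()] object.
#' @param config A [sim_config()] object.
#' @return `simulate_ensemble` returns `list(tracks, events)`: `tracks` is a
#'   data.frame with columns `track_id, frame, t_s, x_um, y_um[, state]` and
#'   `events` the ground-truth jump list with columns
#'   `track_id, t_start_s, t_end_s, length_um, duration_s, theta_rad`
#'   (`length_um` is the drawn end-to-end length; a jump cut off by the end of
#'   the track has its `t_end_s` censored there).  `simulate_trajectory`
#'   returns the same for a single track.
#' @seealso [simulate_sedimenting_ensemble()], [deff_jump_diffusion()]
#' @export
#' @examples
#' sim <- simulate_ensemble(model_params(),
#'   sim_config(n_tracks = 2, duration = 50, N_c = 2, save_every = 10, seed = 7))
#' head(sim$tracks); sim$events
simulate_ensemble <- function(params, config) {
  .simulate_core(params, config, v_sed = 0, H = NULL, walls = FALSE)
}

#' @rdname simulate_ensemble
#' @export
simulate_trajectory <- function(params, config) {
  config$n_tracks <- 1L
  .simulate_core(params, config, v_sed = 0, H = NULL, walls = FALSE)
}

#' Simulate a sedimenting, wall-confined jump-diffusion ensemble
#'
#' Same dynamics as [simulate_ensemble()] plus a constant downward drift
#' `-v_sed` on the vertical (`y`) coordinate and mirror-reflecting walls at
#' `y = 0` and `y = H` (jump segments are reflected too).  Initial heights are
#' uniform on `[0, H]`.  At steady state the height distribution balances
#' sedimentation against effective diffusion, giving an exponential profile
#' with gravitational length `D_eff / v_sed` (for `l_g` well below `H`).
#'
#' @inheritParams simulate_ensemble
#' @param v_sed Sedimentation speed, um/s (nonnegative).
#' @param H Channel height, um.
#' @return `list(tracks, events)` as in [simulate_ensemble()]; `y_um` is the
#'   height in `[0, H]`.
#' @export
simulate_sedimenting_ensemble <- function(params, config, v_sed, H) {
  .simulate_core(params, config, v_sed = v_sed, H = H, walls = TRUE,
                 prefix = "sed")
}
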