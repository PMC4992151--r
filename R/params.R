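#' Microscopic parameters of the jump-diffusion model
#'
#' Container for the constants describing the motion of a passive micron-sized
#' particle in a dilute suspension of swimming microalgae.  The particle
#' alternates enhanced Brownian diffusion (thermal diffusivity plus a far-field
#' contribution linear in cell concentration) with rare ballistic entrainment
#' jumps initiated as a Poisson process.  Defaults describe 1 um polystyrene
#' beads among *Chlamydomonas reinhardtii* in a thin quasi-2D chamber.
#'
#' Units are micrometres and seconds throughout; cell concentrations `N_c` are
#' in units of 10^6 cells/ml (one such unit equals 1e-6 um^-3).
#'
#' @param D0 Thermal diffusivity of the particle, um^2/s.
#' @param alpha_WJ Slope of the far-field-enhanced diffusivity,
#'   (um^2/s)/(10^6 cells/ml): the diffusing-state diffusivity is
#'   `D_WJ = D0 + alpha_WJ * N_c`.
#' @param L_T Jump-length threshold, um.  Only entrainment events longer than
#'   `L_T` are modelled as explicit jumps; the compounded effect of shorter
#'   ones is folded into `alpha_WJ`.
#' @param L_J Characteristic length, um, of the exponential distribution of
#'   jump lengths in excess of `L_T`.
#' @param tau_J Jump duration, s (deterministic: the observed duration
#'   distribution is much tighter than the length distribution).
#' @param A_wait Coefficient, s*(10^6 cells/ml), of the hyperbolic waiting law
#'   `<DT_J> = A_wait / N_c` for the mean diffusive time between jumps.
#' @param v Mean swimming speed of the algae, um/s.
#'
#' @return An object of class `model_params` (a validated named list).
#' @seealso [sim_config()], [simulate_ensemble()], [mean_waiting_time()]
#' @export
#' @examples
#' p <- model_params()
#' p$D0 + p$alpha_WJ * 2   # diffusing-state diffusivity at N_c = 2
model_params <- function(D0 = 0.40, alpha_WJ = 0.33, L_T = 7.5, L_J = 7.5,
                         tau_J = 1.7, A_wait = 68.2, v = 49.1) {
  p <- list(D0 = D0, alpha_WJ = alpha_WJ, L_T = L_T, L_J = L_J,
            tau_J = tau_J, A_wait = A_wait, v = v)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("model_params field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Jump-diffusion model parameters (um, s, 10^6 cells/ml):\n")
  cat(sprintf("  D0 = %.3g um^2/s   alpha_WJ = %.3g   v = %.3g um/s\n",
              x$D0, x$alpha_WJ, x$v))
  cat(sprintf("  jumps: L_T = %.3g um, L_J = %.3g um, tau_J = %.3g s, A_wait = %.3g s\n",
              x$L_T, x$L_J, x$tau_J, x$A_wait))
  invisible(x)
}

#' Simulation configuration for the jump-diffusion integrator
#'
#' @param dt Integration step, s.  Must be positive and smaller than the jump
#'   duration; `dt / <DT_J>` must be below 1 for the acceptance-rejection jump
#'   initiation to be a valid Poisson scheme (checked at simulation time).
#' @param duration Track duration, s.
#' @param n_tracks Number of independent trajectories.
#' @param N_c Algal concentration, 10^6 cells/ml (0 gives pure Brownian motion).
#' @param seed Master seed; each track gets its own reproducible stream derived
#'   from `(seed, track index)`.
#' @param record_truth Record the per-frame motion state (diffusing/jumping)
#'   alongside positions.
#' @param save_every Record every `save_every`-th integration step (the initial
#'   position is always recorded), so the frame interval is `dt * save_every`.
#' @param jump_mode `"ballistic"` (straight constant-speed segments lasting
#'   `tau_J`) or `"instant"` (the whole jump displacement applied in one step),
#'   the latter useful for studying the jump-duration dependence.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.004, duration = 2000, n_tracks = 1000, N_c = 1,
                       seed = 1, record_truth = TRUE, save_every = 1L,
                       jump_mode = c("ballistic", "instant")) {
  jump_mode <- match.arg(jump_mode)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.numeric(n_tracks) || n_tracks < 1)
    stop("n_tracks must be >= 1", call. = FALSE)
  if (!is.numeric(N_c) || N_c < 0)
    stop("N_c must be nonnegative", call. = FALSE)
  save_every <- as.integer(save_every)
  if (save_every < 1L) stop("save_every must be >= 1", call. = FALSE)
  structure(list(dt = dt, duration = duration, n_tracks = as.integer(n_tracks),
                 N_c = N_c, seed = as.integer(seed),
                 record_truth = isTRUE(record_truth),
                 save_every = save_every, jump_mode = jump_mode),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d tracks x %.6g s, dt = %.4g s (saved every %d steps), N_c = %.3g, seed = %d, %s jumps\n",
    x$n_tracks, x$duration, x$dt, x$save_every, x$N_c, x$seed, x$jump_mode))
  invisible(x)
}

#' Two-state continuum-model parameters
#'
#' Parameters of the two-population continuum description: a diffusing
#' population with diffusivity `D_WJ` exchanging with a ballistic population
#' moving at constant speed `u` in a uniformly distributed direction, with
#' constant switching rates `lambda_d` (diffusing to ballistic) and `lambda_b`
#' (ballistic to diffusing).
#'
#' @param D_WJ Diffusivity of the diffusing population, um^2/s.
#' @param u Speed of the ballistic population, um/s.
#' @param lambda_d Rate of entering the ballistic state, 1/s.
#' @param lambda_b Rate of leaving the ballistic state, 1/s (must be positive;
#'   mean run length is `u / lambda_b`).
#'
#' @return An object of class `continuum_params`.
#' @seealso [deff_longtime()], [msd_twostate()], [stationary_fractions()]
#' @export
continuum_params <- function(D_WJ, u, lambda_d, lambda_b) {
  vals <- c(D_WJ = D_WJ, u = u, lambda_d = lambda_d, lambda_b = lambda_b)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("continuum_params fields must be finite and nonnegative", call. = FALSE)
  if (lambda_b <= 0) stop("lambda_b must be positive", call. = FALSE)
  structure(as.list(vals), class = "continuum_params")
}

#' @export
print.continuum_params <- function(x, ...) {
  cat(sprintf(
    "Two-state continuum params: D_WJ = %.4g um^2/s, u = %.4g um/s, lambda_d = %.4g /s, lambda_b = %.4g /s\n",
    x$D_WJ, x$u, x$lambda_d, x$lambda_b))
  invisible(x)
}

.model_param_names <- c("D0", "alpha_WJ", "L_T", "L_J", "tau_J", "A_wait", "v")

#' Read or write model parameters as YAML
#'
#' The YAML file holds the [model_params()] field names; unknown keys are
#' rejected, missing keys fall back to the defaults.
#'
#' @param path File path.
#' @param params A `model_params` object (for writing).
#' @return `read_params` returns a `model_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("parameter file must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(vals), .model_param_names)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
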