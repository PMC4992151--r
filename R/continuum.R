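#' Stationary state fractions of the two-state model
#'
#' Fractions of particles in the diffusing (`x_d`) and ballistic (`x_b`)
#' states at stationarity of the switching dynamics:
#' `x_d = lambda_b / (lambda_d + lambda_b)`, `x_b = 1 - x_d`.
#'
#' @param p A [continuum_params()] object.
#' @return Named numeric vector `c(x_d, x_b)`.
#' @export
#' @examples
#' stationary_fractions(continuum_params(0.73, 15 / 1.7, 1 / 68.2, 1 / 1.7))
stationary_fractions <- function(p) {
  stopifnot(inherits(p, "continuum_params"))
  s <- p$lambda_d + p$lambda_b
  if (s <= 0) stop("lambda_d + lambda_b must be positive", call. = FALSE)
  c(x_d = p$lambda_b / s, x_b = p$lambda_d / s)
}

#' Long-time effective diffusivity of the two-state model
#'
#' Closed form `D_eff = x_d * (D_WJ + lambda_d * u^2 / (2 * lambda_b^2))`,
#' equivalently `x_d * D_WJ + x_b * u^2 / (2 * lambda_b)`: the diffusing-state
#' contribution plus the run-and-tumble contribution of exponential ballistic
#' runs of mean duration `1 / lambda_b`.  It reduces to `D_WJ` when
#' `lambda_d = 0` and tends to `u^2 / (2 * lambda_b)` as `lambda_d` grows (at
#' fixed `D_WJ`), and agrees with the long-time slope of [msd_twostate()] and
#' with direct two-state Monte-Carlo simulation.
#'
#' @param p A [continuum_params()] object.
#' @return Effective diffusivity, um^2/s.
#' @export
deff_longtime <- function(p) {
  stopifnot(inherits(p, "continuum_params"))
  x <- stationary_fractions(p)
  unname(x["x_d"] * (p$D_WJ + p$lambda_d * p$u^2 / (2 * p$lambda_b^2)))
}

#' Low-concentration effective diffusivity
#'
#' In the dilute regime (`lambda_d << lambda_b`) the effective diffusivity
#' separates into thermal, far-field and entrainment contributions:
#' `D_eff = D0 + alpha_WJ * N_c + lambda_d * <L^2> / 4` with
#' `lambda_d = gamma * v * N_c * 1e-6` and `<L^2> = 2 <L>^2` for exponentially
#' distributed jump lengths — the freely jointed chain picture, where bonds of
#' exponential mean length `<L>` are added at the encounter rate.  The result
#' contains no dependence on the jump duration.
#'
#' @param D0 Thermal diffusivity, um^2/s.
#' @param alpha_WJ Far-field slope, (um^2/s)/(10^6 cells/ml).
#' @param gamma Entrainment cross-section, um^2.
#' @param v Swimmer speed, um/s.
#' @param N_c Cell concentration, 10^6 cells/ml.
#' @param mean_L Mean jump length `<L>`, um.
#' @param tau_J Optional jump duration, s, used only to check the dilute-regime
#'   assumption (`lambda_d / lambda_b < 0.1`; a warning is issued otherwise).
#' @return Effective diffusivity, um^2/s (`D0` at `N_c = 0`).
#' @export
#' @examples
#' deff_lowconc(0.40, 0.33, 299, 49.1, 1, 12.6)
deff_lowconc <- function(D0, alpha_WJ, gamma, v, N_c, mean_L, tau_J = NULL) {
  vals <- c(D0, alpha_WJ, gamma, v, N_c, mean_L)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("inputs must be finite and nonnegative", call. = FALSE)
  lambda_d <- gamma * v * N_c * 1e-6
  if (!is.null(tau_J) && lambda_d * tau_J > 0.1)
    warning("lambda_d is not small compared with lambda_b; ",
            "the dilute expansion may be inaccurate", call. = FALSE)
  D0 + alpha_WJ * N_c + lambda_d * mean_L^2 / 2
}

#' Entrainment cross-section
#'
#' Inverts the encounter-rate relation `lambda_d = gamma * v * N_c` (with
#' `N_c` in 10^6 cells/ml, i.e. 1e-6 um^-3) using the waiting-law coefficient
#' `A_wait` (`lambda_d = N_c / A_wait`), giving
#' `gamma = 1 / (A_wait * v * 1e-6)` in um^2: the effective area around a
#' swimmer's line of motion within which a particle gets entrained.
#'
#' @param A_wait Waiting-law coefficient, s*(10^6 cells/ml).
#' @param v Swimmer speed, um/s.
#' @return Cross-section, um^2.
#' @export
#' @examples
#' entrainment_cross_section(68.2, 49.1)  # ~ 299 um^2
entrainment_cross_section <- function(A_wait, v) {
  if (A_wait <= 0) stop("A_wait must be positive", call. = FALSE)
  if (v <= 0) stop("v must be positive", call. = FALSE)
  1 / (A_wait * v * 1e-6)
}

#' Mean-square displacement of the two-state continuum model
#'
#' Integrates the closed set of moment equations implied by the two-population
#' transport equations: with state probabilities `p_d, p_b`, second spatial
#' moments `M_d, M_b` restricted to each state, and the position-direction
#' moment `C` of the ballistic population,
#' \deqn{M_d' = 4 D_{WJ} p_d - \lambda_d M_d + \lambda_b M_b}
#' \deqn{M_b' = 2 u C + \lambda_d M_d - \lambda_b M_b}
#' \deqn{C' = u p_b - \lambda_b C}
#' starting from the stationary state fractions at the origin, so
#' `MSD(t) = M_d + M_b`.  The short-time slope is `4 x_d D_WJ`; the long-time
#' slope is `4 deff_longtime(p)`.
#'
#' @param p A [continuum_params()] object.
#' @param times Positive, strictly increasing evaluation times, s.
#' @param rtol,atol Integrator tolerances passed to [deSolve::ode()].
#' @return Numeric vector of MSD values (um^2) at `times`, with attribute
#'   `"conservation"` giving the largest deviation of `p_d + p_b` from 1.
#' @export
msd_twostate <- function(p, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "continuum_params"))
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("times must be positive and strictly increasing", call. = FALSE)
  x <- stationary_fractions(p)
  y0 <- c(pd = unname(x["x_d"]), pb = unname(x["x_b"]), Md = 0, Mb = 0, C = 0)
  rhs <- function(t, y, parms) {
    list(c(
      pd = -p$lambda_d * y["pd"] + p$lambda_b * y["pb"],
      pb = p$lambda_d * y["pd"] - p$lambda_b * y["pb"],
      Md = 4 * p$D_WJ * y["pd"] - p$lambda_d * y["Md"] + p$lambda_b * y["Mb"],
      Mb = 2 * p$u * y["C"] + p$lambda_d * y["Md"] - p$lambda_b * y["Mb"],
      C = p$u * y["pb"] - p$lambda_b * y["C"]))
  }
  sol <- deSolve::ode(y0, c(0, times), rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (!is.matrix(sol) || nrow(sol) != length(times) + 1 ||
      any(!is.finite(sol)))
    stop("moment-ODE integration failed (lambda_d = ", p$lambda_d,
         ", lambda_b = ", p$lambda_b, ", u = ", p$u, ")", call. = FALSE)
  msd <- sol[-1, "Md"] + sol[-1, "Mb"]
  attr(msd, "conservation") <- max(abs(sol[, "pd"] + sol[, "pb"] - 1))
  msd
}

#' Effective diffusivity as a function of cell concentration
#'
#' Maps a concentration grid through the two-state closed form with the
#' microscopic parameter mapping `lambda_d = N_c / A_wait`,
#' `lambda_b = 1 / tau_J`, `u = (L_T + L_J) / tau_J` (mean run length and
#' duration preserved) and `D_WJ = D0 + alpha_WJ * N_c`.  The curve grows
#' linearly at low concentration and saturates once the waiting time becomes
#' comparable to the jump duration, approaching
#' `u^2 / (2 lambda_b) + alpha_WJ * A_wait * lambda_b`.
#'
#' @param params A [model_params()] object.
#' @param N_c_grid Positive concentrations, 10^6 cells/ml.
#' @param tau_J Jump duration, s (defaults to `params$tau_J`; override to study
#'   the duration dependence of the plateau).
#' @return Numeric vector of effective diffusivities, um^2/s.
#' @export
deff_vs_concentration <- function(params, N_c_grid, tau_J = params$tau_J) {
  stopifnot(inherits(params, "model_params"))
  if (any(N_c_grid <= 0)) stop("N_c_grid must be positive", call. = FALSE)
  u <- (params$L_T + params$L_J) / tau_J
  vapply(N_c_grid, function(nc) {
    deff_longtime(continuum_params(
      D_WJ = params$D0 + params$alpha_WJ * nc, u = u,
      lambda_d = nc / params$A_wait, lambda_b = 1 / tau_J))
  }, numeric(1))
}
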