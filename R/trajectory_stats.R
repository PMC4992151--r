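.check_tracks <- function(tracks) {
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(tracks))
  if (length(miss))
    stop("tracks table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tracks) == 0) stop("tracks table is empty", call. = FALSE)
  invisible(tracks)
}

# uniform frame interval of one track (errors if spacing is not uniform)
.frame_interval <- function(t_s, id = "?") {
  d <- diff(t_s)
  if (length(d) == 0) stop("track ", id, " has fewer than 2 frames", call. = FALSE)
  dtf <- stats::median(d)
  if (any(abs(d - dtf) > 1e-6 * max(dtf, 1)))
    stop("non-uniform frame spacing in track ", id, call. = FALSE)
  dtf
}

.split_tracks <- function(tracks) split(tracks, tracks$track_id, drop = TRUE)

#' Ensemble mean-square displacement
#'
#' Time-averaged MSD over all overlapping position pairs within each track,
#' ensemble-averaged across tracks weighted by pair counts.  Both coordinates
#' contribute (2D MSD), so for pure diffusion `MSD(t) = 4 D t`.
#'
#' @param tracks Tracks data.frame (`track_id, frame, t_s, x_um, y_um`), all
#'   tracks sharing one frame interval.
#' @param max_lag Largest lag to evaluate, s (must not exceed the longest
#'   track).
#' @param lags Optional numeric vector of lags (s, multiples of the frame
#'   interval) to evaluate; default every frame lag up to `max_lag`.
#' @return An object of class `msd_result`: data.frame with columns
#'   `lag_s`, `msd` (um^2) and `n_pairs`, including the exact `MSD(0) = 0` row.
#' @seealso [fit_diffusivity()]
#' @export
compute_msd <- function(tracks, max_lag, lags = NULL) {
  .check_tracks(tracks)
  parts <- .split_tracks(tracks)
  dtf <- .frame_interval(parts[[1]]$t_s, names(parts)[1])
  for (nm in names(parts)) {
    d <- .frame_interval(parts[[nm]]$t_s, nm)
    if (abs(d - dtf) > 1e-9 * dtf)
      stop("tracks do not share a common frame interval", call. = FALSE)
  }
  longest <- max(vapply(parts, nrow, 1L))
  if (max_lag > (longest - 1L) * dtf + 1e-9)
    stop("max_lag exceeds the longest track", call. = FALSE)
  if (is.null(lags)) {
    klags <- seq_len(floor(max_lag / dtf + 1e-9))
  } else {
    klags <- round(lags / dtf)
    if (any(abs(klags * dtf - lags) > 1e-6 * dtf))
      stop("lags must be multiples of the frame interval", call. = FALSE)
    klags <- sort(unique(klags[klags >= 1]))
  }
  sum_sq <- numeric(length(klags))
  n_pairs <- numeric(length(klags))
  for (tr in parts) {
    a <- msd_accumulate_cpp(tr$x_um, tr$y_um, as.integer(klags))
    sum_sq <- sum_sq + a$sum_sq
    n_pairs <- n_pairs + a$n_pairs
  }
  keep <- n_pairs >= 1
  out <- data.frame(lag_s = c(0, klags[keep] * dtf),
                    msd = c(0, sum_sq[keep] / n_pairs[keep]),
                    n_pairs = c(sum(vapply(parts, nrow, 1L)), n_pairs[keep]))
  class(out) <- c("msd_result", "data.frame")
  out
}

#' Fit an effective diffusivity to an MSD curve
#'
#' Ordinary least squares of MSD against lag on a window, with a free
#' intercept that absorbs localization noise and short-time (finite jump
#' duration) offsets.  The 2D convention `MSD = 4 D t` gives
#' `D_eff = slope / 4`.
#'
#' @param msd An `msd_result` from [compute_msd()].
#' @param window Fit window `(lo, hi)` in seconds.  The default 2-20 s sits
#'   beyond the jump duration so the asymptotic slope is sampled, while keeping
#'   good pair statistics on a few-hundred-second track.
#' @return An object of class `diffusivity_fit`: list with `D_eff`, `stderr`
#'   (both um^2/s), `intercept` (um^2), `window`, `n_lags`.
#' @export
fit_diffusivity <- function(msd, window = c(2, 20)) {
  stopifnot(inherits(msd, "msd_result"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing pair of lags", call. = FALSE)
  sel <- msd$lag_s >= window[1] - 1e-9 & msd$lag_s <= window[2] + 1e-9 &
    msd$lag_s > 0
  if (sum(sel) < 3)
    stop("fit window must contain at least 3 lag points", call. = FALSE)
  fit <- stats::lm(msd ~ lag_s, data = msd[sel, ])
  co <- summary(fit)$coefficients
  structure(list(D_eff = unname(co["lag_s", "Estimate"]) / 4,
                 stderr = unname(co["lag_s", "Std. Error"]) / 4,
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 window = window, n_lags = sum(sel)),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("D_eff = %.4g +/- %.2g um^2/s (intercept %.3g um^2, window %g-%g s, %d lags)\n",
              x$D_eff, x$stderr, x$intercept, x$window[1], x$window[2], x$n_lags))
  invisible(x)
}

#' Jump-detection parameters
#'
#' Thresholds for segmenting entrainment jumps out of noisy tracks.  The
#' defaults separate the windowed speed of Brownian motion at the thermal
#' diffusivity (~1.8 um/s over 0.5 s) from that of a typical jump
#' (~8.8 um/s for a 15 um jump lasting 1.7 s).
#'
#' @param smooth_window Window, s, over which the displacement is measured to
#'   form a windowed speed.
#' @param speed_threshold Windowed speed above which frames are candidate jump
#'   frames, um/s.
#' @param merge_gap Candidate runs separated by less than this, s, are merged.
#' @param min_length Minimum end-to-end displacement of a reported event, um.
#' @return An object of class `jump_detection_params`.
#' @export
jump_detection_params <- function(smooth_window = 0.5, speed_threshold = 4.0,
                                  merge_gap = 0.2, min_length = 3.0) {
  vals <- c(smooth_window = smooth_window, speed_threshold = speed_threshold,
            merge_gap = merge_gap, min_length = min_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("jump detection parameters must be positive", call. = FALSE)
  structure(as.list(vals), class = "jump_detection_params")
}

.detect_jumps_one <- function(tr, det) {
  dtf <- .frame_interval(tr$t_s, tr$track_id[1])
  if (dtf > det$smooth_window / 2 + 1e-9)
    stop("frame interval must be <= smooth_window / 2", call. = FALSE)
  n <- nrow(tr)
  w <- max(1L, round(det$smooth_window / dtf))
  if (n <= w) stop("track ", tr$track_id[1], " shorter than smooth_window",
                   call. = FALSE)
  x <- tr$x_um; y <- tr$y_um
  i0 <- seq_len(n - w)
  disp <- sqrt((x[i0 + w] - x[i0])^2 + (y[i0 + w] - y[i0])^2)
  speed <- disp / (w * dtf)
  above <- speed > det$speed_threshold
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than merge_gap (in window-start indices)
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if ((runs[k, 1] - last[2] - 1L) * dtf < det$merge_gap)
        keep[[length(keep)]] <- c(last[1], runs[k, 2])
      else keep[[length(keep) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }
  # event boundaries sit at the centres of the first and last qualifying
  # windows, so the time extent tracks the above-threshold run; the candidate
  # filter uses the displacement across that extent, which stays small for
  # brief Brownian exceedances.  The reported end-to-end length spans the full
  # smoothing support of the run, which is unbiased for ballistic segments.
  hw <- as.integer(round(w / 2))
  ev <- cbind(runs[, 1] + hw, pmin(runs[, 2] + hw, n))
  L_run <- sqrt((x[ev[, 2]] - x[ev[, 1]])^2 + (y[ev[, 2]] - y[ev[, 1]])^2)
  full <- cbind(runs[, 1], pmin(runs[, 2] + w, n))
  ok <- L_run >= det$min_length
  if (!any(ok)) return(NULL)
  dx <- x[full[ok, 2]] - x[full[ok, 1]]
  dy <- y[full[ok, 2]] - y[full[ok, 1]]
  data.table::data.table(
    track_id = tr$track_id[1],
    t_start_s = tr$t_s[ev[ok, 1]], t_end_s = tr$t_s[ev[ok, 2]],
    length_um = sqrt(dx^2 + dy^2),
    duration_s = tr$t_s[ev[ok, 2]] - tr$t_s[ev[ok, 1]],
    theta_rad = atan2(dy, dx))
}

#' Detect entrainment jumps in particle tracks
#'
#' Computes a windowed speed (displacement over `smooth_window` divided by the
#' window) along each track, finds contiguous runs above `speed_threshold`,
#' merges runs separated by less than `merge_gap`, and keeps runs whose
#' displacement is at least `min_length`.  An event's time extent runs between
#' the centres of the first and last qualifying windows (so `duration_s`
#' tracks the above-threshold run), while its reported `length_um` is the
#' end-to-end displacement over the full smoothing support of the run, which
#' is unbiased for ballistic segments.  Events are sorted by start time and
#' non-overlapping.  The detector only uses inter-frame distances, so it is
#' invariant under global translation and rotation of the tracks.
#'
#' @param tracks Tracks data.frame (one or several tracks).
#' @param det A [jump_detection_params()] object.
#' @return Events data.frame with columns
#'   `track_id, t_start_s, t_end_s, length_um, duration_s, theta_rad`
#'   (zero rows when nothing is detected).
#' @export
detect_jumps <- function(tracks, det = jump_detection_params()) {
  .check_tracks(tracks)
  stopifnot(inherits(det, "jump_detection_params"))
  out <- lapply(.split_tracks(tracks), .detect_jumps_one, det = det)
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(track_id = character(), t_start_s = numeric(),
                      t_end_s = numeric(), length_um = numeric(),
                      duration_s = numeric(), theta_rad = numeric()))
  as.data.frame(data.table::rbindlist(out))
}

#' Summary statistics of jump events
#'
#' Mean end-to-end length and duration over all events, plus the
#' maximum-likelihood estimate of the exponential characteristic length of the
#' tail above `L_T`: `L_J_hat = mean(L - L_T | L >= L_T)` (memorylessness makes
#' this estimate insensitive to the cut).
#'
#' @param events Events data.frame (from [detect_jumps()] or simulator truth).
#' @param L_T Threshold length, um.
#' @return List with `mean_L`, `mean_tau`, `L_J_hat`, `n`, `n_above`.
#'   `L_J_hat` is `NA` (with a warning) when no event reaches `L_T`.
#' @export
jump_statistics <- function(events, L_T = 7.5) {
  if (is.null(events) || nrow(events) == 0)
    stop("no events supplied", call. = FALSE)
  above <- events$length_um >= L_T
  L_J_hat <- if (any(above)) mean(events$length_um[above] - L_T) else {
    warning("no events with L >= L_T; L_J_hat undefined", call. = FALSE)
    NA_real_
  }
  list(mean_L = mean(events$length_um), mean_tau = mean(events$duration_s),
       L_J_hat = L_J_hat, n = nrow(events), n_above = sum(above))
}

#' Waiting-time statistics between jumps
#'
#' Two estimators of the mean waiting time between entrainment events.  The
#' unbiased one divides the total observed diffusive time (track time minus
#' in-jump time) by the total number of events; it is insensitive to the
#' finite track duration.  The naive one fits an exponential (maximum
#' likelihood, i.e. the sample mean) to the gaps between consecutive event
#' initiations observed within each track; finite tracks censor long gaps, so
#' this estimate is biased low.
#'
#' @param tracks Tracks data.frame (used for the total observed time).
#' @param events Events data.frame assigned to those tracks.
#' @return An object of class `waiting_time_stats`: list with `mean_unbiased`
#'   (s, `NA` with a warning when there are no events), `gaps` (s, possibly
#'   empty), `tau_exp_fit` (s, `NA` when fewer than one gap), `n_events`,
#'   `total_time`, `total_jump_time`.
#' @export
waiting_time_stats <- function(tracks, events) {
  .check_tracks(tracks)
  parts <- .split_tracks(tracks)
  total_time <- sum(vapply(parts, function(tr) max(tr$t_s) - min(tr$t_s), 1.0))
  n_ev <- if (is.null(events)) 0L else nrow(events)
  total_jump <- if (n_ev) sum(events$duration_s) else 0
  mean_unbiased <- if (n_ev) (total_time - total_jump) / n_ev else {
    warning("no events: unbiased mean waiting time undefined", call. = FALSE)
    NA_real_
  }
  gaps <- numeric(0)
  if (n_ev) {
    for (ev in split(events$t_start_s, events$track_id))
      if (length(ev) > 1) gaps <- c(gaps, diff(sort(ev)))
  }
  tau_exp_fit <- if (length(gaps)) mean(gaps) else NA_real_
  structure(list(mean_unbiased = mean_unbiased, gaps = gaps,
                 tau_exp_fit = tau_exp_fit, n_events = n_ev,
                 total_time = total_time, total_jump_time = total_jump),
            class = "waiting_time_stats")
}

#' @export
print.waiting_time_stats <- function(x, ...) {
  cat(sprintf("Waiting times: unbiased mean %.4g s (%d events over %.4g s);\n",
              x$mean_unbiased, x$n_events, x$total_time))
  cat(sprintf("  exponential fit to %d observed gaps: %.4g s (censoring-biased low)\n",
              length(x$gaps), x$tau_exp_fit))
  invisible(x)
}

#' Displacement probability density
#'
#' Pools one-dimensional displacements over both coordinates (the process is
#' isotropic) at a given lag and bins them into a normalized histogram.  With
#' `exclude_jumps`, displacement pairs whose time interval overlaps any event
#' of the same track are dropped, giving the jump-free distribution.
#'
#' @param tracks Tracks data.frame.
#' @param dt_lag Displacement interval, s (a multiple of the frame interval).
#' @param exclude_jumps Drop displacement pairs overlapping a jump.
#' @param events Events data.frame (required when `exclude_jumps = TRUE`).
#' @param breaks Passed to [graphics::hist()]-style binning: number of bins or
#'   a vector of break points.
#' @return An object of class `displacement_pdf`: list with `mids`, `density`
#'   (1/um, integrating to 1), `breaks`, `displacements` (the pooled raw
#'   displacements, um) and `n_pairs`.
#' @seealso [modified_kurtosis()]
#' @export
displacement_pdf <- function(tracks, dt_lag, exclude_jumps = FALSE,
                             events = NULL, breaks = 201) {
  .check_tracks(tracks)
  if (exclude_jumps && is.null(events))
    stop("events must be supplied when exclude_jumps = TRUE", call. = FALSE)
  parts <- .split_tracks(tracks)
  ev_by_track <- if (!is.null(events) && nrow(events))
    split(events, events$track_id) else list()
  disp <- vector("list", length(parts))
  j <- 0L
  for (tr in parts) {
    dtf <- .frame_interval(tr$t_s, tr$track_id[1])
    k <- round(dt_lag / dtf)
    if (k < 1 || abs(k * dtf - dt_lag) > 1e-6 * dtf)
      stop("dt_lag must be a positive multiple of the frame interval",
           call. = FALSE)
    n <- nrow(tr)
    if (n <= k) next
    i0 <- seq_len(n - k)
    keep <- rep(TRUE, length(i0))
    if (exclude_jumps) {
      ev <- ev_by_track[[tr$track_id[1]]]
      if (!is.null(ev) && nrow(ev)) {
        t0 <- tr$t_s[i0]
        for (e in seq_len(nrow(ev)))
          keep <- keep & !(t0 < ev$t_end_s[e] & (t0 + dt_lag) > ev$t_start_s[e])
      }
    }
    if (!any(keep)) next
    j <- j + 1L
    disp[[j]] <- c(tr$x_um[i0 + k][keep] - tr$x_um[i0][keep],
                   tr$y_um[i0 + k][keep] - tr$y_um[i0][keep])
  }
  d <- unlist(disp[seq_len(j)])
  if (!length(d)) stop("no valid displacement pairs after exclusion",
                       call. = FALSE)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(mids = h$mids, density = h$density, breaks = h$breaks,
                 displacements = d, n_pairs = length(d) / 2),
            class = "displacement_pdf")
}

#' Modified kurtosis of a displacement sample
#'
#' `kappa = <dx^4> / (3 <dx^2>^2) - 1` about the sample mean: zero in
#' expectation for Gaussian data, positive for heavy-tailed distributions
#' (1 for a Laplace law), so it measures the distance from the Gaussian limit.
#'
#' @param displacements Numeric vector, um (at least 4 values, nonzero
#'   variance).
#' @return Dimensionless kurtosis excess (relative to 3 times the squared
#'   second moment).
#' @export
modified_kurtosis <- function(displacements) {
  if (inherits(displacements, "displacement_pdf"))
    displacements <- displacements$displacements
  d <- displacements[is.finite(displacements)]
  if (length(d) < 4) stop("need at least 4 displacements", call. = FALSE)
  m <- mean(d)
  m2 <- mean((d - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  mean((d - m)^4) / (3 * m2^2) - 1
}

#' Rescale a diffusivity by the ratio of swimming speeds
#'
#' The active contribution to the diffusivity is proportional to the swimmers'
#' mean speed (active flux `v * N_c`), so measurements taken at different
#' swimming speeds are compared after multiplying by `v_reference /
#' v_experiment`.
#'
#' @param D Diffusivity, um^2/s.
#' @param v_experiment Mean swimming speed in the experiment, um/s.
#' @param v_reference Reference swimming speed, um/s.
#' @return Rescaled diffusivity, um^2/s.
#' @export
rescale_by_speed <- function(D, v_experiment, v_reference) {
  if (v_experiment <= 0 || v_reference <= 0)
    stop("speeds must be positive", call. = FALSE)
  D * v_reference / v_experiment
}
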