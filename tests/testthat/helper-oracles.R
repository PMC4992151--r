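# Independent oracles used to validate the package's estimators and closed
# forms.  These deliberately avoid the code paths they check.

# Long-time diffusivity of the two-state process by direct Monte Carlo:
# alternate exponentially distributed diffusive and ballistic episodes and
# return per-particle squared displacement / (4 T).
two_state_mc_deff <- function(D_WJ, u, lambda_d, lambda_b, n = 2000,
                              T_total = 2000) {
  d2 <- numeric(n)
  for (i in seq_len(n)) {
    t <- 0; x <- 0; y <- 0
    repeat {
      tau_d <- rexp(1, lambda_d)
      tau_d <- min(tau_d, T_total - t)
      x <- x + rnorm(1, sd = sqrt(2 * D_WJ * tau_d))
      y <- y + rnorm(1, sd = sqrt(2 * D_WJ * tau_d))
      t <- t + tau_d
      if (t >= T_total) break
      tau_b <- min(rexp(1, lambda_b), T_total - t)
      th <- runif(1, -pi, pi)
      x <- x + u * tau_b * cos(th)
      y <- y + u * tau_b * sin(th)
      t <- t + tau_b
      if (t >= T_total) break
    }
    d2[i] <- (x^2 + y^2) / (4 * T_total)
  }
  d2
}

# Mean observed gap between consecutive points of a Poisson process of rate
# `rate` when both points must fall inside a window of length T_win: the gap
# density is proportional to (T_win - g) * exp(-rate * g) on (0, T_win).
censored_gap_mean <- function(rate, T_win) {
  num <- stats::integrate(function(g) g * (T_win - g) * exp(-rate * g),
                          0, T_win, rel.tol = 1e-10)$value
  den <- stats::integrate(function(g) (T_win - g) * exp(-rate * g),
                          0, T_win, rel.tol = 1e-10)$value
  num / den
}

# Per-cycle renewal diffusivity of the jump-diffusion process, written out
# independently of the package implementation.
percycle_deff <- function(D0, alpha_WJ, L_T, L_J, tau_J, A_wait, N_c) {
  if (N_c == 0) return(D0)
  D_WJ <- D0 + alpha_WJ * N_c
  mw <- A_wait / N_c
  EL2 <- L_T^2 + 2 * L_T * L_J + 2 * L_J^2
  (4 * D_WJ * mw + EL2) / (4 * (mw + tau_J))
}

# Direct long-time diffusivity estimate from whole-track displacements
# (independent across tracks, so the standard error is clean).
direct_deff <- function(tracks) {
  per <- vapply(split(tracks, tracks$track_id), function(tr) {
    n <- nrow(tr)
    ((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2) /
      (4 * (tr$t_s[n] - tr$t_s[1]))
  }, numeric(1))
  c(D = mean(per), se = sd(per) / sqrt(length(per)))
}

# Greedy time-overlap matching of detected against true events within each
# track; returns recall and precision.
match_events <- function(truth, detected) {
  tp_truth <- 0L
  tp_det <- 0L
  for (id in unique(truth$track_id)) {
    tr_t <- truth[truth$track_id == id, ]
    tr_d <- detected[detected$track_id == id, , drop = FALSE]
    if (nrow(tr_d) == 0) next
    for (k in seq_len(nrow(tr_t))) {
      hit <- tr_d$t_start_s < tr_t$t_end_s[k] & tr_d$t_end_s > tr_t$t_start_s[k]
      if (any(hit)) tp_truth <- tp_truth + 1L
    }
    for (k in seq_len(nrow(tr_d))) {
      hit <- tr_t$t_start_s < tr_d$t_end_s[k] & tr_t$t_end_s > tr_d$t_start_s[k]
      if (any(hit)) tp_det <- tp_det + 1L
    }
  }
  c(recall = tp_truth / nrow(truth), precision = tp_det / nrow(detected))
}

# Build a tracks table holding only the start and end frame of each track
# (sufficient for total-time bookkeeping in waiting-time statistics).
skeleton_tracks <- function(n_tracks, duration) {
  ids <- sprintf("w%05d", seq_len(n_tracks))
  data.frame(track_id = rep(ids, each = 2), frame = rep(c(0L, 1L), n_tracks),
             t_s = rep(c(0, duration), n_tracks), x_um = 0, y_um = 0)
}

# Poisson-initiation event tables on finite tracks (no jump dead time).
poisson_event_tables <- function(rate, duration, n_tracks) {
  evs <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    n <- rpois(1, rate * duration)
    if (n == 0) next
    t0 <- sort(runif(n, 0, duration))
    evs[[i]] <- data.frame(track_id = sprintf("w%05d", i), t_start_s = t0,
                           t_end_s = t0, length_um = 10, duration_s = 0,
                           theta_rad = 0)
  }
  evs <- evs[!vapply(evs, is.null, TRUE)]
  do.call(rbind, evs)
}
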