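## Silencing-front tracking and the zero-velocity line. In the bistable
## regime a silenced domain nucleated at the left (pinned) end meets an
## active domain from the right; the titrated Sir pool self-adjusts the
## effective binding rates until the front is stochastically stationary.

#' Locate the silencing front in one configuration
#'
#' The front is the largest site index at which the moving-average
#' S-indicator (window `smooth_window`, truncated and renormalized at the
#' edges) is at least 0.5; if no site beyond the left pinned region
#' qualifies, the left pin boundary is returned. The estimate is clamped
#' to `[pin_left, length - pin_right]`.
#'
#' @param sample per-site state vector over [NUC_STATES] (or integer codes).
#' @param smooth_window odd moving-average window in sites.
#' @param pin_left,pin_right pinned-site counts of the generating run.
#' @return Integer site index.
#' @export
front_position <- function(sample, smooth_window = 11L,
                           pin_left = 10L, pin_right = 10L) {
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 1")
  s <- if (is.numeric(sample)) sample == 1L else sample == "S"
  L <- length(s)
  hw <- (smooth_window - 1L) / 2L
  cs <- cumsum(c(0, s))
  lo <- pmax(seq_len(L) - hw, 1L)
  hi <- pmin(seq_len(L) + hw, L)
  ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  idx <- which(ma >= 0.5)
  pos <- if (length(idx)) max(idx) else pin_left
  min(max(pos, pin_left), L - pin_right)
}

#' Front positions for every sample of a trajectory
#'
#' Applies [front_position()] to each stored configuration.
#'
#' @param trajectory a `lattice_trajectory`.
#' @param smooth_window odd moving-average window in sites.
#' @return Numeric vector of site indices, one per sample.
#' @export
front_positions <- function(trajectory, smooth_window = 11L) {
  vapply(seq_len(nrow(trajectory$samples)), function(i) {
    front_position(trajectory$samples[i, ], smooth_window,
                   trajectory$config$pin_left, trajectory$config$pin_right)
  }, numeric(1))
}

#' Front velocity from a position trace
#'
#' Least-squares slope of front position against event index, rescaled to
#' sites per million events, with its standard error. The front is a
#' slowly mixing, mean-reverting random walk held in place by the
#' titration feedback, so successive positions are strongly
#' autocorrelated and a whole-trace OLS error would be dishonestly small.
#' The slope and its error are therefore computed by batch-mean
#' regression: positions are averaged in `n_batches` consecutive blocks
#' and the line is fit across block means, so the error is driven by the
#' block-scale fluctuations rather than the fast within-block jitter.
#'
#' @param positions front positions per sample.
#' @param events event indices of the samples (same length).
#' @param n_batches number of blocks for the batch-mean regression.
#' @return List with `velocity` and `velocity_se` (sites per 1e6 events).
#' @export
front_velocity <- function(positions, events, n_batches = 10L) {
  if (length(positions) < 50L)
    stop("need at least 50 samples for a velocity estimate")
  if (length(events) != length(positions))
    stop("positions and events must have equal length")
  if (stats::var(positions) == 0)
    return(list(velocity = 0, velocity_se = 0))
  b <- cut(seq_along(positions), n_batches, labels = FALSE)
  py <- tapply(positions, b, mean)
  px <- tapply(events / 1e6, b, mean)
  fit <- stats::lm.fit(cbind(1, px), py)
  r <- fit$residuals
  xc <- px - mean(px)
  se <- if (max(abs(r)) < 1e-10) 0 else
    sqrt(sum(r^2) / (n_batches - 2L) / sum(xc^2))
  list(velocity = unname(fit$coefficients[2L]), velocity_se = se)
}

# velocity of one trajectory, plus boundary-absorption diagnostics
trajectory_velocity <- function(trajectory, smooth_window = 11L) {
  pos <- front_positions(trajectory, smooth_window)
  v <- front_velocity(pos, trajectory$event)
  L <- trajectory$config$length
  tail_pos <- pos[seq.int(max(1L, length(pos) - 9L), length(pos))]
  absorbed <- all(tail_pos <= trajectory$config$pin_left + 2L) ||
    all(tail_pos >= L - trajectory$config$pin_right - 2L)
  c(v, list(positions = pos, boundary_absorbed = absorbed))
}

#' Trace the zero-velocity line under Sir titration
#'
#' For each value of the swept rate parameter, runs the titrated lattice
#' simulation to (stochastic) stationarity and records how the finite Sir
#' pool has self-adjusted: the mean free-Sir density, the effective basal
#' Sir-binding level `effective_alpha = alpha_sir_basal * mean_rho_free /
#' rho_ref`, the front velocity with its standard error, and the
#' mean-field phase classification at the effective (titration-scaled)
#' rates. Stationarity is asserted as `|velocity| < max(v_threshold,
#' 2 * velocity_se)`; runs whose front reaches either pinned region are
#' flagged `boundary_absorbed` instead.
#'
#' @param sweep_param one of `"eta_sir2_coop"`, `"beta_dot1_coop"`,
#'   `"gamma_sas2"`.
#' @param sweep_values numeric vector of swept rate values.
#' @param config a [lattice_config()]; its seed (plus the point index)
#'   seeds each run.
#' @param params baseline [rate_params()].
#' @param n_events,burn_in,sample_every simulation schedule per point.
#' @param smooth_window front-estimator window, see [front_position()].
#' @param v_threshold stationarity threshold, sites per 1e6 events.
#' @param chain start each sweep point from the previous point's final
#'   configuration (adiabatic continuation, default); `FALSE` restarts
#'   every point from `config$initial_state`.
#' @return A `data.frame` with one row per swept value: `swept_param`,
#'   `swept_value`, `mean_rho_free`, `effective_alpha`, `velocity`,
#'   `velocity_se`, `stationary`, `boundary_absorbed`, `phase_class`.
#' @export
zero_velocity_line <- function(sweep_param, sweep_values, config, params,
                               n_events = 1e6, burn_in = 2e5,
                               sample_every = 2000, smooth_window = 11L,
                               v_threshold = 0.5, chain = TRUE) {
  sweep_param <- match.arg(sweep_param,
                           c("eta_sir2_coop", "beta_dot1_coop", "gamma_sas2"))
  if (!is.finite(params$n_sir_total))
    stop("zero-velocity tracing requires a finite Sir pool")
  rows <- vector("list", length(sweep_values))
  init <- config$initial_state
  for (i in seq_along(sweep_values)) {
    p_i <- do.call(update_params,
                   c(list(params), stats::setNames(list(sweep_values[i]),
                                                   sweep_param)))
    cfg_i <- config
    cfg_i$initial_state <- init
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + i - 1L
    tr <- run_gillespie(cfg_i, p_i, n_events = n_events, burn_in = burn_in,
                        sample_every = sample_every, titrate = TRUE)
    rows[[i]] <- zero_velocity_point(tr, sweep_param, sweep_values[i],
                                     smooth_window, v_threshold)
    if (chain) init <- sample_states(tr, nrow(tr$samples))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zero-velocity observables of one titrated stationary run
#'
#' Condenses a titrated trajectory into a single zero-velocity-line row:
#' front velocity with standard error, stationarity and
#' boundary-absorption flags, mean free-Sir density, the effective
#' Sir-binding level, and the mean-field phase class at the
#' titration-scaled rates. Used by [zero_velocity_line()] and by
#' fresh-seed confirmation runs.
#'
#' @param trajectory a titrated `lattice_trajectory`.
#' @param sweep_param,sweep_value labels recorded in the output row.
#' @inheritParams zero_velocity_line
#' @return One-row `data.frame`, see [zero_velocity_line()].
#' @export
zero_velocity_point <- function(trajectory, sweep_param, sweep_value,
                                smooth_window = 11L, v_threshold = 0.5) {
  tv <- trajectory_velocity(trajectory, smooth_window)
  mean_rho <- mean(trajectory$rho_free)
  params <- trajectory$params
  fac <- mean_rho / params$rho_ref
  eff <- phase_report(scale_titrated_rates(params, fac))
  data.frame(swept_param = sweep_param, swept_value = sweep_value,
             mean_rho_free = mean_rho,
             effective_alpha = params$alpha_sir_basal * fac,
             velocity = tv$velocity, velocity_se = tv$velocity_se,
             stationary = abs(tv$velocity) <
               max(v_threshold, 2 * tv$velocity_se),
             boundary_absorbed = tv$boundary_absorbed,
             phase_class = eff$phase_class)
}

#' Apply a titration factor to the Sir-binding rates
#'
#' Returns a parameter set whose basal and cooperative Sir-binding rates
#' are scaled by `fac = rho_free / rho_ref`, for mean-field analysis at
#' the effective (self-adjusted) rates of a titrated run.
#'
#' @param params a [rate_params()].
#' @param fac titration factor.
#' @export
scale_titrated_rates <- function(params, fac) {
  update_params(params,
                alpha_sir_basal = params$alpha_sir_basal * fac,
                delta_sir_coop = params$delta_sir_coop * fac)
}

#' Zero-velocity point by bisection on the Sir-binding scale
#'
#' Cross-check utility for [zero_velocity_line()]: instead of letting the
#' titration dynamics self-adjust, runs untitrated simulations at fixed
#' titration factors and bisects on the factor until the front velocity
#' changes sign (silenced-spreading vs active-spreading).
#'
#' @inheritParams zero_velocity_line
#' @param interval numeric length-2 bracket of titration factors.
#' @param n_iter bisection iterations.
#' @return List with `fac` (the zero-velocity titration factor) and the
#'   bracketing velocity table.
#' @export
zero_velocity_bisect <- function(config, params, interval = c(0.2, 1.2),
                                 n_iter = 8L, n_events = 5e5,
                                 burn_in = 1e5, sample_every = 2000,
                                 smooth_window = 11L) {
  vel_at <- function(fac, seed_shift) {
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + seed_shift
    tr <- run_gillespie(cfg, params, n_events = n_events, burn_in = burn_in,
                        sample_every = sample_every, titrate = FALSE,
                        rho_free_fixed = fac * params$rho_ref)
    trajectory_velocity(tr, smooth_window)$velocity
  }
  lo <- interval[1]; hi <- interval[2]
  v_lo <- vel_at(lo, 0L); v_hi <- vel_at(hi, 1L)
  if (sign(v_lo) == sign(v_hi))
    stop("front velocity does not change sign over the interval")
  hist <- data.frame(fac = c(lo, hi), velocity = c(v_lo, v_hi))
  for (k in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    v_mid <- vel_at(mid, k + 1L)
    hist <- rbind(hist, data.frame(fac = mid, velocity = v_mid))
    if (sign(v_mid) == sign(v_lo)) { lo <- mid; v_lo <- v_mid } else hi <- mid
  }
  list(fac = (lo + hi) / 2, history = hist)
}
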