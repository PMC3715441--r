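## Gillespie lattice simulation: R-side configuration and wrappers around
## the compiled event loop.

# channel table in the 0-based integer form the C++ core expects
channels_for_cpp <- function(params) {
  cc <- compile_channels(params)
  list(src = cc$src - 1L, tgt = cc$tgt - 1L,
       cm = ifelse(cc$cm > 0L, cc$cm - 1L, -1L),
       basal = cc$basal, coop = cc$coop, tit = as.integer(cc$tit))
}

# full centered weight vector (length 2*hw+1) for the compiled core
weights_for_cpp <- function(spec) {
  w <- neighbor_weights(spec)
  full <- numeric(2L * spec$half_width + 1L)
  names(full) <- seq.int(-spec$half_width, spec$half_width)
  full[names(w)] <- w
  unname(full)
}

#' Lattice simulation configuration
#'
#' A one-dimensional chromatin segment of `length` nucleosomes. The first
#' `pin_left` sites are pinned to S and the last `pin_right` sites to E,
#' never changing state; this mimics the telomeric nucleation center on
#' the left and a robustly active region on the right. Pinned sites still
#' exert cooperative influence as neighbors, and pinned S sites count
#' against the Sir pool.
#'
#' @param length number of nucleosomes.
#' @param pin_left,pin_right number of pinned sites at each end
#'   (`pin_left + pin_right < length`).
#' @param neighborhood a [neighborhood_spec()].
#' @param initial_state either a per-site state vector over [NUC_STATES]
#'   or a named preset: `"unmodified"` (interior all U), `"silenced"`
#'   (all S), `"active"` (all E), or `"half"` (left half S, right half E).
#' @param seed RNG seed used by [run_gillespie()]; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `"lattice_config"`.
#' @export
lattice_config <- function(length = 1000L, pin_left = 10L, pin_right = 10L,
                           neighborhood = neighborhood_spec(),
                           initial_state = "half", seed = NULL) {
  length <- as.integer(length)
  pin_left <- as.integer(pin_left); pin_right <- as.integer(pin_right)
  if (pin_left < 0 || pin_right < 0 || pin_left + pin_right >= length)
    stop("need pin_left + pin_right < length")
  stopifnot(inherits(neighborhood, "neighborhood_spec"))
  structure(list(length = length, pin_left = pin_left,
                 pin_right = pin_right, neighborhood = neighborhood,
                 initial_state = initial_state, seed = seed),
            class = "lattice_config")
}

initial_lattice_state <- function(config) {
  L <- config$length
  init <- config$initial_state
  if (is.character(init) && length(init) == 1L && init %in%
      c("unmodified", "silenced", "active", "half")) {
    st <- switch(init,
                 unmodified = rep("U", L),
                 silenced = rep("S", L),
                 active = rep("E", L),
                 half = rep(c("S", "E"), c(floor(L / 2), ceiling(L / 2))))
  } else {
    if (length(init) != L) stop("initial_state vector must have length ", L)
    st <- as.character(init)
    if (!all(st %in% NUC_STATES)) stop("invalid states in initial_state")
  }
  if (config$pin_left > 0) st[seq_len(config$pin_left)] <- "S"
  if (config$pin_right > 0) st[L - seq_len(config$pin_right) + 1L] <- "E"
  st
}

#' Run the Gillespie lattice simulation
#'
#' Direct-method stochastic simulation of the five-state model on the
#' pinned lattice. One reaction is executed per event ("time step"), with
#' reactions chosen with probabilities proportional to their propensities;
#' exponential waiting times are recorded alongside. After each event only
#' the propensities of sites within one neighborhood radius of the change
#' are updated. The free-Sir pool is updated on every S-creating or
#' S-destroying event; Sir-binding channels are scaled by
#' `rho_free / rho_ref` (the titration effect) when `titrate = TRUE`,
#' otherwise by the fixed factor `rho_free_fixed / rho_ref`.
#'
#' Sampling is event-indexed: configurations are recorded every
#' `sample_every` events after `burn_in` events. If the lattice freezes
#' (total propensity zero) the trajectory is flagged and the remaining
#' scheduled samples repeat the frozen configuration.
#'
#' @param config a [lattice_config()].
#' @param params a [rate_params()].
#' @param n_events total number of events (must exceed `burn_in`).
#' @param burn_in events discarded before sampling starts.
#' @param sample_every sampling stride in events.
#' @param titrate whether the finite Sir pool scales the binding rates.
#' @param rho_free_fixed constant ambient density used when
#'   `titrate = FALSE` (default `rho_ref`, i.e. nominal rates).
#' @return An object of class `"lattice_trajectory"`: `samples` (integer
#'   matrix, one row per sample, codes into [NUC_STATES]), `event`,
#'   `time`, `n_bound` and `rho_free` per sample, `event_count` (reactions
#'   executed), `frozen`, plus the `config`, `params` and `seed` used.
#' @examples
#' cfg <- lattice_config(length = 60, pin_left = 5, pin_right = 5, seed = 1)
#' tr <- run_gillespie(cfg, rate_params(), n_events = 2e4, burn_in = 5e3,
#'                     sample_every = 500)
#' dim(tr$samples)
#' @export
run_gillespie <- function(config, params, n_events = 1e6, burn_in = 2e5,
                          sample_every = 2000, titrate = TRUE,
                          rho_free_fixed = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  validate_rate_params(params)
  if (n_events <= burn_in) stop("n_events must exceed burn_in")
  st <- initial_lattice_state(config)
  n_bound0 <- sum(st == "S")
  if (titrate) {
    if (!is.finite(params$n_sir_total))
      stop("titrate = TRUE requires a finite n_sir_total")
    if (n_bound0 > params$n_sir_total)
      stop("initial bound Sir (", n_bound0, ") exceeds n_sir_total")
  }
  fixed_fac <- if (is.null(rho_free_fixed)) 1 else rho_free_fixed / params$rho_ref
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- gillespie_lattice(
    init_state = state_code(st) - 1L,
    pin_left = config$pin_left, pin_right = config$pin_right,
    weights = weights_for_cpp(config$neighborhood),
    half_width = config$neighborhood$half_width,
    include_self = config$neighborhood$include_self,
    channels = channels_for_cpp(params),
    n_total = if (titrate) params$n_sir_total else Inf,
    v_nucleus = params$v_nucleus, rho_ref = params$rho_ref,
    titrate = titrate, fixed_fac = fixed_fac,
    n_events = n_events, burn_in = burn_in, sample_every = sample_every)
  structure(list(samples = res$samples, event = res$event, time = res$time,
                 n_bound = res$n_bound, rho_free = res$rho_free,
                 event_count = res$event_count, frozen = res$frozen,
                 titrate = titrate, config = config, params = params,
                 seed = config$seed,
                 n_events = n_events, burn_in = burn_in,
                 sample_every = sample_every),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf("Lattice trajectory: L = %d, %d samples, %g reactions%s\n",
              x$config$length, nrow(x$samples), x$event_count,
              if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

#' Extract one sample as a character state vector
#'
#' @param trajectory a `lattice_trajectory`.
#' @param i sample index.
#' @return Character vector over [NUC_STATES].
#' @export
sample_states <- function(trajectory, i) {
  NUC_STATES[trajectory$samples[i, ]]
}

#' Sir pool bookkeeping
#'
#' A finite pool of Sir proteins: `rho_free = (n_total - n_bound) /
#' v_nucleus`. [update_titration()] applies a single binding (+1) or
#' unbinding (-1) event; crossing either pool bound is an invariant
#' violation (it would indicate a propensity bug in a simulator).
#'
#' @param n_total total Sir copies.
#' @param v_nucleus nuclear volume.
#' @param n_bound currently chromatin-bound copies.
#' @return An object of class `"sir_pool"`.
#' @export
sir_pool <- function(n_total, v_nucleus, n_bound = 0) {
  if (n_total < 0 || v_nucleus <= 0) stop("invalid pool parameters")
  if (n_bound < 0 || n_bound > n_total) stop("n_bound outside [0, n_total]")
  structure(list(n_total = n_total, v_nucleus = v_nucleus,
                 n_bound = n_bound,
                 rho_free = (n_total - n_bound) / v_nucleus),
            class = "sir_pool")
}

#' @rdname sir_pool
#' @param pool a `sir_pool`.
#' @param delta_bound `+1` (binding) or `-1` (unbinding).
#' @export
update_titration <- function(pool, delta_bound) {
  stopifnot(inherits(pool, "sir_pool"))
  if (!delta_bound %in% c(-1, 1)) stop("delta_bound must be +1 or -1")
  nb <- pool$n_bound + delta_bound
  if (nb < 0 || nb > pool$n_total)
    stop("titration invariant violated: n_bound would be ", nb)
  pool$n_bound <- nb
  pool$rho_free <- (pool$n_total - nb) / pool$v_nucleus
  pool
}

#' Well-mixed stochastic reference run
#'
#' Gillespie dynamics identical to [run_gillespie()] except that local
#' densities are uniform over the whole lattice (every site senses the
#' global mark fractions) and no sites are pinned. In this limit the
#' stationary fractions converge to the mean-field fixed point, so the run
#' serves as an independent bridge between the stochastic simulator and
#' the ODE analysis; it is used in the package's tests.
#'
#' @inheritParams run_gillespie
#' @param length lattice size.
#' @param seed RNG seed (`NULL` leaves the RNG untouched).
#' @param initial_state preset or state vector as in [lattice_config()].
#' @return List with `frac` (per-sample state-fraction matrix, columns
#'   S, U, A, M, E), `mean` (time-averaged fractions), `se` (batch-means
#'   standard errors, 20 batches), `event_count`, `frozen`.
#' @export
wellmixed_reference_run <- function(params, length = 500L, n_events = 1e6,
                                    seed = NULL, burn_in = 2e5,
                                    sample_every = 500,
                                    initial_state = "unmodified",
                                    titrate = FALSE, rho_free_fixed = NULL) {
  validate_rate_params(params)
  cfg <- lattice_config(length = length, pin_left = 0L, pin_right = 0L,
                        initial_state = initial_state)
  st <- initial_lattice_state(cfg)
  fixed_fac <- if (is.null(rho_free_fixed)) 1 else rho_free_fixed / params$rho_ref
  if (!is.null(seed)) set.seed(seed)
  res <- gillespie_wellmixed(
    init_state = state_code(st) - 1L,
    channels = channels_for_cpp(params),
    n_total = if (titrate) params$n_sir_total else Inf,
    v_nucleus = params$v_nucleus, rho_ref = params$rho_ref,
    titrate = titrate, fixed_fac = fixed_fac,
    n_events = n_events, burn_in = burn_in, sample_every = sample_every)
  fr <- res$frac
  colnames(fr) <- NUC_STATES
  means <- colMeans(fr)
  # batch means absorb autocorrelation between successive samples
  nb <- 20L
  bid <- cut(seq_len(nrow(fr)), nb, labels = FALSE)
  bm <- apply(fr, 2, function(col) tapply(col, bid, mean))
  se <- apply(bm, 2, stats::sd) / sqrt(nb)
  list(frac = fr, mean = means, se = se,
       event_count = res$event_count, frozen = res$frozen)
}
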