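## Synthetic validation fixtures: binary Markov fields with known
## correlation length, exact Lorentzian spectra, and step-front
## configurations. These exercise the spectral estimator and the front
## tracker against closed-form truth.

#' Binary two-state Markov fields
#'
#' Generates spatial binary fields where successive sites flip with
#' probability `p_flip`. The stationary autocorrelation is
#' `(1 - 2 p_flip)^d`, so the analytic correlation length is
#' `xi = -1 / log(1 - 2 p_flip)` — the closed-form target for the
#' Lorentzian estimator.
#'
#' @param p_flip per-step flip probability in (0, 0.5).
#' @param length sites per field.
#' @param n_samples number of independent fields.
#' @param seed RNG seed (`NULL` leaves the RNG untouched).
#' @return Integer 0/1 matrix (`n_samples` rows) with the analytic
#'   correlation length attached as attribute `"xi"`.
#' @export
synth_markov_field <- function(p_flip, length = 4096L, n_samples = 200L,
                               seed = NULL) {
  if (p_flip <= 0 || p_flip >= 0.5) stop("p_flip must be in (0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  flips <- matrix(stats::rbinom(n_samples * (length - 1L), 1L, p_flip),
                  nrow = n_samples)
  start <- stats::rbinom(n_samples, 1L, 0.5)
  x <- (start + cbind(0L, t(apply(flips, 1L, cumsum)))) %% 2L
  structure(x, xi = -1 / log(1 - 2 * p_flip), p_flip = p_flip)
}

#' Exact Lorentzian spectrum
#'
#' The noiseless spectrum `G(q) = c1 / (c2 + q^2)` evaluated on the same
#' frequency grid [s_power_spectrum()] uses for a field of `length` sites.
#' Fitting it back must return `xi = 1 / sqrt(c2)` to numerical precision.
#'
#' @param c1,c2 Lorentzian constants (`c2 > 0`).
#' @param length field length defining the q grid.
#' @return A `data.frame` with `q` and `G`.
#' @export
synth_lorentzian_spectrum <- function(c1 = 4, c2 = 0.04, length = 1024L) {
  if (c2 <= 0) stop("c2 must be > 0")
  q <- 2 * pi * seq_len(length %/% 2L) / length
  data.frame(q = q, G = c1 / (c2 + q^2))
}

#' Step-front lattice configuration
#'
#' A sharp silenced/active step: sites `1..breakpoint` in S, the rest in
#' E. [front_position()] applied to it returns `breakpoint` exactly (for
#' any odd window), which anchors the front estimator.
#'
#' @param length lattice length.
#' @param breakpoint last S site.
#' @return Character state vector over [NUC_STATES].
#' @export
synth_step_front <- function(length = 1000L, breakpoint = 500L) {
  if (breakpoint < 1L || breakpoint >= length) stop("breakpoint out of range")
  rep(c("S", "E"), c(breakpoint, length - breakpoint))
}

#' Power spectrum of plain binary field matrices
#'
#' The same estimator as [s_power_spectrum()], applied to a matrix of
#' fields (one per row) rather than a trajectory — used to validate the
#' spectral pipeline on the synthetic fixtures.
#'
#' @param x numeric or 0/1 matrix, one field per row.
#' @inheritParams s_power_spectrum
#' @return A `data.frame` with `q`, `G`, `se`.
#' @export
field_power_spectrum <- function(x, detrend = TRUE, method = "hann",
                                 n_tapers = 5L) {
  spectrum_of_fields(x * 1.0, detrend, method, n_tapers)
}
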