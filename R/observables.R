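## Steady-state observables: density profiles, bound-Sir fraction,
## spatial power spectrum of the silenced mark and the correlation length
## from a Lorentzian fit G(q) = c1 / (c2 + q^2), xi = 1 / sqrt(c2).

#' Per-site mark-density profiles
#'
#' Empirical mark frequencies per site over the post-burn-in samples of a
#' trajectory. Pinned sites are included but flagged.
#'
#' @param trajectory a `lattice_trajectory` from [run_gillespie()].
#' @return A `data.frame` with `site`, `P_S`, `P_U`, `P_A`, `P_M`, `P_E`,
#'   `pinned` and the sample count as attribute `"n_samples"`.
#' @export
density_profiles <- function(trajectory) {
  sm <- trajectory$samples
  if (is.null(sm) || nrow(sm) == 0L) stop("trajectory has no samples")
  L <- ncol(sm)
  freq <- vapply(1:5, function(code) colMeans(sm == code),
                 numeric(L))
  colnames(freq) <- paste0("P_", NUC_STATES)
  cfg <- trajectory$config
  out <- data.frame(site = seq_len(L), freq,
                    pinned = seq_len(L) <= cfg$pin_left |
                      seq_len(L) > L - cfg$pin_right)
  attr(out, "n_samples") <- nrow(sm)
  out
}

#' Fraction of the Sir pool bound to chromatin
#'
#' Time average of `n_bound / n_total` over the trajectory's samples.
#'
#' @param trajectory a titrated `lattice_trajectory`.
#' @return Fraction in `[0, 1]`.
#' @export
bound_fraction <- function(trajectory) {
  if (!isTRUE(trajectory$titrate))
    stop("bound_fraction requires a titrated run")
  nt <- trajectory$params$n_sir_total
  if (!is.finite(nt) || nt == 0) stop("bound fraction undefined: n_total is 0")
  mean(trajectory$n_bound) / nt
}

# interior (unpinned) site range of a trajectory
interior_sites <- function(config) {
  seq.int(config$pin_left + 1L, config$length - config$pin_right)
}

#' Local Sir density within the silenced domain
#'
#' The plateau height of the silenced-mark density profile: the mean S
#' occupancy over the interior sites where S is the majority mark on time
#' average (`P_S >= threshold`). When no interior site reaches the
#' threshold — silencing too dilute to form a domain — the average over
#' all interior sites is returned instead. Together with
#' [bound_fraction()] this quantifies domain compactness: fragmented
#' silencing lowers the local density while raising the chromatin-bound
#' total.
#'
#' @param trajectory a `lattice_trajectory`.
#' @param threshold majority threshold on the per-site time-averaged S
#'   occupancy (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
domain_sir_density <- function(trajectory, threshold = 0.5) {
  cfg <- trajectory$config
  int <- interior_sites(cfg)
  p_s <- colMeans(trajectory$samples[, int, drop = FALSE] == 1L)
  dom <- p_s >= threshold
  if (!any(dom)) mean(p_s) else mean(p_s[dom])
}

#' Spatial power spectrum of the silenced mark
#'
#' Per-sample periodogram of the mean-subtracted S-indicator over the
#' interior (unpinned) sites, averaged across samples. The default
#' estimator applies a single Hann taper per sample (the samples act as
#' the averaged segments); `method = "multitaper"` averages `n_tapers`
#' sine tapers per sample instead, trading a little bias for variance.
#'
#' @param trajectory a `lattice_trajectory`.
#' @param detrend subtract the per-sample interior mean (default `TRUE`).
#' @param method `"hann"` (segment-averaged tapered periodogram) or
#'   `"multitaper"` (sine tapers).
#' @param n_tapers number of sine tapers for the multitaper estimate.
#' @return A `data.frame` with `q` (spatial frequency, radians per
#'   nucleosome, excluding q = 0), `G` (averaged spectral power) and `se`
#'   (standard error across samples).
#' @export
s_power_spectrum <- function(trajectory, detrend = TRUE, method = c("hann", "multitaper"),
                             n_tapers = 5L) {
  method <- match.arg(method)
  sm <- trajectory$samples
  if (is.null(sm) || nrow(sm) < 10L) stop("need >= 10 samples for a spectrum")
  int <- interior_sites(trajectory$config)
  if (length(int) < 64L) stop("interior length must be >= 64 sites")
  x <- (sm[, int, drop = FALSE] == 1L) * 1.0
  spectrum_of_fields(x, detrend, method, n_tapers)
}

# shared estimator; x is an n_samples x N matrix of numeric fields
spectrum_of_fields <- function(x, detrend = TRUE,
                               method = c("hann", "multitaper"),
                               n_tapers = 5L) {
  method <- match.arg(method)
  N <- ncol(x)
  kmax <- N %/% 2L
  q <- 2 * pi * seq_len(kmax) / N
  tapers <- if (method == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 0.5) / N)
    matrix(w / sqrt(sum(w^2)), ncol = 1L)
  } else {
    t_idx <- seq_len(N) - 0.5
    w <- vapply(seq_len(n_tapers),
                function(k) sin(pi * k * t_idx / N), numeric(N))
    sweep(w, 2, sqrt(colSums(w^2)), "/")
  }
  G <- matrix(0, nrow(x), kmax)
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    if (detrend) xi <- xi - mean(xi)
    pk <- 0
    for (j in seq_len(ncol(tapers))) {
      ft <- stats::fft(xi * tapers[, j])
      pk <- pk + Mod(ft[2:(kmax + 1L)])^2
    }
    G[i, ] <- pk / ncol(tapers)
  }
  data.frame(q = q, G = colMeans(G),
             se = apply(G, 2, stats::sd) / sqrt(nrow(G)))
}

#' Correlation length from a Lorentzian spectral fit
#'
#' Nonlinear least squares of `G(q) = c1 / (c2 + q^2)` over
#' `0 < q <= q_max_fit * pi`; the correlation length is
#' `xi = 1 / sqrt(c2)`. The fit is unweighted by default: periodogram
#' noise is multiplicative, so inverse-variance weighting amounts to
#' fitting relative errors and lets the (many) high-q floor points
#' overwhelm the low-q Lorentzian peak that actually carries the
#' correlation length. Absolute-error fitting keeps the peak in charge;
#' `weighting = "inverse_variance"` is available for spectra without a
#' noise floor (it needs an `se` column and >= 20 samples). The default
#' fit range stops at half-Nyquist to limit lattice-discreteness bias in
#' the Lorentzian tail.
#'
#' @param spectrum a `data.frame` with columns `q`, `G` and optionally
#'   `se`, as from [s_power_spectrum()].
#' @param q_max_fit upper end of the fit range as a fraction of the
#'   Nyquist frequency pi.
#' @param weighting `"none"` (default) or `"inverse_variance"`.
#' @param n_samples number of samples behind the spectrum; the
#'   inverse-variance option falls back to unweighted below 20.
#' @return List of class `"spectrum_fit"`: `c1`, `c2`, `xi`, `fit_rmse`,
#'   `q_range`, `weighted`.
#' @export
correlation_length <- function(spectrum, q_max_fit = 0.5,
                               weighting = c("none", "inverse_variance"),
                               n_samples = Inf) {
  stopifnot(all(c("q", "G") %in% names(spectrum)))
  weighting <- match.arg(weighting)
  sel <- spectrum$q > 0 & spectrum$q <= q_max_fit * pi
  d <- spectrum[sel, , drop = FALSE]
  if (nrow(d) < 4L) stop("fewer than 4 spectral points in the fit range")
  if (any(d$G <= 0)) stop("spectrum must be positive on the fit range")
  w <- if (weighting == "inverse_variance" && !is.null(d$se) &&
           all(d$se > 0) && n_samples >= 20) 1 / d$se^2
       else rep(1, nrow(d))
  # start values: peak height ~ c1/c2, half-maximum at q ~ sqrt(c2)
  g0 <- max(d$G)
  i_half <- which(d$G <= g0 / 2)
  c2_0 <- if (length(i_half)) d$q[min(i_half)]^2 else stats::median(d$q)^2
  if (!is.finite(c2_0) || c2_0 <= 0) c2_0 <- 0.1
  c1_0 <- g0 * c2_0
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ c1 / (c2 + q^2), data = d,
                      start = list(c1 = c1_0, c2 = c2_0),
                      weights = w,
                      lower = c(1e-300, 1e-300),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Lorentzian fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["c2"]] <= 0) stop("Lorentzian fit failed: c2 <= 0")
  pred <- cf[["c1"]] / (cf[["c2"]] + d$q^2)
  structure(list(c1 = unname(cf[["c1"]]), c2 = unname(cf[["c2"]]),
                 xi = 1 / sqrt(unname(cf[["c2"]])),
                 fit_rmse = sqrt(mean((pred - d$G)^2)),
                 q_range = range(d$q), weighted = !all(w == 1)),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: xi = %.3f nucleosomes (c1 = %.4g, c2 = %.4g, rmse = %.3g)\n",
              x$xi, x$c1, x$c2, x$fit_rmse))
  invisible(x)
}

#' Correlation length of the silenced mark in a trajectory
#'
#' Convenience wrapper: [s_power_spectrum()] followed by
#' [correlation_length()].
#'
#' @inheritParams s_power_spectrum
#' @inheritParams correlation_length
#' @export
trajectory_correlation_length <- function(trajectory, q_max_fit = 0.5,
                                          method = "hann") {
  sp <- s_power_spectrum(trajectory, method = method)
  correlation_length(sp, q_max_fit)
}
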