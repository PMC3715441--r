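#' Nucleosome state alphabet
#'
#' The five mutually exclusive local states of a nucleosome: `"S"`
#' (Sir-complex bound), `"U"` (unmodified), `"A"` (H4K16-acetylated),
#' `"M"` (H3K79-methylated) and `"E"` (transcriptionally active, carrying
#' both the acetyl and the methyl mark). Integer codes 1..5 in this order
#' are used internally and by the compiled simulator.
#'
#' @format Character vector of length 5.
#' @export
NUC_STATES <- c("S", "U", "A", "M", "E")

state_code <- function(x) {
  i <- match(x, NUC_STATES)
  if (anyNA(i)) stop("unknown nucleosome state: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Rate parameters of the silencing model
#'
#' All rates are measured in units of the global mark-loss rate
#' `lambda_loss`, which is fixed to 1 and sets the time unit. The basal
#' and cooperative Sir-binding rates are the nominal values at free-Sir
#' density `rho_ref`; during titrated simulation they are scaled by
#' `rho_free / rho_ref`.
#'
#' The defaults are the package's wild-type operating point: a
#' silenced/active bistable regime with small basal rates, used by the
#' scenario presets. The biochemical rates of the real system are
#' unknown, so these are package choices (see the methods vignette).
#'
#' @param alpha_sir_basal basal Sir-complex binding rate (U to S).
#' @param delta_sir_coop cooperative Sir binding rate, driven by
#'   Sir-bound neighbors ("silencing polymerization").
#' @param gamma_sas2 Sas2 acetylation rate (U to A and M to E).
#' @param beta0_dot1_basal basal Dot1 methylation rate (U to M, A to E).
#' @param beta_dot1_coop cooperative Dot1 methylation rate, driven by
#'   transcriptionally active (E) neighbors ("transcriptional feedback").
#' @param eta_sir2_coop cooperative Sir2 deacetylation rate, driven by
#'   Sir-bound neighbors (A to U, E to M).
#' @param lambda_loss global mark-loss rate; the time unit (default 1).
#' @param n_sir_total total Sir protein copy number (the titrated pool).
#' @param v_nucleus nuclear volume, in arbitrary volume units.
#' @param rho_ref reference free-Sir density at which the Sir-binding
#'   rates take their nominal values.
#' @return An object of class `"rate_params"` (a validated named list).
#' @examples
#' p <- rate_params()
#' canonical_reaction_set(p)
#' @export
rate_params <- function(alpha_sir_basal = 0.01,
                        delta_sir_coop = 8,
                        gamma_sas2 = 3,
                        beta0_dot1_basal = 0.05,
                        beta_dot1_coop = 20,
                        eta_sir2_coop = 10,
                        lambda_loss = 1,
                        n_sir_total = 750,
                        v_nucleus = 200,
                        rho_ref = 1) {
  p <- list(alpha_sir_basal = alpha_sir_basal,
            delta_sir_coop = delta_sir_coop,
            gamma_sas2 = gamma_sas2,
            beta0_dot1_basal = beta0_dot1_basal,
            beta_dot1_coop = beta_dot1_coop,
            eta_sir2_coop = eta_sir2_coop,
            lambda_loss = lambda_loss,
            n_sir_total = n_sir_total,
            v_nucleus = v_nucleus,
            rho_ref = rho_ref)
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

validate_rate_params <- function(p) {
  rates <- c("alpha_sir_basal", "delta_sir_coop", "gamma_sas2",
             "beta0_dot1_basal", "beta_dot1_coop", "eta_sir2_coop",
             "lambda_loss")
  for (r in rates) {
    v <- p[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate '", r, "' must be a single nonnegative number")
  }
  if (p$n_sir_total < 0) stop("n_sir_total must be >= 0")
  if (p$v_nucleus <= 0) stop("v_nucleus must be > 0")
  if (p$rho_ref <= 0) stop("rho_ref must be > 0")
  invisible(p)
}

#' Modify rate parameters
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#'
#' @param params a [rate_params()] object.
#' @param ... named fields to override.
#' @export
update_params <- function(params, ...) {
  ov <- list(...)
  stopifnot(inherits(params, "rate_params"))
  bad <- setdiff(names(ov), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(ov)] <- ov
  validate_rate_params(params)
  structure(params, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Silencing-model rate parameters (units of the loss rate):\n")
  for (n in names(x)) cat(sprintf("  %-17s %g\n", n, x[[n]]))
  invisible(x)
}

#' Neighborhood specification for cooperative coupling
#'
#' Cooperative reactions sense the local density of a mark in a window of
#' `half_width` nucleosomes on each side, with exponentially decaying
#' weights `w(d) ~ exp(-|d| / decay_length)`. The window models the
#' polymer nature of chromatin: nearby nucleosomes come into physical
#' contact most often.
#'
#' @param half_width number of nucleosomes on each side (>= 1).
#' @param decay_length e-folding distance of the weights, in nucleosomes.
#' @param include_self whether the focal nucleosome contributes to its own
#'   local density (default `FALSE`, so a site cannot catalyze its own
#'   transition).
#' @return An object of class `"neighborhood_spec"`.
#' @export
neighborhood_spec <- function(half_width = 5, decay_length = 2,
                              include_self = FALSE) {
  if (!is.numeric(half_width) || half_width < 1 || half_width != round(half_width))
    stop("half_width must be an integer >= 1")
  if (!is.numeric(decay_length) || decay_length <= 0)
    stop("decay_length must be > 0")
  structure(list(half_width = as.integer(half_width),
                 decay_length = decay_length,
                 include_self = isTRUE(include_self)),
            class = "neighborhood_spec")
}

#' Exponentially decaying neighbor weights
#'
#' Emits the normalized weight vector indexed by offset
#' `-half_width .. +half_width` (offset 0 omitted when `include_self` is
#' `FALSE`). Weights are proportional to `exp(-|offset| / decay_length)`
#' and sum to one.
#'
#' @param spec a [neighborhood_spec()].
#' @return Named numeric vector; names are the signed offsets.
#' @examples
#' neighbor_weights(neighborhood_spec(half_width = 1))  # (0.5, 0.5)
#' @export
neighbor_weights <- function(spec) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  off <- seq.int(-spec$half_width, spec$half_width)
  if (!spec$include_self) off <- off[off != 0L]
  w <- exp(-abs(off) / spec$decay_length)
  w <- w / sum(w)
  names(w) <- off
  w
}

#' Neighborhood-weighted local mark density
#'
#' The weighted fraction of nucleosomes around `site` carrying `mark`.
#' Near the lattice edges, weights of out-of-range offsets are dropped and
#' the remainder renormalized to sum to one (the lattice models a
#' telomere-proximal segment, not a ring).
#'
#' @param config character vector of per-site states over [NUC_STATES].
#' @param site site index (1-based).
#' @param mark the state whose local density is measured.
#' @param spec a [neighborhood_spec()].
#' @return A fraction in `[0, 1]`.
#' @export
local_density <- function(config, site, mark, spec) {
  stopifnot(site >= 1, site <= length(config))
  w <- neighbor_weights(spec)
  off <- as.integer(names(w))
  j <- site + off
  ok <- j >= 1 & j <= length(config)
  sum(w[ok] * (config[j[ok]] == mark)) / sum(w[ok])
}

#' The canonical reaction channels of the silencing model
#'
#' Instantiates the model's full reaction list as a channel table. Each
#' channel converts `source` to `target` with propensity
#' `basal + coop * (local density of coop_mark)`, further scaled by
#' `rho_free / rho_ref` when `titrated`:
#'
#' * basal (`alpha_sir_basal`) and cooperative (`delta_sir_coop`, driven
#'   by S neighbors) Sir binding, U -> S, both titrated;
#' * Sas2 acetylation (`gamma_sas2`): U -> A and M -> E;
#' * basal Dot1 methylation (`beta0_dot1_basal`): U -> M and A -> E;
#' * cooperative Dot1 methylation (`beta_dot1_coop`, driven by E
#'   neighbors, the transcriptional feedback): U -> M and A -> E;
#' * cooperative Sir2 deacetylation (`eta_sir2_coop`, driven by S
#'   neighbors): A -> U and E -> M (the acetyl mark is removed, the
#'   methyl mark remains);
#' * mark loss at `lambda_loss`: S, A, M, E -> U in a single step.
#'
#' @param params a [rate_params()] object.
#' @return A `data.frame` with one row per channel: `source`, `target`,
#'   `basal`, `coop`, `coop_mark` (`NA` for purely basal channels) and
#'   `titrated`.
#' @export
canonical_reaction_set <- function(params) {
  validate_rate_params(params)
  p <- params
  ch <- rbind(
    data.frame(source = "U", target = "S", basal = p$alpha_sir_basal,
               coop = 0, coop_mark = NA_character_, titrated = TRUE),
    data.frame(source = "U", target = "S", basal = 0,
               coop = p$delta_sir_coop, coop_mark = "S", titrated = TRUE),
    data.frame(source = "U", target = "A", basal = p$gamma_sas2,
               coop = 0, coop_mark = NA_character_, titrated = FALSE),
    data.frame(source = "M", target = "E", basal = p$gamma_sas2,
               coop = 0, coop_mark = NA_character_, titrated = FALSE),
    data.frame(source = "U", target = "M", basal = p$beta0_dot1_basal,
               coop = 0, coop_mark = NA_character_, titrated = FALSE),
    data.frame(source = "A", target = "E", basal = p$beta0_dot1_basal,
               coop = 0, coop_mark = NA_character_, titrated = FALSE),
    data.frame(source = "U", target = "M", basal = 0,
               coop = p$beta_dot1_coop, coop_mark = "E", titrated = FALSE),
    data.frame(source = "A", target = "E", basal = 0,
               coop = p$beta_dot1_coop, coop_mark = "E", titrated = FALSE),
    data.frame(source = "A", target = "U", basal = 0,
               coop = p$eta_sir2_coop, coop_mark = "S", titrated = FALSE),
    data.frame(source = "E", target = "M", basal = 0,
               coop = p$eta_sir2_coop, coop_mark = "S", titrated = FALSE),
    data.frame(source = c("S", "A", "M", "E"), target = "U",
               basal = p$lambda_loss, coop = 0,
               coop_mark = NA_character_, titrated = FALSE)
  )
  rownames(ch) <- NULL
  ch
}
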