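## Scenario presets for the perturbation experiments: knock-outs zero a
## rate, inhibition/overexpression scale it, and sweeps trace a rate from
## the wild-type operating point into the perturbed regime.

#' Scenario presets for perturbation experiments
#'
#' Named perturbations of the wild-type operating point (the
#' [rate_params()] defaults):
#'
#' * `wild_type` — the unperturbed bistable reference point.
#' * `dot1_null` — knock-out: `beta_dot1_coop = beta0_dot1_basal = 0`.
#' * `dot1_inhibition_sweep` — `beta_dot1_coop` swept down from wild type.
#' * `dot1_overexpression_sweep` — `beta_dot1_coop` swept up.
#' * `sir2_inhibition_sweep` — `eta_sir2_coop` swept down to full
#'   inhibition.
#' * `sas2_inhibition_sweep` — `gamma_sas2` swept down.
#' * `sir_overexpression` — `n_sir_total` raised 1.5-fold.
#'
#' @param name preset name.
#' @param params baseline parameters the preset perturbs.
#' @return A list of class `"scenario_preset"`: `name`, `params` (the
#'   perturbed [rate_params()]), and for sweeps `sweep_param` plus
#'   `sweep_values` (ordered from wild type into the perturbation).
#' @export
scenario_preset <- function(name = c("wild_type", "dot1_null",
                                     "dot1_inhibition_sweep",
                                     "dot1_overexpression_sweep",
                                     "sir2_inhibition_sweep",
                                     "sas2_inhibition_sweep",
                                     "sir_overexpression"),
                            params = rate_params()) {
  name <- match.arg(name)
  out <- list(name = name, params = params,
              sweep_param = NULL, sweep_values = NULL)
  be <- params$beta_dot1_coop
  switch(name,
    wild_type = NULL,
    dot1_null = {
      out$params <- update_params(params, beta_dot1_coop = 0,
                                  beta0_dot1_basal = 0)
    },
    dot1_inhibition_sweep = {
      out$sweep_param <- "beta_dot1_coop"
      out$sweep_values <- be * c(1, 0.5, 0.25, 0.1)
    },
    dot1_overexpression_sweep = {
      out$sweep_param <- "beta_dot1_coop"
      out$sweep_values <- be * c(1, 1.5, 2)
    },
    sir2_inhibition_sweep = {
      out$sweep_param <- "eta_sir2_coop"
      out$sweep_values <- params$eta_sir2_coop * c(1, 0.5, 0)
    },
    sas2_inhibition_sweep = {
      out$sweep_param <- "gamma_sas2"
      out$sweep_values <- params$gamma_sas2 * c(1, 0.75, 0.5, 0.25)
    },
    sir_overexpression = {
      out$params <- update_params(params,
                                  n_sir_total = 1.5 * params$n_sir_total)
    })
  structure(out, class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset:", x$name, "\n")
  if (!is.null(x$sweep_param))
    cat("  sweep", x$sweep_param, "over",
        paste(signif(x$sweep_values, 4), collapse = ", "), "\n")
  invisible(x)
}
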