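# shared fixture builders

# all marks decay, nothing is written
loss_only_params <- function() {
  rate_params(alpha_sir_basal = 0, delta_sir_coop = 0, gamma_sas2 = 0,
              beta0_dot1_basal = 0, beta_dot1_coop = 0, eta_sir2_coop = 0)
}

# no cooperativity, unit basal rates: the analytically solvable point
linear_params <- function() {
  rate_params(alpha_sir_basal = 1, delta_sir_coop = 0, gamma_sas2 = 1,
              beta0_dot1_basal = 1, beta_dot1_coop = 0, eta_sir2_coop = 0)
}

# stationary fractions of the linear point from the balance equations,
# solved as a plain linear system (independent of the package's solver):
# unknowns (s, u, a, m, e), equations d/dt = 0 plus normalization
linear_point_oracle <- function() {
  # s' = u - s; a' = u - 2a; m' = u - 2m; e' = a + m - e; sum = 1
  A <- rbind(c(-1, 1, 0, 0, 0),
             c(0, 1, -2, 0, 0),
             c(0, 1, 0, -2, 0),
             c(0, 0, 1, 1, -1),
             c(1, 1, 1, 1, 1))
  drop(solve(A, c(0, 0, 0, 0, 1)))  # order (s, u, a, m, e)
}

# hand-built trajectory for observable tests
mk_traj <- function(states_matrix, pin_left = 0L, pin_right = 0L,
                    params = rate_params(), titrate = TRUE) {
  codes <- matrix(match(states_matrix, NUC_STATES),
                  nrow = nrow(states_matrix))
  cfg <- lattice_config(length = ncol(codes), pin_left = pin_left,
                        pin_right = pin_right, initial_state = "unmodified")
  structure(list(samples = codes,
                 event = seq_len(nrow(codes)) * 1000,
                 time = seq_len(nrow(codes)),
                 n_bound = rowSums(codes == 1L),
                 rho_free = (params$n_sir_total - rowSums(codes == 1L)) /
                   params$v_nucleus,
                 event_count = nrow(codes) * 1000,
                 frozen = FALSE, titrate = titrate,
                 config = cfg, params = params, seed = 1L),
            class = "lattice_trajectory")
}
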