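test_that("mean-field derivatives conserve probability and match the channel table", {
  set.seed(11)
  for (i in 1:10) {
    g <- rexp(5); p <- g / sum(g)
    prm <- rate_params(alpha_sir_basal = runif(1), delta_sir_coop = runif(1, 0, 10),
                       gamma_sas2 = runif(1, 0, 5), beta0_dot1_basal = runif(1),
                       beta_dot1_coop = runif(1, 0, 20), eta_sir2_coop = runif(1, 0, 10))
    d <- meanfield_rhs(p, prm, rho_free = 0.7)
    expect_equal(sum(d), 0, tolerance = 1e-12)
    # the hand-expanded reduced system used by the solver agrees with the
    # generic channel-assembled derivatives and Jacobian
    funs <- sirspread:::mf_fast_funs(prm, 0.7)
    x <- p[c(1, 3, 4, 5)]
    expect_equal(funs$F(x), unname(d[c(1, 3, 4, 5)]), tolerance = 1e-12)
    cc <- sirspread:::compile_channels(prm)
    expect_equal(funs$J(x), sirspread:::mf_red_J(x, cc, 0.7),
                 tolerance = 1e-12)
  }
})

test_that("single-channel and absorbing-state limits are exact", {
  pU <- c(0, 1, 0, 0, 0)
  expect_equal(unname(meanfield_rhs(pU, loss_only_params())), rep(0, 5))
  only_alpha <- update_params(loss_only_params(), alpha_sir_basal = 1,
                              lambda_loss = 0)
  d <- meanfield_rhs(pU, only_alpha)
  expect_equal(unname(d), c(1, -1, 0, 0, 0))
})

test_that("the no-cooperativity fixed point matches the linear-balance oracle", {
  oracle <- linear_point_oracle()           # (s, u, a, m, e)
  expect_equal(oracle, c(0.25, 0.25, 0.125, 0.125, 0.25))
  set.seed(2)
  fps <- find_fixed_points(linear_params())
  expect_equal(nrow(fps), 1L)
  expect_true(fps$stable)
  expect_equal(unlist(fps[1, c("p_s", "p_u", "p_a", "p_m", "p_e")]),
               oracle, tolerance = 1e-8, ignore_attr = TRUE)
  # independent cross-check: long forward ODE integration
  tr <- integrate_meanfield(c(0, 1, 0, 0, 0), linear_params(), t_end = 200)
  expect_equal(unname(tr[nrow(tr), 2:6]), oracle, tolerance = 1e-6)
})

test_that("loss-only flow has the unmodified state as unique stable fixed point", {
  set.seed(3)
  fps <- find_fixed_points(loss_only_params())
  expect_equal(nrow(fps), 1L)
  expect_equal(fps$p_u, 1, tolerance = 1e-10)
  expect_true(fps$stable)
})

test_that("returned fixed points are genuine roots on the simplex", {
  set.seed(4)
  for (prm in list(rate_params(),
                   update_params(rate_params(), eta_sir2_coop = 0),
                   update_params(rate_params(), beta_dot1_coop = 2))) {
    fps <- find_fixed_points(prm, rho_free = 1.5)
    for (i in seq_len(nrow(fps))) {
      p <- unlist(fps[i, c("p_s", "p_u", "p_a", "p_m", "p_e")])
      expect_true(all(p >= -1e-12) && abs(sum(p) - 1) < 1e-9)
      expect_lt(max(abs(meanfield_rhs(p, prm, 1.5))), 1e-10)
    }
  }
})

test_that("fixed-point labels follow the occupancy thresholds", {
  expect_equal(classify_fixed_point(c(1, 0, 0, 0, 0)), "silenced")
  expect_equal(classify_fixed_point(c(0, 0, 0, 0, 1)), "active")
  expect_equal(classify_fixed_point(c(0.4, 0.1, 0.05, 0.05, 0.4)), "bivalent")
  expect_equal(classify_fixed_point(c(0.1, 0.4, 0.3, 0.15, 0.05)),
               "intermediate")
  expect_error(classify_fixed_point(c(1, 0, 0, 0, 0), theta_hi = 0.2,
                                    theta_lo = 0.5), "theta")
})

test_that("stable-label sets do not depend on the multi-start RNG", {
  prm <- rate_params()
  grid <- list(beta_dot1_coop = c(2, 10, 20), eta_sir2_coop = c(0, 10))
  set.seed(101); s1 <- scan_phase_diagram(grid, prm)
  set.seed(9876); s2 <- scan_phase_diagram(grid, prm)
  expect_equal(s1$labels, s2$labels)
  expect_equal(s1$phase_class, s2$phase_class)
})

test_that("forward integration lands on a reported stable fixed point", {
  set.seed(5)
  prm <- update_params(rate_params(), beta_dot1_coop = 10)
  fps <- find_fixed_points(prm)
  stab <- fps[fps$stable, c("p_s", "p_u", "p_a", "p_m", "p_e"), drop = FALSE]
  expect_gt(nrow(stab), 0)
  for (i in 1:12) {
    g <- rexp(5); p0 <- g / sum(g)
    end <- integrate_meanfield(p0, prm, t_end = 200)[101, 2:6]
    d <- apply(stab, 1, function(s) max(abs(s - end)))
    expect_lt(min(d), 1e-4)
  }
})

test_that("steady-state Sir occupancy grows with basal binding (monostable)", {
  set.seed(6)
  ps <- vapply(c(0.2, 0.5, 1, 2, 4), function(a) {
    prm <- rate_params(alpha_sir_basal = a, delta_sir_coop = 0,
                       gamma_sas2 = 1, beta0_dot1_basal = 0.5,
                       beta_dot1_coop = 0, eta_sir2_coop = 1)
    fps <- find_fixed_points(prm)
    expect_equal(nrow(fps), 1L)
    fps$p_s
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("overwhelming mark loss drives the system to unmodified", {
  set.seed(7)
  prm <- update_params(rate_params(), lambda_loss = 1000)
  fps <- find_fixed_points(prm)
  expect_equal(nrow(fps), 1L)
  expect_equal(fps$p_u, 1, tolerance = 1e-2)
})

test_that("no silenced-active bistability without Sir cooperativity", {
  # cooperative Sir binding and cooperative deacetylation are the
  # essential bistability ingredients; with both absent a coarse plane
  # scan must stay monostable in the silenced/active sense
  set.seed(8)
  prm <- rate_params(alpha_sir_basal = 0.05, beta0_dot1_basal = 0.05,
                     delta_sir_coop = 0, eta_sir2_coop = 0)
  sc <- scan_phase_diagram(list(gamma_sas2 = c(0.5, 2, 6),
                                beta_dot1_coop = c(0, 5, 15)), prm)
  expect_false(any(sc$phase_class == "silenced-active-bistable"))
})

test_that("critical Dot1 rate: sharp label step without basal rates", {
  set.seed(9)
  sharp <- rate_params(alpha_sir_basal = 0, beta0_dot1_basal = 0,
                       gamma_sas2 = 3, delta_sir_coop = 4,
                       eta_sir2_coop = 10)
  # dense-scan oracle: the label of the non-silenced stable branch is a
  # step function of the cooperative Dot1 rate
  branch <- function(beta) {
    fps <- find_fixed_points(update_params(sharp, beta_dot1_coop = beta))
    st <- fps[fps$stable & fps$label != "silenced", , drop = FALSE]
    if (!nrow(st)) NA_character_ else
      st$label[which.max(st$p_e + st$p_a + st$p_m)]
  }
  betas <- seq(2, 6, by = 0.5)
  labs <- vapply(betas, branch, character(1))
  expect_true(any(labs == "intermediate") && any(labs == "active"))
  flips <- sum(labs[-1] != labs[-length(labs)])
  expect_equal(flips, 1L)  # one step, no re-entrance on this grid
  cr <- critical_dot1_rate(sharp, c(2, 6))
  expect_equal(cr$mode, "sharp")
  lo <- max(betas[labs == "intermediate"]); hi <- min(betas[labs == "active"])
  expect_gte(cr$critical_beta, lo)
  expect_lte(cr$critical_beta, hi)
  expect_error(critical_dot1_rate(sharp, c(5, 6)), "not bracketed")
  expect_error(critical_dot1_rate(sharp, c(5, 5)), "straddle|bracket")
})

test_that("critical Dot1 rate: positive basal rates give a finite crossover", {
  set.seed(10)
  soft <- rate_params(alpha_sir_basal = 0.05, beta0_dot1_basal = 0.05,
                      gamma_sas2 = 3, delta_sir_coop = 4,
                      eta_sir2_coop = 10)
  cr <- critical_dot1_rate(soft, c(1, 16), n_scan = 31L)
  expect_equal(cr$mode, "crossover")
  expect_gte(cr$width, 0)
  expect_true(all(cr$interval >= 1 & cr$interval <= 16))
})
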