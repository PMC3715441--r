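test_that("density profiles are empirical per-site frequencies", {
  tr <- mk_traj(matrix(rep("S", 80), nrow = 1))
  pr <- density_profiles(tr)
  expect_true(all(pr$P_S == 1))
  two <- mk_traj(rbind(rep("S", 80), rep("U", 80)))
  pr2 <- density_profiles(two)
  expect_true(all(pr2$P_S == 0.5) && all(pr2$P_U == 0.5))
  # occupancies sum to one per site; pinned flag matches geometry
  mixed <- mk_traj(matrix(sample(NUC_STATES, 400, replace = TRUE),
                          nrow = 4), pin_left = 10, pin_right = 10)
  prm <- density_profiles(mixed)
  expect_equal(rowSums(prm[, paste0("P_", NUC_STATES)]), rep(1, 100),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(prm$pinned), 20L)
  expect_error(density_profiles(list(samples = NULL)), "samples")
})

test_that("bound fraction is the time average of pool occupancy", {
  p <- rate_params(n_sir_total = 200, v_nucleus = 100)
  none <- mk_traj(rbind(rep("U", 50), rep("E", 50)), params = p)
  expect_equal(bound_fraction(none), 0)
  half <- mk_traj(rbind(rep(c("S", "U"), 25), rep("S", 50)), params = p)
  expect_equal(bound_fraction(half), (25 + 50) / 2 / 200)
  expect_error(bound_fraction(mk_traj(matrix("U", 2, 50), titrate = FALSE)),
               "titrated")
})

test_that("spectral estimator localizes canonical fields correctly", {
  N <- 256
  # deterministic alternating field: all mass at the Nyquist line q = pi
  alt <- matrix(rep(c(1, 0), N / 2), nrow = 12, ncol = N, byrow = TRUE)
  sp <- field_power_spectrum(alt)
  expect_equal(sp$q[which.max(sp$G)], pi, tolerance = 1e-9)
  expect_gt(max(sp$G) / (mean(sp$G[sp$q < 3]) + 1e-12), 100)
  # constant field: detrending removes everything
  flat <- field_power_spectrum(matrix(1, 12, N))
  expect_true(all(flat$G < 1e-20))
  # i.i.d. coin flips: white spectrum, no log-log trend
  set.seed(14)
  coin <- matrix(rbinom(100 * 512, 1, 0.5), nrow = 100)
  spc <- field_power_spectrum(coin)
  fit <- lm(log(G) ~ log(q), data = spc)
  slope_se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(coef(fit)[2]), 3 * slope_se + 0.05)
})

test_that("multitaper option gives a consistent white-noise level", {
  set.seed(15)
  coin <- matrix(rbinom(60 * 512, 1, 0.5), nrow = 60)
  s1 <- field_power_spectrum(coin, method = "hann")
  s2 <- field_power_spectrum(coin, method = "multitaper")
  # both estimate the same flat density p(1-p) = 0.25
  expect_equal(mean(s1$G), 0.25, tolerance = 0.05)
  expect_equal(mean(s2$G), 0.25, tolerance = 0.05)
})

test_that("an exact Lorentzian is inverted to its correlation length", {
  sp <- synth_lorentzian_spectrum(c1 = 4, c2 = 0.04, length = 1024)
  fit <- correlation_length(sp)
  expect_equal(fit$xi, 5, tolerance = 1e-6)
  expect_equal(fit$c1, 4, tolerance = 1e-6)
  expect_lt(fit$fit_rmse, 1e-10)
  expect_error(correlation_length(data.frame(q = c(0.1, 0.2),
                                             G = c(1, 1))), "4 spectral")
  neg <- sp; neg$G[3] <- -1
  expect_error(correlation_length(neg), "positive")
})

test_that("Markov-field correlation length is recovered within tolerance", {
  xi_true <- 5
  p_flip <- (1 - exp(-1 / xi_true)) / 2
  x <- synth_markov_field(p_flip, length = 2048, n_samples = 120, seed = 33)
  fit <- correlation_length(field_power_spectrum(x))
  expect_lt(abs(fit$xi - xi_true) / xi_true, 0.10)
  # short-correlation regime is harder; 15% band
  x2 <- synth_markov_field(0.25, length = 2048, n_samples = 120, seed = 34)
  fit2 <- correlation_length(field_power_spectrum(x2))
  expect_lt(abs(fit2$xi - attr(x2, "xi")) / attr(x2, "xi"), 0.15)
})

test_that("more samples tighten the correlation-length estimate", {
  p_flip <- (1 - exp(-1 / 5)) / 2
  xi_at <- function(n, seed) {
    x <- synth_markov_field(p_flip, length = 1024, n_samples = n,
                            seed = seed)
    correlation_length(field_power_spectrum(x))$xi
  }
  few <- vapply(1:5, function(s) xi_at(25, 100 + s), numeric(1))
  many <- vapply(1:5, function(s) xi_at(100, 200 + s), numeric(1))
  expect_lt(sd(many), sd(few))
})

test_that("domain density reads the silenced plateau", {
  # solid left domain at density 1, active right half
  cfgs <- rbind(c(rep("S", 50), rep("E", 50)))
  tr <- mk_traj(cfgs, pin_left = 5, pin_right = 5)
  expect_equal(domain_sir_density(tr), 1)
  # dilute silencing with no majority site falls back to the global mean
  set.seed(16)
  dil <- matrix(sample(c("S", "E"), 2000, TRUE, prob = c(0.2, 0.8)), 20, 100)
  trd <- mk_traj(dil, pin_left = 5, pin_right = 5)
  expect_lt(domain_sir_density(trd), 0.5)
})
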