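test_that("simulated trials have the right shape and are seed-reproducible", {
  d <- design_years(2)
  dat <- simulate_trial(mci, d, 50, mci_effect, seed = 5)
  expect_equal(nrow(dat), 50 * d$n_visits)
  expect_equal(sort(unique(dat$time)), d$visit_times)
  expect_true(all(table(dat$subject) == d$n_visits))
  expect_equal(sum(tapply(dat$arm, dat$subject, `[`, 1)), 25)
  dat2 <- simulate_trial(mci, d, 50, mci_effect, seed = 5)
  expect_identical(dat, dat2)
})

test_that("noise-free trajectories follow the mean structure", {
  quiet <- mlmm_params(beta2 = c(0.5, -0.2), beta0 = c(1, 2),
                       sigma_b = diag(1e-12, 2),
                       sigma_eps = diag(1e-12, 2))
  eff <- effect_spec(gamma = c(-0.1, 0.05))
  d <- design_years(2)
  dat <- simulate_trial(quiet, d, 10, eff, seed = 1)
  g <- gamma_star(eff, quiet)
  for (j in 1:2) {
    expected <- quiet$beta0[j] + (quiet$beta2[j] + g[j] * dat$arm) * dat$time
    expect_equal(dat[[quiet$labels[j]]], unname(expected), tolerance = 1e-5)
  }
})

test_that("baseline cross-sectional covariance matches sigma_eps + sigma_b", {
  d <- design_years(2)
  dat <- simulate_trial(mci, d, 20000, NULL, seed = 99)
  base <- as.matrix(dat[dat$time == 0, mci$labels])
  S <- cov(base)
  truth <- mci$sigma_eps + mci$sigma_b
  # moment check: entrywise within ~3 standard errors (var of a sample
  # covariance entry is approx (s_ii s_jj + s_ij^2) / n)
  se <- sqrt((diag(truth) %o% diag(truth) + truth^2) / 20000)
  expect_true(all(abs(S - truth) < 3.5 * se))
})

test_that("GLS with known covariances recovers noise-free effects exactly", {
  quiet <- mlmm_params(beta2 = c(0.5, -0.2), beta0 = c(1, 2),
                       sigma_b = diag(2) * 1e-12, sigma_eps = diag(2) * 1e-12)
  eff <- effect_spec(gamma = c(-0.1, 0.05))
  dat <- simulate_trial(quiet, design_years(2), 8, eff, seed = 2)
  fit <- gls_fit(dat, quiet)
  expect_equal(unname(fit$gamma_hat), gamma_star(eff, quiet),
               tolerance = 1e-4)
  expect_equal(unname(fit$beta2_hat), unname(quiet$beta2), tolerance = 1e-4)
})

test_that("the GLS estimator is unbiased with the advertised covariance", {
  d <- design_years(2)
  n <- 400
  g <- gamma_star(mci_effect, mci)
  reps <- 2000
  set.seed(7)
  arm <- rep(c(1L, 0L), each = n / 2)
  draws <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    Y <- mlmmpower:::sim_response_matrix(mci, d, arm, g)
    draws[r, ] <- mlmmpower:::gls_core(Y, arm, d$visit_times, mci)$gamma_hat
  }
  sg_n <- gamma_covariance(mci, d)$sigma_gamma1 / n
  mc_se <- sqrt(diag(sg_n) / reps)
  expect_true(all(abs(colMeans(draws) - g) < 3 * mc_se))
  expect_lt(norm(cov(draws) - sg_n, "F") / norm(sg_n, "F"), 0.10)
})

test_that("Wald statistics obey the algebraic ordering and null calibration", {
  d <- design_years(2)
  set.seed(13)
  arm <- rep(c(1L, 0L), each = 50)
  w <- unclass(equal_weights(3))
  xi_j <- numeric(500)
  for (r in 1:500) {
    Y <- mlmmpower:::sim_response_matrix(mci, d, arm, c(0, 0, 0))
    xs <- mlmmpower:::wald_core(Y, arm, d$visit_times, mci, w)
    expect_lte(xs["xi_jc"], xs["xi_j"] + 1e-10)
    xi_j[r] <- xs["xi_j"]
  }
  # under the null the joint statistic is chi-square with J df: mean J
  expect_lt(abs(mean(xi_j) - 3), 3 * sd(xi_j) / sqrt(500))

  # single component: the three statistics coincide
  p1 <- toy1(sigma_b = 0.4, sigma_eps = 1, beta2 = 0.3)
  dat <- simulate_trial(p1, d, 40, effect_spec(0.25), seed = 3)
  xs1 <- wald_statistics(dat, p1, 1)
  expect_equal(unname(xs1["xi_jc"]), unname(xs1["xi_j"]), tolerance = 1e-10)
  expect_equal(unname(xs1["xi_c"]), unname(xs1["xi_j"]), tolerance = 1e-10)
})

test_that("type-I error of the simulated tests sits at the nominal level", {
  d <- design_years(2)
  ep <- empirical_power(mci, d, 80, effect = NULL, statistic = "J",
                        reps = 2000, seed = 17)
  expect_lt(abs(ep$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("empirical power of the weighted-effect test dominates the composite test", {
  d <- design_years(6)
  set.seed(29)
  for (i in 1:20) {
    w <- abs(random_unit_weights(3))
    # variance ordering implies power ordering at any common sample size
    s2 <- composite_gamma_variance(w, mci, d)$sigma_gamma1_sq
    sg <- gamma_covariance(mci, d)$sigma_gamma1
    expect_gte(s2, drop(t(w) %*% sg %*% w) - 1e-12)
  }
  # and on simulated data the rejection rates respect the same order
  n <- 200
  pj <- empirical_power(mci, d, n, mci_effect, "JC", "equal",
                        reps = 600, seed = 31)
  pc <- empirical_power(mci, d, n, mci_effect, "C", "equal",
                        reps = 600, seed = 31)
  se <- sqrt(pj$power * (1 - pj$power) / 600)
  expect_gte(pj$power, pc$power - 3 * se)
})
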