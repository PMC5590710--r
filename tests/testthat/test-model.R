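test_that("subject design matrix has the documented layout", {
  d <- trial_design(visit_times = c(0, 0.5))
  Xc <- subject_design_matrix(d, 1, "control")
  Xt <- subject_design_matrix(d, 1, "treated")
  expect_equal(Xc, rbind(c(1, 0, 0), c(1, 0.5, 0)))
  expect_equal(Xt, rbind(c(1, 0, 0), c(1, 0.5, 0.5)))

  d5 <- trial_design(visit_times = c(0, 0.5, 1, 1.5, 2))
  X <- subject_design_matrix(d5, 3, "control")
  expect_equal(dim(X), c(15L, 9L))
  expect_true(all(X[, 7:9] == 0))
  Xt5 <- subject_design_matrix(d5, 3, "treated")
  # interaction block equals the time block in the treated arm
  expect_equal(Xt5[, 7:9], Xt5[, 4:6])
})

test_that("marginal covariance has the compound-symmetric block structure", {
  p <- toy2()
  expect_equal(marginal_covariance(p, 1), p$sigma_eps + p$sigma_b,
               ignore_attr = TRUE)
  V <- marginal_covariance(p, 3)
  expect_equal(dim(V), c(6L, 6L))
  for (t in 1:3) {
    blk <- V[(t - 1) * 2 + 1:2, (t - 1) * 2 + 1:2]
    expect_equal(blk, unname(p$sigma_eps + p$sigma_b))
  }
  expect_equal(V[1:2, 3:4], unname(p$sigma_b))
  # round trip: the blocks recover both inputs exactly
  expect_equal(V[1:2, 1:2] - V[1:2, 3:4], unname(p$sigma_eps))
  # packaged values: top-left entry is the total variance 0.56 + 0.58
  expect_equal(marginal_covariance(mci, 4)[1, 1], 1.14)
})

test_that("average information matches the hand-computed toy and is symmetric in arms", {
  p <- toy1()
  d <- trial_design(visit_times = c(0, 1))
  Ibar <- participant_information(p, d)
  expect_equal(Ibar,
               matrix(c(2, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 0.5), 3),
               tolerance = 1e-12)
  # swapping allocation between identical arms changes nothing at 1/2
  d2 <- trial_design(visit_times = c(0, 1), allocation = 0.5)
  expect_equal(participant_information(p, d2), Ibar)
  # Loewner monotonicity: more visits never lose information
  I4 <- participant_information(p, trial_design(visit_times = c(0, 0.5, 1)))
  ev <- eigen(I4 - Ibar, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("treatment-effect covariance: toy value, invariances, limits", {
  p <- toy1()
  d <- trial_design(visit_times = c(0, 1))
  gc <- gamma_covariance(p, d)
  expect_equal(gc$sigma_gamma1[1, 1], 4, tolerance = 1e-10)

  # invariant to intercepts and to shifting the rates
  p2 <- mlmm_params(beta2 = mci$beta2 + 5, sigma_b = mci$sigma_b,
                    sigma_eps = mci$sigma_eps, beta0 = c(10, -3, 2))
  d2 <- design_years(2)
  expect_equal(gamma_covariance(p2, d2)$sigma_gamma1,
               gamma_covariance(mci, d2)$sigma_gamma1, ignore_attr = TRUE)

  # enlarging the error covariance never decreases the covariance (Loewner)
  bump <- mlmm_params(beta2 = mci$beta2, sigma_b = mci$sigma_b,
                      sigma_eps = mci$sigma_eps + diag(0.3, 3))
  dS <- gamma_covariance(bump, d2)$sigma_gamma1 -
    gamma_covariance(mci, d2)$sigma_gamma1
  expect_gte(min(eigen(dS, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # huge random-intercept variance: only within-subject contrasts remain,
  # Sigma_gamma1 -> 4 * Sigma_eps / S_tt
  big <- mlmm_params(beta2 = mci$beta2, sigma_b = 1e6 * mci$sigma_b,
                     sigma_eps = mci$sigma_eps)
  tt <- d2$visit_times
  Stt <- sum((tt - mean(tt))^2)
  lim <- 4 * mci$sigma_eps / Stt
  got <- gamma_covariance(big, d2)$sigma_gamma1
  expect_lt(max(abs(got - lim) / abs(lim)), 1e-3)

  expect_error(gamma_covariance(p, trial_design(visit_times = 0)),
               "increasing|two visits|slope")
})

test_that("composite variance components are the advertised quadratic forms", {
  expect_equal(composite_variance_components(c(1, 0, 0), mci),
               c(sigma_a2 = 0.58, sigma_d2 = 0.56))
  wz <- unclass(equal_weights(3))
  vc <- composite_variance_components(wz, mci)
  expect_equal(unname(vc["sigma_a2"]), sum(mci$sigma_b) / 3,
               tolerance = 1e-12)
  expect_equal(unname(vc["sigma_a2"]), 1.453333, tolerance = 1e-6)
  # quadratic: doubling the weights quadruples both components
  expect_equal(composite_variance_components(2 * wz, mci), 4 * vc)
  expect_error(composite_variance_components(c(1, 0), mci), "length")
})

test_that("composite pipeline agrees with the multivariate one when J = 1", {
  p <- toy1(sigma_b = 0.3, sigma_eps = 1.2)
  d <- design_years(3)
  s_multi <- gamma_covariance(p, d)$sigma_gamma1[1, 1]
  s_comp <- composite_gamma_variance(1, p, d)$sigma_gamma1_sq
  expect_equal(s_comp, s_multi, tolerance = 1e-12)
})

test_that("composite-score estimator is never more precise than the joint fit", {
  d <- design_years(2)
  sg <- gamma_covariance(mci, d)$sigma_gamma1
  set.seed(11)
  for (i in 1:100) {
    w <- random_unit_weights(3)
    s2 <- composite_gamma_variance(w, mci, d)$sigma_gamma1_sq
    expect_gte(s2, drop(t(w) %*% sg %*% w) - 1e-12)
  }
  # large-Sigma_b limit for the composite route as well
  big <- mlmm_params(beta2 = mci$beta2, sigma_b = 1e6 * mci$sigma_b,
                     sigma_eps = mci$sigma_eps)
  w <- unclass(equal_weights(3))
  tt <- d$visit_times
  lim <- 4 * drop(t(w) %*% mci$sigma_eps %*% w) / sum((tt - mean(tt))^2)
  expect_equal(composite_gamma_variance(w, big, d)$sigma_gamma1_sq, lim,
               tolerance = 1e-3)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(mlmm_params(beta2 = c(0.1, 0.2),
                           sigma_b = matrix(c(1, 0.5, 0.4, 1), 2),
                           sigma_eps = diag(2)), "symmetric")
  expect_error(mlmm_params(beta2 = 0.1, sigma_b = matrix(1),
                           sigma_eps = matrix(0)), "positive definite")
  expect_error(mlmm_params(beta2 = 0.1, sigma_b = matrix(-1),
                           sigma_eps = matrix(1)), "semi-definite")
  expect_error(trial_design(2, interval = 0.3), "multiple")
  expect_error(trial_design(visit_times = c(0.5, 1)), "start at 0")
})
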