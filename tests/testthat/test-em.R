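test_that("EM log-likelihood ascends and matches the standalone evaluator", {
  set.seed(4)
  dat <- simulate_trial(toy2(), design_years(3), 120, NULL, seed = 4)
  fit <- mlmm_fit(dat, model = "time_only")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-9 * (abs(fit$loglik) + 1)))
  # the trace's final value is the likelihood at the final parameters,
  # up to the last covariance update
  ll <- mlmm_loglik(dat, as_mlmm_params(fit))
  expect_equal(ll, fit$loglik, tolerance = 1e-4)
})

test_that("log-likelihood agrees with a dense multivariate-normal oracle", {
  p <- toy2()
  dat <- simulate_trial(p, design_years(2), 5, NULL, seed = 8)
  ll <- mlmm_loglik(dat, p)
  # brute force: build each subject's full covariance and density directly
  d <- design_years(2)
  Tn <- d$n_visits
  V <- diag(Tn) %x% p$sigma_eps + matrix(1, Tn, Tn) %x% p$sigma_b
  ll_oracle <- 0
  for (s in unique(dat$subject)) {
    rows <- dat[dat$subject == s, ]
    y <- as.vector(t(as.matrix(rows[, p$labels])))
    mu <- as.vector(vapply(rows$time, function(t) p$beta0 + p$beta2 * t,
                           numeric(2)))
    k <- length(y)
    ll_oracle <- ll_oracle -
      0.5 * (k * log(2 * pi) + determinant(V)$modulus[1] +
               drop(t(y - mu) %*% solve(V) %*% (y - mu)))
  }
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("single-outcome EM reproduces the lme4 maximum likelihood fit", {
  skip_if_not_installed("lme4")
  p <- toy1(sigma_b = 0.5, sigma_eps = 1, beta2 = 0.4)
  dat <- simulate_trial(p, design_years(4), 150, NULL, seed = 12)
  fit <- mlmm_fit(dat, components = "Y1", model = "time_only",
                  max_iter = 10000, tol = 1e-13)
  lm4 <- lme4::lmer(Y1 ~ time + (1 | subject), data = dat, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-6)
  expect_equal(unname(fit$beta2), unname(lme4::fixef(lm4)["time"]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$sigma_b[1, 1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma_eps[1, 1], vc$vcov[2], tolerance = 1e-3)
})

test_that("EM handles unbalanced visit sets and near-noise-free initialization", {
  set.seed(9)
  dat <- simulate_trial(toy2(), design_years(3), 100, NULL, seed = 9)
  drop_rows <- sample(nrow(dat), 0.2 * nrow(dat))
  # never drop a subject's first visit so everyone keeps >= 1 row
  drop_rows <- drop_rows[dat$time[drop_rows] > 0]
  sparse <- dat[-drop_rows, ]
  fit <- mlmm_fit(sparse, model = "time_only")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-9 * (abs(fit$loglik) + 1)))
  expect_lt(max(abs(fit$beta2 - toy2()$beta2)),
            5 * max(sqrt(diag(fit$fixef_cov))))

  # with almost no noise and a truthful start the fixed point is immediate
  quiet <- mlmm_params(beta2 = 0.5, sigma_b = matrix(1e-6),
                       sigma_eps = matrix(1e-6))
  qdat <- simulate_trial(quiet, design_years(2), 30, NULL, seed = 10)
  qfit <- mlmm_fit(qdat, components = "Y1", model = "time_only",
                   init = list(beta = c(0, 0.5), sigma_b = matrix(1e-6),
                               sigma_eps = matrix(1e-6)))
  expect_lte(qfit$iterations, 10)
  expect_true(qfit$converged)
})

test_that("interaction model recovers a simulated treatment effect", {
  eff <- effect_spec(gamma = c(-0.15, 0.1))
  dat <- simulate_trial(toy2(), design_years(4), 400, eff, seed = 14)
  fit <- mlmm_fit(dat, model = "time_plus_interaction")
  se <- sqrt(diag(fit$fixef_cov))[5:6]
  expect_true(all(abs(fit$gamma - c(-0.15, 0.1)) < 3 * se))
})

test_that("estimated parameters feed back into the power engine consistently", {
  panel <- trial_design(10)
  dat <- simulate_trial(mci, panel, 600, NULL, seed = 16)
  fit <- mlmm_fit(dat, model = "time_only")
  n_est <- sample_size(as_mlmm_params(fit), mci_effect, design_years(2),
                       "JC", "optimal_jc")
  n_true <- sample_size(mci, mci_effect, design_years(2), "JC", "optimal_jc")
  expect_lt(abs(n_est - n_true) / n_true, 0.05)
})

test_that("fit accessors expose the usual modelling interface", {
  dat <- simulate_trial(toy2(), design_years(2), 60, NULL, seed = 20)
  fit <- mlmm_fit(dat, model = "time_only")
  expect_named(coef(fit), c("beta0.Y1", "beta0.Y2", "beta2.Y1", "beta2.Y2"))
  expect_s3_class(summary(fit), "summary.mlmm_fit")
  expect_equal(attr(logLik(fit), "nobs"), nrow(dat))
  res <- residuals(fit, dat)
  expect_equal(dim(res), c(nrow(dat), 2L))
  expect_equal(res + fitted(fit, dat),
               as.matrix(dat[, c("Y1", "Y2")]), ignore_attr = TRUE)
  sim <- simulate(fit, design = design_years(2), n = 10, seed = 1)
  expect_s3_class(sim, "mlmm_trial")
})
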