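# Shared fixtures: a single-outcome toy model with unit error variance and
# no random intercept (hand-checkable), a correlated two-outcome model,
# and the packaged MCI parameter set.

toy1 <- function(sigma_b = 0, sigma_eps = 1, beta2 = 1)
  mlmm_params(beta2 = beta2, sigma_b = matrix(sigma_b),
              sigma_eps = matrix(sigma_eps))

toy2 <- function()
  mlmm_params(beta2 = c(0.5, 0.2),
              sigma_b = matrix(c(0.4, 0.1, 0.1, 0.3), 2),
              sigma_eps = matrix(c(1, 0.2, 0.2, 0.8), 2))

mci <- adni_mci_params()
mci_effect <- effect_spec(reduction = 0.25)

design_years <- function(d, ...) trial_design(duration = d, ...)

random_unit_weights <- function(J) {
  w <- rnorm(J)
  w / sqrt(sum(w^2))
}
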