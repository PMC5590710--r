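#' Simulate a complete two-arm longitudinal trial
#'
#' Draws component scores from the multivariate random-intercept model:
#' per subject a random intercept vector from `N(0, sigma_b)` and
#' independent per-visit errors from `N(0, sigma_eps)`.  Arm assignment
#' is deterministic (the first `ceiling(n * allocation)` subjects are
#' treated) so that simulated power targets the design exactly rather
#' than a randomized allocation.
#'
#' @param params An [mlmm_params()].
#' @param design A [trial_design()].
#' @param n Total number of participants (both arms).
#' @param effect An [effect_spec()], or `NULL` for no treatment effect
#'   (null simulation).
#' @param seed Optional integer seed for reproducibility.
#' @return A long-format data frame with columns `subject`, `arm`
#'   (0 control / 1 treated), `time` (years) and one column per
#'   component label, carrying the generating `params`, `design`, `seed`
#'   and `gamma` as attributes.
#' @export
simulate_trial <- function(params, design, n, effect = NULL, seed = NULL) {
  stopifnot(inherits(params, "mlmm_params"), inherits(design, "trial_design"),
            n >= 2)
  gamma <- if (is.null(effect)) numeric(params$J) else gamma_star(effect, params)
  if (!is.null(seed)) set.seed(seed)
  n_t <- ceiling(n * design$allocation)
  arm <- rep(c(1L, 0L), c(n_t, n - n_t))
  Y <- sim_response_matrix(params, design, arm, gamma)
  times <- design$visit_times
  Tn <- length(times); J <- params$J
  out <- data.frame(
    subject = rep(seq_len(n), each = Tn),
    arm = rep(arm, each = Tn),
    time = rep(times, times = n))
  # Y columns are visit-major (component fastest); pick out component j
  for (j in seq_len(J))
    out[[params$labels[j]]] <- as.vector(t(Y[, (seq_len(Tn) - 1L) * J + j,
                                             drop = FALSE]))
  attr(out, "params") <- params
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  attr(out, "gamma") <- gamma
  class(out) <- c("mlmm_trial", "data.frame")
  out
}

# n x (T*J) response matrix, columns visit-major (component fastest)
sim_response_matrix <- function(params, design, arm, gamma) {
  J <- params$J
  times <- design$visit_times
  Tn <- length(times)
  n <- length(arm)
  theta <- c(params$beta0, params$beta2, gamma)
  mu_c <- drop(subject_design_matrix(design, J, 0) %*% theta)
  mu_t <- drop(subject_design_matrix(design, J, 1) %*% theta)
  cb <- chol(sym_psd_for_chol(params$sigma_b))
  ce <- chol(params$sigma_eps)
  # shared random intercept replicated across visits, fresh error per visit
  b <- matrix(stats::rnorm(n * J), n, J) %*% cb
  Y <- b[, rep(seq_len(J), Tn), drop = FALSE]
  for (t in seq_len(Tn))
    Y[, (t - 1L) * J + seq_len(J)] <- Y[, (t - 1L) * J + seq_len(J)] +
      matrix(stats::rnorm(n * J), n, J) %*% ce
  Y + outer(1 - arm, mu_c) + outer(arm, mu_t)
}

# allow exactly singular (e.g. zero) random-intercept covariance
sym_psd_for_chol <- function(S) {
  S + diag(nrow(S)) * (1e-12 * max(1, max(abs(S))))
}

#' Generalized-least-squares fit with known covariance matrices
#'
#' The maximum-likelihood estimator of the fixed effects when
#' `sigma_b` and `sigma_eps` are treated as known: closed-form weighted
#' least squares with each subject's marginal covariance `V`.  The
#' estimator covariance is the inverse total information, whose
#' gamma-block reproduces [gamma_covariance()] divided by `N` when the
#' arms are split per the design.
#'
#' @param data A complete long-format trial data frame as produced by
#'   [simulate_trial()] (columns `subject`, `arm`, `time`, components).
#' @param params The [mlmm_params()] supplying the known covariances
#'   (its `beta` values are not used).
#' @return An object of class `"gls_fit"`: list with `beta0_hat`,
#'   `beta2_hat`, `gamma_hat`, `gamma_cov` (covariance of `gamma_hat`
#'   at this sample size), `loglik`, `n`, and the visit grid.
#' @export
gls_fit <- function(data, params) {
  stopifnot(inherits(params, "mlmm_params"))
  parts <- trial_to_matrix(data, params)
  gls_core(parts$Y, parts$arm, parts$times, params)
}

trial_to_matrix <- function(data, params) {
  need <- c("subject", "arm", "time", params$labels)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "))
  data <- data[order(data$subject, data$time), , drop = FALSE]
  times <- sort(unique(data$time))
  Tn <- length(times)
  subj <- unique(data$subject)
  n <- length(subj)
  if (nrow(data) != n * Tn)
    stop("data must be complete: every subject observed at every visit time")
  arm <- data$arm[match(subj, data$subject)]
  J <- params$J
  Y <- matrix(0, n, Tn * J)
  for (j in seq_len(J))
    Y[, (seq_len(Tn) - 1L) * J + j] <-
      matrix(data[[params$labels[j]]], n, Tn, byrow = TRUE)
  list(Y = Y, arm = as.integer(arm), times = times)
}

gls_core <- function(Y, arm, times, params) {
  J <- params$J
  des <- trial_design(visit_times = times)
  V <- marginal_covariance(params, length(times))
  Vi <- chol2inv(chol(V))
  Xc <- subject_design_matrix(des, J, 0)
  Xt <- subject_design_matrix(des, J, 1)
  n_t <- sum(arm == 1L); n_c <- sum(arm == 0L)
  if (n_t == 0L || n_c == 0L)
    stop("both arms must be present to identify the treatment effect")
  Ac <- crossprod(Xc, Vi); At <- crossprod(Xt, Vi)
  info <- n_c * (Ac %*% Xc) + n_t * (At %*% Xt)
  s_c <- colSums(Y[arm == 0L, , drop = FALSE])
  s_t <- colSums(Y[arm == 1L, , drop = FALSE])
  theta <- drop(solve(info, Ac %*% s_c + At %*% s_t))
  covtheta <- solve(info)
  gidx <- 2L * J + seq_len(J)
  resid_quad <- function(rows, X) {
    if (!length(rows)) return(0)
    R <- Y[rows, , drop = FALSE] -
      matrix(drop(X %*% theta), length(rows), ncol(Y), byrow = TRUE)
    sum((R %*% Vi) * R)
  }
  q <- resid_quad(which(arm == 0L), Xc) + resid_quad(which(arm == 1L), Xt)
  n <- length(arm)
  ll <- -0.5 * (n * (ncol(Y) * log(2 * pi) +
                       2 * sum(log(diag(chol(V))))) + q)
  structure(
    list(beta0_hat = stats::setNames(theta[seq_len(J)], params$labels),
         beta2_hat = stats::setNames(theta[J + seq_len(J)], params$labels),
         gamma_hat = stats::setNames(theta[gidx], params$labels),
         gamma_cov = covtheta[gidx, gidx, drop = FALSE],
         loglik = ll, n = n, times = times, J = J),
    class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("GLS fit (known covariances), n = ", x$n, "\n", sep = "")
  cat("  gamma_hat: ", paste(signif(x$gamma_hat, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' The three Wald statistics on one trial dataset
#'
#' Computes the joint statistic
#' \eqn{\Xi_J = \hat\gamma' \Sigma_\gamma^{-1} \hat\gamma}, the
#' weighted-effect statistic
#' \eqn{\Xi_{JC}(w) = (w'\hat\gamma)^2 / (w' \Sigma_\gamma w)} from the
#' multivariate fit, and the composite-score statistic
#' \eqn{\Xi_C(w) = \hat\gamma_w^2 / \sigma_\gamma^2} from a separate
#' univariate fit to the weighted composite scores.  For every dataset
#' and every `w`, `xi_jc <= xi_j` (Rayleigh bound); with one component
#' the three coincide.
#'
#' @inheritParams gls_fit
#' @param w Weight vector of length `J`.
#' @return Named numeric vector `c(xi_j, xi_jc, xi_c)`.
#' @export
wald_statistics <- function(data, params, w) {
  w <- as.numeric(unclass(w))
  parts <- trial_to_matrix(data, params)
  wald_core(parts$Y, parts$arm, parts$times, params, w)
}

wald_core <- function(Y, arm, times, params, w) {
  fit <- gls_core(Y, arm, times, params)
  xi_j <- drop(t(fit$gamma_hat) %*% solve(fit$gamma_cov, fit$gamma_hat))
  xi_jc <- sum(w * fit$gamma_hat)^2 / drop(t(w) %*% fit$gamma_cov %*% w)
  # composite route: collapse the scores, refit the univariate model
  Tn <- length(times); J <- params$J
  Wmat <- matrix(0, Tn * J, Tn)
  for (t in seq_len(Tn)) Wmat[(t - 1L) * J + seq_len(J), t] <- w
  Yw <- Y %*% Wmat
  vc <- composite_variance_components(w, params)
  p1 <- mlmm_params(beta2 = 0, sigma_b = matrix(vc[["sigma_a2"]]),
                    sigma_eps = matrix(vc[["sigma_d2"]]),
                    labels = "composite")
  fitw <- gls_core(Yw, arm, times, p1)
  xi_c <- unname(fitw$gamma_hat[1]^2 / fitw$gamma_cov[1, 1])
  c(xi_j = xi_j, xi_jc = unname(xi_jc), xi_c = xi_c)
}

#' Monte-Carlo power of a Wald test
#'
#' Simulates complete trials from the model, applies the
#' known-covariance GLS fit and the requested Wald statistic to each
#' replicate, and reports the proportion rejecting at the central
#' chi-square (or one-sided normal) critical value, with its binomial
#' standard error.  This is the brute-force check of the analytic
#' noncentral chi-square power.
#'
#' @inheritParams power_analysis
#' @param n Total sample size to simulate.
#' @param reps Number of simulated trials.
#' @param seed Integer seed.
#' @return List with `power`, `se`, `reps`, `n`, `statistic`, `reject`
#'   (logical vector) and `stat_values`.
#' @export
empirical_power <- function(params, design, n, effect,
                            statistic = c("J", "JC", "C"), weights = NULL,
                            reps = 2000, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(reps >= 10)
  gamma <- if (is.null(effect)) numeric(params$J) else gamma_star(effect, params)
  w <- NULL
  if (statistic != "J") {
    if (is.null(weights))
      stop("statistic '", statistic, "' requires 'weights'")
    w <- unclass(resolve_weights(weights, params,
                                 effect_spec(gamma = gamma), design, NULL))
  }
  set.seed(seed)
  n_t <- ceiling(n * design$allocation)
  arm <- rep(c(1L, 0L), c(n_t, n - n_t))
  one_sided <- design$sidedness == "one_sided_z"
  if (one_sided && statistic == "J")
    stop("one-sided testing applies only to the 1-df statistics")
  stats_out <- numeric(reps)
  for (r in seq_len(reps)) {
    Y <- sim_response_matrix(params, design, arm, gamma)
    xs <- wald_core(Y, arm, design$visit_times, params,
                    if (is.null(w)) rep(1, params$J) else w)
    stats_out[r] <- switch(statistic, J = xs["xi_j"], JC = xs["xi_jc"],
                           C = xs["xi_c"])
  }
  df <- if (statistic == "J") params$J else 1L
  if (one_sided) {
    # signed root against the direction of the specified alternative
    reject <- sqrt(stats_out) > stats::qnorm(1 - design$alpha)
  } else {
    reject <- stats_out > stats::qchisq(1 - design$alpha, df)
  }
  p <- mean(reject)
  list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps, n = n,
       statistic = statistic, reject = reject, stat_values = stats_out)
}
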