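#' Power of a (noncentral) chi-square Wald test
#'
#' Probability that a noncentral chi-square variate with `df` degrees of
#' freedom and noncentrality `ncp` exceeds the upper-`alpha` quantile of
#' the central chi-square.  Equals `alpha` at `ncp = 0` and is strictly
#' increasing in `ncp`.
#'
#' @param df Degrees of freedom.
#' @param ncp Noncentrality parameter, `>= 0`.
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @export
chi2_power <- function(df, ncp, alpha = 0.05) {
  stopifnot(df >= 1, all(ncp >= 0), alpha > 0, alpha < 1)
  stats::pchisq(stats::qchisq(1 - alpha, df), df, ncp = ncp,
                lower.tail = FALSE)
}

#' Noncentrality required for a target power
#'
#' Solves `chi2_power(df, lambda, alpha) = target_power` for `lambda` by
#' bracketed root finding.  For `df = 1` this agrees with the classical
#' normal identity \eqn{(z_{1-\alpha/2} + z_{power})^2}.
#'
#' @inheritParams chi2_power
#' @param target_power Desired power, must exceed `alpha`.
#' @return Required noncentrality `lambda_req`.
#' @export
required_noncentrality <- function(df, alpha = 0.05, target_power = 0.80) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  if (target_power <= alpha)
    stop("'target_power' must exceed 'alpha'")
  stats::uniroot(function(l) chi2_power(df, l, alpha) - target_power,
                 interval = c(0, 1e4), tol = 1e-10, extendInt = "upX")$root
}

#' Per-participant noncentrality of the three Wald statistics
#'
#' The noncentrality at total sample size `N` is `N * lambda1` with
#' \describe{
#'   \item{`"J"`}{\eqn{\lambda_1 = \gamma^{*\prime} \Sigma_{\gamma 1}^{-1}
#'     \gamma^*} (joint test of all component effects, df `J`);}
#'   \item{`"JC"`}{\eqn{\lambda_1 = (w'\gamma^*)^2 / (w'\Sigma_{\gamma 1} w)}
#'     (weighted-composite-effect test, df 1);}
#'   \item{`"C"`}{\eqn{\lambda_1 = (w'\gamma^*)^2 / \sigma^2_{\gamma 1}(w)}
#'     (composite-score test, df 1).}
#' }
#' `lambda1` is invariant to rescaling `w`.
#'
#' @param statistic One of `"J"`, `"JC"`, `"C"`.
#' @param gamma_star Effect vector under the alternative.
#' @param gcov A [gamma_covariance()].
#' @param composite A [composite_gamma_variance()] (required for `"C"`).
#' @param w Weight vector (required for `"JC"` and `"C"`).
#' @return Scalar `lambda1 >= 0`.
#' @export
noncentrality_per_participant <- function(statistic = c("J", "JC", "C"),
                                          gamma_star, gcov,
                                          w = NULL, composite = NULL) {
  statistic <- match.arg(statistic)
  sg <- gcov$sigma_gamma1
  if (statistic == "J")
    return(drop(t(gamma_star) %*% solve(sg, gamma_star)))
  if (is.null(w)) stop("statistic '", statistic, "' requires weights 'w'")
  w <- as.numeric(unclass(w))
  num <- sum(w * gamma_star)^2
  if (num == 0)
    warning("weights are orthogonal to the alternative effect; ",
            "the test has no power beyond alpha")
  if (statistic == "JC")
    return(num / drop(t(w) %*% sg %*% w))
  if (is.null(composite))
    stop("statistic 'C' requires the composite variance")
  num / composite$sigma_gamma1_sq
}

resolve_weights <- function(weights, params, effect, design, gcov) {
  if (inherits(weights, "composite_weights")) return(weights)
  if (is.numeric(weights))
    return(new_weights(weights, "custom", params$labels))
  if (is.character(weights) && length(weights) == 1) {
    if (weights == "equal") return(equal_weights(params$J, params$labels))
    if (weights %in% c("optimal", "optimal_jc"))
      return(optimal_weights_jc(params, effect, design, gcov))
    if (weights == "optimal_c")
      return(optimal_weights_c(params, effect, design))
    if (grepl("^unit_[0-9]+$", weights))
      return(unit_weights(params$J,
                          as.integer(sub("unit_", "", weights)),
                          params$labels))
  }
  stop("cannot interpret 'weights'; give a numeric vector or one of ",
       "\"equal\", \"optimal_jc\", \"optimal_c\", \"unit_<j>\"")
}

#' Analytic power and required sample size for a Wald test
#'
#' Computes the per-participant noncentrality of the requested statistic,
#' the noncentrality needed for the design's target power, and the total
#' required sample size `N = ceiling(lambda_req / lambda1)` (both arms
#' combined).  With `design$sidedness == "one_sided_z"` the 1-df
#' statistics are used as signed-root Z tests against the beneficial
#' direction, requiring \eqn{(z_{1-\alpha} + z_{power})^2} instead.
#'
#' @param params An [mlmm_params()].
#' @param effect An [effect_spec()].
#' @param design A [trial_design()].
#' @param statistic `"J"` (joint, df `J`), `"JC"` (weighted composite
#'   effect, df 1) or `"C"` (composite score, df 1).
#' @param weights Weight vector, `"composite_weights"` object, or one of
#'   the strategy strings `"equal"`, `"optimal_jc"`, `"optimal_c"`,
#'   `"unit_<j>"`.  Ignored for `statistic = "J"`.
#' @return An object of class `"power_result"`: list with `statistic`,
#'   `weights`, `df`, `lambda1`, `lambda_req`, `n_required`, `alpha`,
#'   `target_power`, `sidedness`, and `power_at(n)`, a vectorized
#'   function returning analytic power at any total sample size.
#' @export
power_analysis <- function(params, effect, design,
                           statistic = c("J", "JC", "C"), weights = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(params, "mlmm_params"), inherits(effect, "effect_spec"),
            inherits(design, "trial_design"))
  g <- gamma_star(effect, params)
  gcov <- gamma_covariance(params, design)
  w <- NULL; composite <- NULL
  if (statistic != "J") {
    if (is.null(weights))
      stop("statistic '", statistic, "' requires 'weights'")
    w <- resolve_weights(weights, params, effect, design, gcov)
    if (statistic == "C")
      composite <- composite_gamma_variance(unclass(w), params, design)
  }
  lambda1 <- noncentrality_per_participant(statistic, g, gcov, w, composite)
  df <- if (statistic == "J") params$J else 1L
  one_sided <- design$sidedness == "one_sided_z"
  if (one_sided && statistic == "J")
    stop("the one-sided Z formulation applies only to the 1-df statistics")
  if (lambda1 <= 0)
    stop("the requested test cannot detect this alternative (lambda1 = 0)")
  if (one_sided) {
    lambda_req <- (stats::qnorm(1 - design$alpha) +
                     stats::qnorm(design$target_power))^2
    power_at <- function(n)
      stats::pnorm(sqrt(n * lambda1) - stats::qnorm(1 - design$alpha))
  } else {
    lambda_req <- required_noncentrality(df, design$alpha, design$target_power)
    power_at <- function(n) chi2_power(df, n * lambda1, design$alpha)
  }
  n_required <- max(2L, as.integer(ceiling(lambda_req / lambda1)))
  structure(
    list(statistic = statistic, weights = w, df = df, lambda1 = lambda1,
         lambda_req = lambda_req, n_required = n_required,
         alpha = design$alpha, target_power = design$target_power,
         sidedness = design$sidedness, power_at = power_at),
    class = "power_result")
}

#' @rdname power_analysis
#' @export
sample_size <- function(params, effect, design,
                        statistic = c("J", "JC", "C"), weights = NULL) {
  power_analysis(params, effect, design, statistic, weights)$n_required
}

#' @export
print.power_result <- function(x, ...) {
  cat("Wald test '", x$statistic, "'", sep = "")
  if (!is.null(x$weights))
    cat(" with weights (", attr(x$weights, "strategy"), ") ",
        paste(formatC(unclass(x$weights), digits = 4, format = "f"),
              collapse = ", "), sep = "")
  cat("\n  df = ", x$df,
      ", per-participant noncentrality = ", signif(x$lambda1, 6),
      "\n  required noncentrality (alpha = ", x$alpha,
      ", power = ", x$target_power, ") = ", signif(x$lambda_req, 6),
      "\n  required total sample size N = ", x$n_required,
      " (about ", ceiling(x$n_required / 2), " per arm)\n", sep = "")
  invisible(x)
}

#' Bonferroni comparator: powering each component separately
#'
#' Sizes the trial by testing each component alone with the
#' composite-score statistic at level `alpha / J` and taking the largest
#' of the per-component sample sizes.
#'
#' @inheritParams power_analysis
#' @return List with `n_required` (the maximum) and `per_component`
#'   (named vector of per-component sizes at level `alpha / J`).
#' @export
bonferroni_sample_size <- function(params, effect, design) {
  J <- params$J
  des <- design
  des$alpha <- design$alpha / J
  ns <- vapply(seq_len(J), function(j)
    power_analysis(params, effect, des, "C",
                   unit_weights(J, j, params$labels))$n_required,
    integer(1))
  names(ns) <- params$labels
  list(n_required = max(ns), per_component = ns)
}
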