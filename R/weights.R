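#' Composite weight vectors
#'
#' Weight vectors are L2-normalized (`sum(w^2) == 1`) and sign-fixed so
#' that the weighted sum of the positive rate-reduction magnitudes is
#' positive; under a beneficial treatment every standard strategy then
#' yields non-negative entries.
#'
#' @name composite_weights
NULL

new_weights <- function(w, strategy, labels = NULL) {
  w <- as.numeric(w)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("weight vector must be non-zero")
  w <- w / nrm
  if (!is.null(labels)) names(w) <- labels
  structure(w, strategy = strategy, class = "composite_weights")
}

fix_sign <- function(w, gamma_plus) {
  if (sum(unclass(w) * gamma_plus) < 0) w[] <- -unclass(w)
  w
}

#' @export
print.composite_weights <- function(x, ...) {
  cat("Composite weights (", attr(x, "strategy"), "): ",
    paste(formatC(unclass(x), digits = 4, format = "f"), collapse = ", "),
    "\n", sep = "")
  invisible(x)
}

#' @describeIn composite_weights Equal weights, all entries `J^(-1/2)`.
#' @param J Number of components.
#' @param labels Optional component names.
#' @export
equal_weights <- function(J, labels = NULL) {
  stopifnot(J >= 1)
  new_weights(rep(1, J), "equal", labels)
}

#' @describeIn composite_weights Unit weight on component `j` alone.
#' @param j Component index.
#' @export
unit_weights <- function(J, j, labels = NULL) {
  stopifnot(J >= 1, j >= 1, j <= J)
  w <- numeric(J); w[j] <- 1
  new_weights(w, paste0("unit_", j), labels)
}

#' Optimal weights for the weighted-composite-effect Wald test
#'
#' The noncentrality of the 1-df Wald test of `w' gamma = 0` is the
#' Rayleigh-type quotient \eqn{N (w'\gamma^*)^2 / (w' \Sigma_{\gamma 1} w)},
#' maximized over the unit sphere by
#' \eqn{w \propto \Sigma_{\gamma 1}^{-1} \gamma^*}; at the maximizer the
#' noncentrality equals the full quadratic form
#' \eqn{N \gamma^{*\prime} \Sigma_{\gamma 1}^{-1} \gamma^*} of the joint
#' J-df test.
#'
#' @param params An [mlmm_params()].
#' @param effect An [effect_spec()].
#' @param design A [trial_design()].
#' @param gcov Optionally, a precomputed [gamma_covariance()].
#' @return A `"composite_weights"` vector (strategy `"optimal_jc"`).
#' @export
optimal_weights_jc <- function(params, effect, design, gcov = NULL) {
  g <- gamma_star(effect, params)
  if (all(g == 0)) stop("the alternative-effect vector is zero")
  if (is.null(gcov)) gcov <- gamma_covariance(params, design)
  w <- drop(solve(gcov$sigma_gamma1, g))
  fix_sign(new_weights(w, "optimal_jc", params$labels), abs(g))
}

#' Optimal weights for the composite-score Wald test
#'
#' Maximizes the per-participant noncentrality
#' \eqn{(w'\gamma^*)^2 / \sigma^2_{\gamma 1}(w)} of the test based on the
#' univariate mixed model for the composite score, over the unit sphere.
#' The objective is smooth and scale-invariant, so it is maximized over
#' an unconstrained vector with the normalization inside the objective,
#' by quasi-Newton search from multiple starts (equal weights, the
#' closed-form `optimal_jc` solution, each unit vector, and `n_starts`
#' random directions under a fixed seed); the best converged local
#' maximum is returned after a tangent-gradient stationarity check.
#'
#' @inheritParams optimal_weights_jc
#' @param n_starts Number of additional random starts.
#' @param seed Seed for the random starts.
#' @return A `"composite_weights"` vector (strategy `"optimal_c"`).
#' @export
optimal_weights_c <- function(params, effect, design, n_starts = 32,
                              seed = 20170524) {
  g <- gamma_star(effect, params)
  if (all(g == 0)) stop("the alternative-effect vector is zero")
  J <- params$J
  if (J == 1L) return(new_weights(1, "optimal_c", params$labels))
  Sb <- params$sigma_b; Se <- params$sigma_eps
  obj <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(Inf)
    w <- v / nv
    s2 <- univariate_sigma_gamma1_sq(drop(t(w) %*% Sb %*% w),
                                     drop(t(w) %*% Se %*% w),
                                     design$visit_times, design$allocation)
    -sum(w * g)^2 / s2
  }
  starts <- c(list(unclass(equal_weights(J))),
              list(unclass(optimal_weights_jc(params, effect, design))),
              lapply(seq_len(J), function(j) unclass(unit_weights(J, j))))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  starts <- c(starts, lapply(seq_len(n_starts),
                             function(i) stats::rnorm(J)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(reltol = 1e-8, maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimal_weights_c: no start converged")
  # polish the winning basin to the final objective tolerance
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(reltol = 1e-12, maxit = 500))
  w <- best$par / sqrt(sum(best$par^2))
  # stationarity on the sphere: gradient projected onto the tangent space
  gr <- numeric(J)
  h <- 1e-6
  for (k in seq_len(J)) {
    e <- numeric(J); e[k] <- h
    gr[k] <- (obj(w + e) - obj(w - e)) / (2 * h)
  }
  tang <- gr - sum(gr * w) * w
  if (sqrt(sum(tang^2)) > 1e-6 * max(1, abs(best$value)))
    warning("optimal_weights_c: tangent gradient not fully stationary")
  fix_sign(new_weights(w, "optimal_c", params$labels), abs(g))
}

#' Optimal-weight table across trial durations
#'
#' Computes both optimal weight vectors for a sequence of trial
#' durations, mirroring how sensitivity shifts between components as
#' follow-up lengthens.
#'
#' @inheritParams optimal_weights_jc
#' @param durations Numeric vector of trial durations in years.
#' @param interval Visit spacing in years.
#' @return A data frame with columns `weights`, `component`, and one
#'   column per duration.
#' @export
optimal_weight_table <- function(params, effect, durations = 2:6,
                                 interval = 0.5) {
  res <- lapply(durations, function(d) {
    des <- trial_design(duration = d, interval = interval)
    cbind(jc = unclass(optimal_weights_jc(params, effect, des)),
          c = unclass(optimal_weights_c(params, effect, des)))
  })
  out <- data.frame(
    weights = rep(c("optimal_jc", "optimal_c"), each = params$J),
    component = rep(params$labels, times = 2),
    stringsAsFactors = FALSE)
  for (i in seq_along(durations)) {
    out[[paste0("y", durations[i])]] <-
      c(res[[i]][, "jc"], res[[i]][, "c"])
  }
  out
}
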