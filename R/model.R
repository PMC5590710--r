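#' Fixed-effect design matrix for one participant
#'
#' Rows are ordered visit-major (all `J` components at the first visit,
#' then all components at the second, ...).  Columns are ordered as the
#' `J` intercepts, the `J` time slopes, then the `J` treatment-by-time
#' interactions.  Control participants have zeros in the interaction
#' block; treated participants carry the visit time there.
#'
#' @param design A [trial_design()].
#' @param J Number of components.
#' @param arm `"control"`/`0` or `"treated"`/`1`.
#' @return A `J * n_visits` by `3 J` matrix.
#' @export
subject_design_matrix <- function(design, J, arm) {
  stopifnot(inherits(design, "trial_design"))
  arm <- resolve_arm(arm)
  IJ <- diag(J)
  do.call(rbind, lapply(design$visit_times, function(t)
    cbind(IJ, t * IJ, arm * t * IJ)))
}

resolve_arm <- function(arm) {
  if (is.character(arm))
    arm <- match(match.arg(arm, c("control", "treated")),
                 c("control", "treated")) - 1L
  if (!arm %in% c(0, 1)) stop("'arm' must be control/treated (0/1)")
  as.numeric(arm)
}

#' Marginal covariance of one participant's stacked observations
#'
#' Under the random-intercept model the `J * T` observation vector
#' (visit-major order) has covariance
#' \eqn{V = I_T \otimes \Sigma_\epsilon + 1_T 1_T' \otimes \Sigma_b}:
#' diagonal `J x J` blocks are \eqn{\Sigma_\epsilon + \Sigma_b} and every
#' off-diagonal block is \eqn{\Sigma_b}.
#'
#' @param params An [mlmm_params()].
#' @param n_visits Number of visits `T >= 1`.
#' @return A `J*T x J*T` symmetric positive definite matrix.
#' @export
marginal_covariance <- function(params, n_visits) {
  stopifnot(inherits(params, "mlmm_params"), n_visits >= 1)
  diag(n_visits) %x% params$sigma_eps +
    matrix(1, n_visits, n_visits) %x% params$sigma_b
}

#' Average per-participant Fisher information for the fixed effects
#'
#' Information about `(beta0, beta2, gamma)` contributed by one
#' participant, averaged over arms with the design's allocation:
#' \eqn{\bar I = a X_t' V^{-1} X_t + (1-a) X_c' V^{-1} X_c}.  The total
#' information of a trial with `N` participants is `N` times this matrix.
#'
#' @inheritParams subject_design_matrix
#' @param params An [mlmm_params()].
#' @return A `3J x 3J` symmetric matrix, positive definite when the
#'   design has two or more visits.
#' @export
participant_information <- function(params, design) {
  stopifnot(inherits(params, "mlmm_params"), inherits(design, "trial_design"))
  V <- marginal_covariance(params, design$n_visits)
  Vi <- tryCatch(chol2inv(chol(V)),
                 error = function(e) stop("marginal covariance V is singular ",
                                          "(is 'sigma_eps' positive definite?)"))
  Xc <- subject_design_matrix(design, params$J, "control")
  Xt <- subject_design_matrix(design, params$J, "treated")
  a <- design$allocation
  Ibar <- a * crossprod(Xt, Vi %*% Xt) + (1 - a) * crossprod(Xc, Vi %*% Xc)
  (Ibar + t(Ibar)) / 2
}

#' Per-participant-scaled covariance of the treatment-effect estimator
#'
#' The generalized-least-squares estimator of the interaction vector
#' `gamma` (treating both covariance matrices as known) has covariance
#' \eqn{\Sigma_\gamma = \Sigma_{\gamma 1} / N} at total sample size `N`.
#' `Sigma_gamma1` is the `gamma` block of the inverse average
#' information.
#'
#' @inheritParams participant_information
#' @return An object of class `"gamma_covariance"`: a list with
#'   `sigma_gamma1` (`J x J`), `J`, and the `design`.
#' @export
gamma_covariance <- function(params, design) {
  if (design$n_visits < 2L)
    stop("the treatment-by-time slope is not identified with fewer than 2 visits")
  Ibar <- participant_information(params, design)
  J <- params$J
  Iinv <- tryCatch(solve(Ibar),
                   error = function(e) stop("average information is singular"))
  sg <- Iinv[2L * J + seq_len(J), 2L * J + seq_len(J), drop = FALSE]
  sg <- (sg + t(sg)) / 2
  dimnames(sg) <- list(params$labels, params$labels)
  structure(list(sigma_gamma1 = sg, J = J, design = design),
            class = "gamma_covariance")
}

#' @export
print.gamma_covariance <- function(x, ...) {
  cat("Treatment-effect estimator covariance: Cov(gamma_hat) = Sigma_gamma1 / N\n")
  print(signif(x$sigma_gamma1, 5))
  invisible(x)
}

#' Random-intercept and error variance of a weighted composite score
#'
#' For composite weights `w` the induced univariate mixed model has
#' random-intercept variance \eqn{\sigma_a^2 = w' \Sigma_b w} and error
#' variance \eqn{\sigma_\delta^2 = w' \Sigma_\epsilon w}.  No
#' normalization is applied.
#'
#' @param w Numeric weight vector of length `J`.
#' @param params An [mlmm_params()].
#' @return Named numeric vector `c(sigma_a2, sigma_d2)`.
#' @export
composite_variance_components <- function(w, params) {
  stopifnot(inherits(params, "mlmm_params"))
  w <- as.numeric(w)
  if (length(w) != params$J)
    stop("'w' has length ", length(w), " but the model has ",
         params$J, " components")
  c(sigma_a2 = drop(t(w) %*% params$sigma_b %*% w),
    sigma_d2 = drop(t(w) %*% params$sigma_eps %*% w))
}

#' Variance of the composite-score treatment-effect estimator
#'
#' Runs the single-outcome version of the information machinery on the
#' univariate mixed model induced by composite weights `w`, giving the
#' per-participant-scaled variance `sigma_gamma1_sq` with
#' \eqn{\mathrm{Var}(\hat\gamma_w) = \sigma^2_{\gamma 1} / N}.  By the
#' information inequality this is never smaller than
#' \eqn{w' \Sigma_{\gamma 1} w}, the variance of the same linear
#' combination estimated under the full multivariate model.
#'
#' @inheritParams composite_variance_components
#' @param design A [trial_design()].
#' @return An object of class `"composite_variance"`: list with
#'   `sigma_a2`, `sigma_d2`, `sigma_gamma1_sq`.
#' @export
composite_gamma_variance <- function(w, params, design) {
  vc <- composite_variance_components(w, params)
  if (vc["sigma_d2"] <= 0)
    stop("composite error variance must be positive (zero-norm 'w'?)")
  s2 <- univariate_sigma_gamma1_sq(vc[["sigma_a2"]], vc[["sigma_d2"]],
                                   design$visit_times, design$allocation)
  structure(list(sigma_a2 = vc[["sigma_a2"]], sigma_d2 = vc[["sigma_d2"]],
                 sigma_gamma1_sq = s2),
            class = "composite_variance")
}

# Per-participant-scaled Var(gamma_hat) for a single outcome, in closed
# form: V^{-1} = (I - c 11')/sd2 with c = sa2/(sd2 + T sa2)
# (Sherman-Morrison), then the interaction entry of the inverse averaged
# information for the design (intercept, time, arm x time).
univariate_sigma_gamma1_sq <- function(sa2, sd2, times, allocation) {
  if (length(times) < 2L)
    stop("the treatment-by-time slope is not identified with fewer than 2 visits")
  Tn <- length(times)
  cc <- sa2 / (sd2 + Tn * sa2)
  st <- sum(times); stt <- sum(times^2)
  i11 <- (Tn - cc * Tn^2) / sd2
  i1t <- (st - cc * Tn * st) / sd2
  itt <- (stt - cc * st^2) / sd2
  a <- allocation
  Ibar <- matrix(c(i11, i1t, a * i1t,
                   i1t, itt, a * itt,
                   a * i1t, a * itt, a * itt), 3, 3)
  solve(Ibar)[3, 3]
}

#' @export
print.composite_variance <- function(x, ...) {
  cat("Composite-score variances: sigma_a2 = ", signif(x$sigma_a2, 5),
      ", sigma_d2 = ", signif(x$sigma_d2, 5),
      ", Var(gamma_hat_w) = ", signif(x$sigma_gamma1_sq, 5), " / N\n", sep = "")
  invisible(x)
}
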