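#' Population parameters of the multivariate linear mixed model
#'
#' Bundles the quantities that define the joint model for `J` longitudinal
#' component scores: per-component intercepts and annual rates of change,
#' the covariance of the correlated subject-level random intercepts, and
#' the covariance of the within-visit errors.  The model for component `j`
#' of subject `n` at time `t` (years) is
#' \deqn{Y_{ntj} = \beta_{j0} + \gamma_j (\mathrm{Trt} \times t) +
#'       \beta_{j2} t + b_{nj} + \epsilon_{ntj},}
#' with \eqn{b_n \sim N_J(0, \Sigma_b)} and
#' \eqn{\epsilon_{nt} \sim N_J(0, \Sigma_\epsilon)} independent.
#'
#' @param beta2 Numeric vector of length `J`: annual rates of change
#'   (score units per year) shared by both arms.
#' @param sigma_b `J x J` symmetric positive semi-definite covariance of
#'   the random intercepts.
#' @param sigma_eps `J x J` symmetric positive definite covariance of the
#'   within-visit errors.
#' @param beta0 Optional numeric vector of intercepts; defaults to zero.
#'   Intercepts never enter the power calculations.
#' @param labels Optional character vector of component names.
#'
#' @return An object of class `"mlmm_params"`.
#' @seealso [adni_mci_params()] for the packaged example parameter set.
#' @export
mlmm_params <- function(beta2, sigma_b, sigma_eps, beta0 = NULL, labels = NULL) {
  beta2 <- as.numeric(beta2)
  J <- length(beta2)
  if (J < 1L || !all(is.finite(beta2)))
    stop("'beta2' must be a finite numeric vector of length >= 1")
  sigma_b <- as_cov_matrix(sigma_b, J, "sigma_b")
  sigma_eps <- as_cov_matrix(sigma_eps, J, "sigma_eps")
  check_psd(sigma_b, "sigma_b", strict = FALSE)
  check_psd(sigma_eps, "sigma_eps", strict = TRUE)
  if (is.null(beta0)) beta0 <- numeric(J)
  beta0 <- as.numeric(beta0)
  if (length(beta0) != J || !all(is.finite(beta0)))
    stop("'beta0' must be a finite numeric vector of length ", J)
  if (is.null(labels)) labels <- paste0("Y", seq_len(J))
  labels <- as.character(labels)
  if (length(labels) != J) stop("'labels' must have length ", J)
  if (anyDuplicated(labels)) stop("'labels' must be distinct")
  dimnames(sigma_b) <- dimnames(sigma_eps) <- list(labels, labels)
  structure(
    list(J = J, labels = labels, beta0 = stats::setNames(beta0, labels),
         beta2 = stats::setNames(beta2, labels),
         sigma_b = sigma_b, sigma_eps = sigma_eps),
    class = "mlmm_params")
}

as_cov_matrix <- function(x, J, name) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != J || ncol(x) != J || !all(is.finite(x)))
    stop("'", name, "' must be a finite ", J, "x", J, " numeric matrix")
  if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x))))
    stop("'", name, "' must be symmetric")
  (x + t(x)) / 2
}

check_psd <- function(x, name, strict) {
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev))
  if (strict && min(ev) <= 1e-12 * scale)
    stop("'", name, "' must be positive definite")
  if (!strict && min(ev) < -1e-10 * max(1, scale))
    stop("'", name, "' must be positive semi-definite")
  invisible(TRUE)
}

#' @export
print.mlmm_params <- function(x, ...) {
  cat("Multivariate linear mixed-model parameters (", x$J,
      " component", if (x$J > 1) "s", ")\n", sep = "")
  cat("Annual rates of change (beta2):\n")
  print(round(x$beta2, 4))
  cat("Random-intercept covariance (sigma_b):\n")
  print(round(x$sigma_b, 4))
  cat("Error covariance (sigma_eps):\n")
  print(round(x$sigma_eps, 4))
  invisible(x)
}

#' Packaged parameter set for an early-AD MCI population
#'
#' Annual rates of change and covariance matrices for transformed MMSE,
#' CDR-SB and ADAS-11 scores in a mild-cognitive-impairment population,
#' as used throughout the package examples and shipped as
#' `extdata/adni_mci.yaml`.  Scores are on a transformed scale on which
#' higher values indicate worse cognition and the baseline standard
#' deviation is close to one.
#'
#' @return An `"mlmm_params"` object with `J = 3` components.
#' @export
adni_mci_params <- function() {
  load_power_config(system.file("extdata", "adni_mci.yaml",
                                package = "mlmmpower", mustWork = TRUE))$params
}

#' Treatment-effect specification
#'
#' The alternative hypothesis is a vector `gamma_star` of
#' treatment-by-time interaction effects (score units per year).  The
#' usual specification is a fractional slowing of decline: each component
#' rate is reduced by `reduction` (default 25%), so
#' `gamma_star = -reduction * beta2`.  An explicit effect vector can be
#' given instead via `gamma`.
#'
#' @param reduction Fraction in (0, 1] of each annual rate removed by
#'   treatment.  Ignored when `gamma` is supplied.
#' @param gamma Optional explicit numeric vector of treatment effects.
#'
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(reduction = 0.25, gamma = NULL) {
  if (!is.null(gamma)) {
    gamma <- as.numeric(gamma)
    if (!all(is.finite(gamma))) stop("'gamma' must be finite")
    return(structure(list(mode = "explicit", gamma = gamma), class = "effect_spec"))
  }
  if (!is.numeric(reduction) || length(reduction) != 1 ||
      reduction <= 0 || reduction > 1)
    stop("'reduction' must be a scalar in (0, 1]")
  structure(list(mode = "fraction_of_rate", reduction = reduction),
            class = "effect_spec")
}

#' Resolve the treatment-effect vector under the alternative
#'
#' @param effect An [effect_spec()].
#' @param params An [mlmm_params()] (needed in fractional mode).
#' @return Numeric vector `gamma_star` of length `params$J`.
#' @export
gamma_star <- function(effect, params) {
  stopifnot(inherits(effect, "effect_spec"))
  if (effect$mode == "explicit") {
    g <- effect$gamma
    if (!missing(params) && length(g) != params$J)
      stop("explicit 'gamma' has length ", length(g),
           " but the model has ", params$J, " components")
    return(g)
  }
  stopifnot(inherits(params, "mlmm_params"))
  -effect$reduction * unname(params$beta2)
}

#' @export
print.effect_spec <- function(x, ...) {
  if (x$mode == "fraction_of_rate")
    cat("Treatment effect: ", 100 * x$reduction,
        "% reduction of each annual rate of change\n", sep = "")
  else
    cat("Treatment effect (explicit): ",
        paste(signif(x$gamma, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
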