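#' Fit the multivariate linear mixed model by maximum likelihood (EM)
#'
#' Estimates the fixed effects and both covariance matrices of the
#' multivariate random-intercept model from long-format longitudinal
#' data.  Subjects may have different visit sets (rows simply omitted);
#' at each observed visit the full component vector must be present.
#'
#' The algorithm alternates a generalized-least-squares update of the
#' fixed effects (which maximizes the observed-data likelihood exactly
#' for the current covariances) with an EM update of `sigma_b` and
#' `sigma_eps` based on the posterior mean and covariance of each
#' subject's random-intercept vector.  The observed-data log-likelihood
#' is non-decreasing across iterations and convergence is declared on
#' its relative change.
#'
#' @param data Long-format data frame with columns `subject`, `time`,
#'   one column per component, and `arm` when
#'   `model = "time_plus_interaction"`.
#' @param components Character vector naming the component columns; by
#'   default every column other than `subject`, `arm`, `time`.
#' @param model `"time_only"` (intercept and time slope per component)
#'   or `"time_plus_interaction"` (adds the treatment-by-time effect).
#' @param init Optional list with starting values `beta` (stacked fixed
#'   effects), `sigma_b`, `sigma_eps`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative log-likelihood
#'   change.
#' @return An object of class `"mlmm_fit"` with components `beta0`,
#'   `beta2`, `gamma` (when applicable), `sigma_b`, `sigma_eps`,
#'   `loglik` (final value), `loglik_trace`, `iterations`, `converged`,
#'   `fixef_cov` (GLS covariance of the stacked fixed effects at the
#'   estimates), `labels`, `model`, and the data dimensions.  Methods:
#'   `print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`,
#'   `simulate`.
#' @export
mlmm_fit <- function(data, components = NULL,
                     model = c("time_only", "time_plus_interaction"),
                     init = NULL, max_iter = 2000, tol = 1e-8) {
  model <- match.arg(model)
  if (is.null(components))
    components <- setdiff(names(data), c("subject", "arm", "time"))
  J <- length(components)
  if (J < 1) stop("no component columns found")
  if (!all(c("subject", "time") %in% names(data)))
    stop("data needs 'subject' and 'time' columns")
  with_arm <- model == "time_plus_interaction"
  if (with_arm && !"arm" %in% names(data))
    stop("model 'time_plus_interaction' needs an 'arm' column")
  vals <- as.matrix(data[, components, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || !all(is.finite(vals)))
    stop("component values must be finite and complete within observed rows")

  data <- data[order(data$subject, data$time), , drop = FALSE]
  vals <- as.matrix(data[, components, drop = FALSE])
  subj <- data$subject
  usubj <- unique(subj)
  n <- length(usubj)
  idx <- split(seq_len(nrow(data)), factor(subj, levels = usubj))
  p <- if (with_arm) 3L * J else 2L * J

  # per-subject stacked response and design, visit-major
  ylist <- vector("list", n); Xlist <- vector("list", n)
  pat <- character(n)
  IJ <- diag(J)
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    tms <- data$time[rows]
    if (anyDuplicated(tms)) stop("duplicate visit times within a subject")
    a <- if (with_arm) data$arm[rows][1] else 0
    ylist[[i]] <- as.vector(t(vals[rows, , drop = FALSE]))
    Xi <- do.call(rbind, lapply(tms, function(t)
      if (with_arm) cbind(IJ, t * IJ, a * t * IJ) else cbind(IJ, t * IJ)))
    Xlist[[i]] <- Xi
    pat[i] <- paste0(a, "|", paste(tms, collapse = ","))
  }
  Tn <- lengths(idx)

  # starting values: per-component OLS, residual covariance split in half
  if (is.null(init)) {
    beta <- numeric(p)
    R0 <- matrix(0, nrow(vals), J)
    for (j in seq_len(J)) {
      xj <- if (with_arm) cbind(1, data$time, data$arm * data$time)
            else cbind(1, data$time)
      f <- stats::lm.fit(xj, vals[, j])
      beta[(seq_len(p / J) - 1L) * J + j] <- f$coefficients
      R0[, j] <- f$residuals
    }
    S0 <- crossprod(R0) / nrow(R0)
    sigma_eps <- S0 / 2
    sigma_b <- S0 / 2
  } else {
    beta <- init$beta; sigma_b <- as.matrix(init$sigma_b)
    sigma_eps <- as.matrix(init$sigma_eps)
  }

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  ridge <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      warning("covariance update not positive definite; ridge applied")
      S <- S + diag(nrow(S)) * (1e-10 + abs(min(ev)))
    }
    S
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    # cache per visit-pattern quantities for the current covariances
    cache <- new.env(parent = emptyenv())
    getpat <- function(i) {
      key <- pat[i]
      got <- get0(key, cache)
      if (!is.null(got)) return(got)
      Ti <- Tn[i]
      V <- diag(Ti) %x% sigma_eps + matrix(1, Ti, Ti) %x% sigma_b
      cV <- chol(V)
      Vi <- chol2inv(cV)
      Zt <- matrix(rep(diag(J), Ti), J, J * Ti)   # t(1_T %x% I_J)
      M <- sigma_b %*% (Zt %*% Vi)                # J x JT, gives posterior mean
      Vb <- sigma_b - M %*% t(Zt) %*% sigma_b     # posterior covariance
      XtVi <- crossprod(Xlist[[i]], Vi)
      val <- list(Vi = Vi, logdet = 2 * sum(log(diag(cV))), M = M,
                  Vb = (Vb + t(Vb)) / 2, XtVi = XtVi,
                  XtViX = XtVi %*% Xlist[[i]])
      assign(key, val, cache)
      val
    }
    # GLS step for the fixed effects
    A <- matrix(0, p, p); rhs <- numeric(p)
    for (i in seq_len(n)) {
      pc <- getpat(i)
      A <- A + pc$XtViX
      rhs <- rhs + drop(pc$XtVi %*% ylist[[i]])
    }
    beta <- drop(solve(A, rhs))
    # E step + covariance M step
    Sb_new <- matrix(0, J, J); Se_new <- matrix(0, J, J)
    ll <- 0
    for (i in seq_len(n)) {
      pc <- getpat(i)
      r <- ylist[[i]] - drop(Xlist[[i]] %*% beta)
      ll <- ll - 0.5 * (length(r) * log(2 * pi) + pc$logdet +
                          drop(t(r) %*% pc$Vi %*% r))
      bhat <- drop(pc$M %*% r)
      Sb_new <- Sb_new + outer(bhat, bhat) + pc$Vb
      E <- matrix(r, nrow = J) - bhat              # J x T residuals minus b
      Se_new <- Se_new + tcrossprod(E) + Tn[i] * pc$Vb
    }
    sigma_b <- ridge(Sb_new / n)
    sigma_eps <- ridge(Se_new / sum(Tn))
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  labels <- components
  sigma_b <- (sigma_b + t(sigma_b)) / 2
  sigma_eps <- (sigma_eps + t(sigma_eps)) / 2
  dimnames(sigma_b) <- dimnames(sigma_eps) <- list(labels, labels)
  # GLS covariance of the fixed effects at the final covariances
  A <- matrix(0, p, p)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- pat[i]
    got <- get0(key, cache)
    if (is.null(got)) {
      Ti <- Tn[i]
      V <- diag(Ti) %x% sigma_eps + matrix(1, Ti, Ti) %x% sigma_b
      got <- chol2inv(chol(V))
      assign(key, got, cache)
    }
    A <- A + crossprod(Xlist[[i]], got %*% Xlist[[i]])
  }
  fixef_cov <- solve(A)

  out <- list(
    beta0 = stats::setNames(beta[seq_len(J)], labels),
    beta2 = stats::setNames(beta[J + seq_len(J)], labels),
    gamma = if (with_arm) stats::setNames(beta[2L * J + seq_len(J)], labels),
    sigma_b = sigma_b, sigma_eps = sigma_eps,
    loglik = loglik_trace[length(loglik_trace)],
    loglik_trace = loglik_trace, iterations = iter, converged = converged,
    fixef_cov = fixef_cov, labels = labels, model = model,
    n_subjects = n, n_obs = nrow(data),
    call = match.call())
  class(out) <- "mlmm_fit"
  out
}

#' Observed-data log-likelihood of the multivariate mixed model
#'
#' Sum over subjects of the multivariate-normal log-density of the
#' stacked observed component vector, with mean from the fixed effects
#' and covariance `V` restricted to the observed visits.
#'
#' @inheritParams mlmm_fit
#' @param params An [mlmm_params()] supplying `sigma_b`/`sigma_eps` and
#'   (together with `gamma`) the fixed effects: mean at time `t` is
#'   `beta0 + beta2 t (+ gamma * arm * t)`.
#' @param gamma Optional treatment-interaction vector (requires an `arm`
#'   column).
#' @return Scalar log-likelihood.
#' @export
mlmm_loglik <- function(data, params, gamma = NULL, components = NULL) {
  stopifnot(inherits(params, "mlmm_params"))
  if (is.null(components)) components <- params$labels
  J <- params$J
  data <- data[order(data$subject, data$time), , drop = FALSE]
  vals <- as.matrix(data[, components, drop = FALSE])
  idx <- split(seq_len(nrow(data)), factor(data$subject,
                                           levels = unique(data$subject)))
  ll <- 0
  for (rows in idx) {
    tms <- data$time[rows]
    Ti <- length(tms)
    V <- diag(Ti) %x% params$sigma_eps + matrix(1, Ti, Ti) %x% params$sigma_b
    cV <- tryCatch(chol(V), error = function(e)
      stop("marginal covariance not positive definite"))
    a <- if (!is.null(gamma)) data$arm[rows][1] else 0
    g <- if (!is.null(gamma)) gamma else numeric(J)
    mu <- as.vector(vapply(tms, function(t)
      params$beta0 + params$beta2 * t + g * a * t, numeric(J)))
    r <- as.vector(t(vals[rows, , drop = FALSE])) - mu
    z <- backsolve(cV, r, transpose = TRUE)
    ll <- ll - 0.5 * (Ti * J * log(2 * pi) + 2 * sum(log(diag(cV))) +
                        sum(z^2))
  }
  ll
}

#' Convert fitted parameters for use in power analysis
#'
#' @param fit An `"mlmm_fit"`.
#' @return An [mlmm_params()] carrying the fitted rates and covariances.
#' @export
as_mlmm_params <- function(fit) {
  stopifnot(inherits(fit, "mlmm_fit"))
  mlmm_params(beta2 = unname(fit$beta2), sigma_b = fit$sigma_b,
              sigma_eps = fit$sigma_eps, beta0 = unname(fit$beta0),
              labels = fit$labels)
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat("Multivariate linear mixed model fit (EM, model '", x$model, "')\n",
      sep = "")
  cat("  ", x$n_subjects, " subjects, ", x$n_obs, " subject-visits, ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  log-likelihood: ", formatC(x$loglik, format = "f", digits = 3),
      "\n", sep = "")
  cat("Annual rates of change (beta2):\n")
  print(round(x$beta2, 4))
  if (!is.null(x$gamma)) {
    cat("Treatment-by-time effects (gamma):\n")
    print(round(x$gamma, 4))
  }
  invisible(x)
}

#' @export
coef.mlmm_fit <- function(object, ...) {
  c(stats::setNames(object$beta0, paste0("beta0.", object$labels)),
    stats::setNames(object$beta2, paste0("beta2.", object$labels)),
    if (!is.null(object$gamma))
      stats::setNames(object$gamma, paste0("gamma.", object$labels)))
}

#' @export
logLik.mlmm_fit <- function(object, ...) {
  J <- length(object$labels)
  p <- length(coef(object)) + J * (J + 1)  # fixed effects + two covariances
  structure(object$loglik, df = p, nobs = object$n_obs, class = "logLik")
}

#' @export
summary.mlmm_fit <- function(object, ...) {
  se <- sqrt(diag(object$fixef_cov))
  est <- coef(object)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `z value` = est / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(est / se)))
  out <- list(coefficients = tab, sigma_b = object$sigma_b,
              sigma_eps = object$sigma_eps, loglik = object$loglik,
              iterations = object$iterations, converged = object$converged,
              model = object$model)
  class(out) <- "summary.mlmm_fit"
  out
}

#' @export
print.summary.mlmm_fit <- function(x, ...) {
  cat("EM fit of the multivariate random-intercept model ('",
      x$model, "')\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("Random-intercept covariance (sigma_b):\n")
  print(round(x$sigma_b, 4))
  cat("Error covariance (sigma_eps):\n")
  print(round(x$sigma_eps, 4))
  cat("log-likelihood ", formatC(x$loglik, format = "f", digits = 3),
      " after ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
fitted.mlmm_fit <- function(object, data, ...) {
  if (missing(data))
    stop("supply the 'data' the model was fitted to")
  J <- length(object$labels)
  a <- if (!is.null(object$gamma)) data$arm else 0
  g <- if (!is.null(object$gamma)) object$gamma else numeric(J)
  out <- matrix(0, nrow(data), J, dimnames = list(NULL, object$labels))
  for (j in seq_len(J))
    out[, j] <- object$beta0[j] + object$beta2[j] * data$time +
      g[j] * a * data$time
  out
}

#' @export
residuals.mlmm_fit <- function(object, data, ...) {
  as.matrix(data[, object$labels, drop = FALSE]) - fitted(object, data)
}

#' @export
simulate.mlmm_fit <- function(object, nsim = 1, seed = NULL, design, n,
                              effect = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  params <- as_mlmm_params(object)
  if (nsim == 1) return(simulate_trial(params, design, n, effect))
  lapply(seq_len(nsim), function(i) simulate_trial(params, design, n, effect))
}
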