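#' Trial design for a two-arm longitudinal study
#'
#' Describes the measurement schedule and testing conventions of a
#' two-arm randomized trial.  With a duration of `d` years and visits
#' every `interval` years, participants are measured at
#' `0, interval, ..., d - interval`: a `d`-year trial with biannual
#' visits observes each participant `2 d` times (e.g. a 2-year trial has
#' four visits at 0, 0.5, 1 and 1.5 years).  An arbitrary strictly
#' increasing grid starting at 0 can be supplied via `visit_times`.
#'
#' @param duration Trial duration in years; must be a positive multiple
#'   of `interval`.  Ignored when `visit_times` is given.
#' @param interval Spacing between visits in years (default biannual,
#'   0.5).
#' @param allocation Fraction of participants in the treated arm, in
#'   (0, 1).
#' @param alpha Significance level of the Wald tests.
#' @param target_power Power the trial is sized for.
#' @param sidedness `"two_sided_chi2"` for the chi-square Wald tests
#'   (default) or `"one_sided_z"` for the signed-root Z versions of the
#'   single-degree-of-freedom tests.
#' @param visit_times Optional explicit visit-time grid (years), strictly
#'   increasing and starting at 0, with at least two visits.
#'
#' @return An object of class `"trial_design"`.
#' @export
trial_design <- function(duration, interval = 0.5, allocation = 0.5,
                         alpha = 0.05, target_power = 0.80,
                         sidedness = c("two_sided_chi2", "one_sided_z"),
                         visit_times = NULL) {
  sidedness <- match.arg(sidedness)
  if (is.null(visit_times)) {
    if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
      stop("'duration' must be a positive scalar (years)")
    if (!is.numeric(interval) || length(interval) != 1 || interval <= 0)
      stop("'interval' must be a positive scalar (years)")
    k <- duration / interval
    if (abs(k - round(k)) > 1e-8)
      stop("'duration' must be an integer multiple of 'interval'")
    visit_times <- seq(0, by = interval, length.out = round(k))
  } else {
    visit_times <- as.numeric(visit_times)
    if (visit_times[1] != 0) stop("'visit_times' must start at 0")
    if (any(diff(visit_times) <= 0))
      stop("'visit_times' must be strictly increasing")
    if (length(visit_times) < 2L)
      stop("at least two visits are needed to identify a slope")
    duration <- max(visit_times) + min(diff(visit_times))
    interval <- NA_real_
  }
  if (length(visit_times) < 2L)
    stop("at least two visits are needed to identify a slope")
  if (!is.numeric(allocation) || length(allocation) != 1 ||
      allocation <= 0 || allocation >= 1)
    stop("'allocation' must be in (0, 1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (!is.numeric(target_power) || target_power <= 0 || target_power >= 1)
    stop("'target_power' must be in (0, 1)")
  if (target_power <= alpha)
    stop("'target_power' must exceed 'alpha'")
  structure(
    list(duration = duration, interval = interval,
         visit_times = visit_times, n_visits = length(visit_times),
         allocation = allocation, alpha = alpha,
         target_power = target_power, sidedness = sidedness),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-arm trial design\n")
  cat("  visits (years): ", paste(x$visit_times, collapse = ", "), "\n", sep = "")
  cat("  treated allocation: ", x$allocation,
      ", alpha: ", x$alpha, ", target power: ", x$target_power,
      ", test: ", x$sidedness, "\n", sep = "")
  invisible(x)
}
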