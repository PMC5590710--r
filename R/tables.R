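#' Sample-size table across test statistics, weights and durations
#'
#' Reproduces the package's headline design table: required total sample
#' sizes at the design's alpha and target power for the joint J-df test,
#' the two 1-df tests under six weighting strategies (each unit vector,
#' equal weights, and both optimal vectors), and the Bonferroni
#' comparator that powers each component separately at `alpha / J`.
#'
#' @param params An [mlmm_params()].
#' @param effect An [effect_spec()].
#' @param durations Trial durations in years.
#' @param interval Visit spacing in years.
#' @param alpha,target_power,allocation Design settings applied at every
#'   duration.
#' @return Data frame with columns `statistic`, `weights` and one column
#'   of sample sizes per duration.
#' @export
sample_size_table <- function(params, effect, durations = 2:6,
                              interval = 0.5, alpha = 0.05,
                              target_power = 0.80, allocation = 0.5) {
  J <- params$J
  strategies <- c(paste0("unit_", seq_len(J)), "equal",
                  "optimal_jc", "optimal_c")
  rows <- rbind(
    data.frame(statistic = "J", weights = "-"),
    expand.grid(weights = strategies, statistic = c("JC", "C"),
                stringsAsFactors = FALSE)[, c("statistic", "weights")],
    data.frame(statistic = "bonferroni", weights = paste0("unit, alpha/", J)))
  out <- rows
  for (d in durations) {
    des <- trial_design(duration = d, interval = interval,
                        allocation = allocation, alpha = alpha,
                        target_power = target_power)
    # resolve each weight strategy once per duration
    wlist <- c(lapply(seq_len(J), function(j) unit_weights(J, j)),
               list(equal_weights(J),
                    optimal_weights_jc(params, effect, des),
                    optimal_weights_c(params, effect, des)))
    names(wlist) <- strategies
    ns <- integer(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      ns[r] <- switch(rows$statistic[r],
        J = power_analysis(params, effect, des, "J")$n_required,
        bonferroni = bonferroni_sample_size(params, effect, des)$n_required,
        power_analysis(params, effect, des, rows$statistic[r],
                       wlist[[rows$weights[r]]])$n_required)
    }
    out[[paste0("y", d)]] <- ns
  }
  out
}
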