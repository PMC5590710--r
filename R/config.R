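#' Read a power-analysis configuration file
#'
#' Loads population parameters, the treatment-effect rule and the trial
#' design from a YAML (or JSON-compatible YAML) file and validates them.
#' Missing design fields take the package defaults (biannual visits,
#' equal allocation, alpha 0.05, target power 0.80, 25% rate reduction).
#' The packaged example configuration is
#' `system.file("extdata", "adni_mci.yaml", package = "mlmmpower")`.
#'
#' @param path Path to the configuration file.
#' @return List with elements `params` ([mlmm_params()]),
#'   `effect` ([effect_spec()]) and `design` ([trial_design()]).
#' @export
load_power_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("beta2", "sigma_b", "sigma_eps"))
    if (is.null(cfg[[key]]))
      stop("config '", path, "': missing required key '", key, "'")
  to_matrix <- function(x, key) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    if (is.null(dim(x))) {
      k <- sqrt(length(x))
      if (k != round(k))
        stop("config '", path, "': '", key, "' is not square")
      x <- matrix(as.numeric(x), k, k, byrow = TRUE)
    }
    x
  }
  params <- tryCatch(
    mlmm_params(beta2 = as.numeric(cfg$beta2),
                sigma_b = to_matrix(cfg$sigma_b, "sigma_b"),
                sigma_eps = to_matrix(cfg$sigma_eps, "sigma_eps"),
                beta0 = cfg$beta0, labels = cfg$labels),
    error = function(e) stop("config '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  eff <- cfg$effect
  effect <- if (!is.null(eff$gamma)) effect_spec(gamma = as.numeric(eff$gamma))
            else effect_spec(reduction = eff$reduction %||% 0.25)
  des <- cfg$design %||% list()
  design <- tryCatch(
    trial_design(duration = des$duration %||% 2,
                 interval = des$interval %||% 0.5,
                 allocation = des$allocation %||% 0.5,
                 alpha = des$alpha %||% 0.05,
                 target_power = des$target_power %||% 0.80,
                 sidedness = des$sidedness %||% "two_sided_chi2"),
    error = function(e) stop("config '", path, "': design: ",
                             conditionMessage(e), call. = FALSE))
  list(params = params, effect = effect, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a power-analysis configuration file
#'
#' Serializes a parameter/effect/design triple back to YAML in the
#' format read by [load_power_config()]; loading the written file
#' reproduces the objects.
#'
#' @param params An [mlmm_params()].
#' @param effect An [effect_spec()].
#' @param design A [trial_design()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_power_config <- function(params, effect, design, path) {
  cfg <- list(
    labels = as.list(params$labels),
    beta0 = as.list(unname(params$beta0)),
    beta2 = as.list(unname(params$beta2)),
    sigma_b = lapply(seq_len(params$J),
                     function(i) as.list(unname(params$sigma_b[i, ]))),
    sigma_eps = lapply(seq_len(params$J),
                       function(i) as.list(unname(params$sigma_eps[i, ]))),
    effect = if (effect$mode == "explicit") list(gamma = as.list(effect$gamma))
             else list(reduction = effect$reduction),
    design = list(duration = design$duration, interval = design$interval,
                  allocation = design$allocation, alpha = design$alpha,
                  target_power = design$target_power,
                  sidedness = design$sidedness))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
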