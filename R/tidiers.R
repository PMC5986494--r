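#' Tidy an uptake estimate
#'
#' @param x A `fopl_uptake` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_labelled`, `n_total`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @method tidy fopl_uptake
#' @export
tidy.fopl_uptake <- function(x, ...) {
  tibble::tibble(
    n_labelled = x$n_labelled, n_total = x$n_total,
    proportion = x$proportion, ci_low = x$ci_low, ci_high = x$ci_high
  )
}

#' Tidy a paired t-test result
#'
#' @param x A `fopl_paired_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, interval, statistic, df and
#'   p value, in broom's column naming.
#' @method tidy fopl_paired_test
#' @export
tidy.fopl_paired_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff, conf.low = x$ci_low, conf.high = x$ci_high,
    statistic = x$t_stat, parameter = x$df, p.value = x$p_value
  )
}

#' Tidy a scenario run
#'
#' @param x A `fopl_run` bundle from [run_scenario()].
#' @param ... Unused.
#' @return The per-category effect table of the run.
#' @method tidy fopl_run
#' @export
tidy.fopl_run <- function(x, ...) {
  tibble::as_tibble(x$effects)
}

#' One-row summary of a scenario run
#'
#' @param x A `fopl_run` bundle from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble: scenario, attributable fraction, point-estimate
#'   HALYs, costs, offsets, net cost and ICER; when a PSA was run, its mean
#'   and 95% UI columns are appended.
#' @method glance fopl_run
#' @export
glance.fopl_run <- function(x, ...) {
  out <- tibble::tibble(
    scenario = x$scenario,
    attributable_fraction = x$attributable_fraction,
    halys = x$ce$halys,
    intervention_cost = x$ce$intervention_cost,
    cost_offsets = x$ce$cost_offsets,
    net_cost = x$ce$net_cost,
    icer = x$ce$icer,
    dominance = x$ce$dominance,
    cost_effective = x$ce$cost_effective
  )
  if (!is.null(x$psa)) {
    out <- dplyr::bind_cols(
      out, glance(x$psa)[, c("halys_mean", "halys_ui_low", "halys_ui_high",
                             "net_cost_mean", "net_cost_ui_low",
                             "net_cost_ui_high", "icer_mean", "icer_ui_low",
                             "icer_ui_low_dominant", "icer_ui_high",
                             "share_ne", "share_nw", "share_se", "share_sw")]
    )
  }
  out
}
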