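#' Discounted lifetime intervention cost
#'
#' Expands each cost item along its schedule — `one_off` at year 0, `annual`
#' every year of the horizon, `per_cycle` every `labelling_cycle` years
#' starting at year 0 — discounts each occurrence to year 0 at `discount_rate`
#' and sums. Government administration is typically annual over the lifetime
#' of the scheme, industry relabelling recurs once per labelling cycle, and
#' legislation is a one-off.
#'
#' @param costs Cost table (columns `item`, `point_m`, `schedule`; see
#'   [simulate_costs()]), already filtered to one scenario.
#' @param horizon Years of the scheme (cost years 0 to `horizon - 1`).
#' @param discount_rate Annual discount rate.
#' @param labelling_cycle Length of a labelling cycle in years (>= 1).
#' @return Total discounted cost in the units of `point_m` (A$ millions).
#' @examples
#' costs <- dplyr::filter(simulate_costs(), scenario == "voluntary")
#' aggregate_intervention_costs(costs, horizon = 100, discount_rate = 0.03)
#' @export
aggregate_intervention_costs <- function(costs, horizon, discount_rate,
                                         labelling_cycle = 3) {
  check_number(horizon, "horizon", lower = 1)
  check_number(labelling_cycle, "labelling_cycle", lower = 1)
  bad <- setdiff(unique(costs$schedule), c("one_off", "annual", "per_cycle"))
  if (length(bad)) {
    stop_invalid(paste("unknown cost schedule:", paste(bad, collapse = ", ")))
  }
  total <- 0
  for (i in seq_len(nrow(costs))) {
    years <- switch(costs$schedule[i],
      one_off = 0,
      annual = seq_len(horizon) - 1,
      per_cycle = seq(0, horizon - 1, by = labelling_cycle)
    )
    total <- total + sum(costs$point_m[i] * discount_factor(years, discount_rate))
  }
  total
}

#' Discounted cost offsets from averted prevalent case-years
#'
#' Sums, over cohorts, cycles and diseases, the annual treatment cost per
#' prevalent case times the difference in prevalent cases between the
#' intervention and comparator arms, discounted to cycle 0. Negative values
#' are savings (cases averted).
#'
#' @param comparator A `fopl_lifetable` run, or a `fopl_lifetable_pair`.
#' @param intervention A `fopl_lifetable` run.
#' @return Offsets in A$ (same monetary units as `cost_per_case_year`).
#' @export
compute_cost_offsets <- function(comparator, intervention = NULL) {
  if (inherits(comparator, "fopl_lifetable_pair")) {
    intervention <- comparator$intervention
    comparator <- comparator$comparator
  }
  check_paired(comparator, intervention)
  D <- length(comparator$disease_names)
  if (D == 0) return(0)
  r <- comparator$config$discount_rate
  T_max <- ncol(comparator$survivors)
  total <- 0
  for (t in seq_len(T_max)) {
    dcases <- (slice3(intervention$prev, t) * intervention$survivors[, t]) -
      (slice3(comparator$prev, t) * comparator$survivors[, t])
    total <- total + sum(dcases %*% comparator$cost) *
      discount_factor(t - 1, r)
  }
  total
}

#' Net cost, ICER and dominance classification
#'
#' Combines the intervention cost, cost offsets and incremental HALYs into a
#' cost-effectiveness outcome: `net_cost = intervention_cost + cost_offsets`;
#' an intervention that gains health and saves money is `dominant`, one that
#' loses health and costs money is `dominated`, otherwise the ICER is
#' `net_cost / halys` and is compared with the willingness-to-pay threshold.
#' Zero incremental HALYs leave the ICER undefined (`NA`, reported, not an
#' error).
#'
#' @param intervention_cost Discounted intervention cost (A$).
#' @param cost_offsets Discounted offsets (A$, negative = savings).
#' @param halys Incremental HALYs.
#' @param wtp Willingness-to-pay threshold (A$/HALY, default 50,000).
#' @return A tibble of class `fopl_ce` with columns `intervention_cost`,
#'   `cost_offsets`, `net_cost`, `halys`, `icer`, `dominance`
#'   (`"dominant"`/`"dominated"`/`NA`), `cost_effective`.
#' @examples
#' net_and_icer(46.1e6, -41.6e6, 4207)
#' @export
net_and_icer <- function(intervention_cost, cost_offsets, halys, wtp = 50000) {
  if (any(!is.finite(c(intervention_cost, cost_offsets, halys)))) {
    stop_invalid("cost and HALY inputs must be finite")
  }
  net <- intervention_cost + cost_offsets
  dominance <- NA_character_
  icer <- NA_real_
  if (halys > 0 && net < 0) {
    dominance <- "dominant"
    icer <- net / halys
  } else if (halys < 0 && net > 0) {
    dominance <- "dominated"
    icer <- net / halys
  } else if (halys != 0) {
    icer <- net / halys
  } else {
    inform("incremental HALYs are zero; ICER undefined")
  }
  ce <- identical(dominance, "dominant") ||
    (halys > 0 && !is.na(icer) && icer < wtp)
  out <- tibble::tibble(
    intervention_cost = intervention_cost,
    cost_offsets = cost_offsets,
    net_cost = net,
    halys = halys,
    icer = icer,
    dominance = dominance,
    cost_effective = ce
  )
  class(out) <- c("fopl_ce", class(out))
  out
}
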