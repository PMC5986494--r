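# Deterministic point-estimate pipeline shared by run_scenario() and
# run_psa(). Returns every intermediate the uncertainty layer reuses.
point_pipeline <- function(inputs, scenario, attributable_fraction,
                           config, wtp, labelling_cycle,
                           ew_params = energy_weight_params()) {
  effects <- compute_category_effects(inputs$products)
  eff <- scenario_effect(effects, scenario = scenario,
                         attributable_fraction = attributable_fraction)
  anthro <- cohort_anthro_changes(eff, inputs$consumption, inputs$population,
                                  ew_params)
  ctx <- pmslt_context(inputs$population, inputs$diseases, config)
  key <- paste(ctx$cohorts$age_lo, ctx$cohorts$sex)
  delta <- anthro$delta_bmi[match(key, paste(anthro$age_lo, anthro$sex))]
  reduction <- -delta
  comparator <- run_arm(ctx)
  intervention <- run_arm(ctx, pif_matrix(ctx, reduction), ref = comparator)
  costs_scen <- inputs$costs[inputs$costs$scenario == scenario, ]
  cost <- 1e6 * aggregate_intervention_costs(
    costs_scen, horizon = config$horizon_age,
    discount_rate = config$discount_rate, labelling_cycle = labelling_cycle
  )
  offsets <- compute_cost_offsets(comparator, intervention)
  halys <- incremental_halys(comparator, intervention)
  ce <- suppressMessages(net_and_icer(cost, offsets, halys, wtp))
  list(effects = effects, scenario_effect = eff, anthro = anthro, ctx = ctx,
       comparator = comparator, intervention = intervention,
       reduction = reduction, costs_scen = costs_scen, cost = cost,
       offsets = offsets, halys = halys, ce = ce)
}

# deterministic, well-separated substream seed for iteration k (kept < 2^31)
iter_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1000003) %% 2147483629)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo uncertainty analysis of the full pipeline. Each iteration
#' independently draws: the overall weight-change effect (normal, with SD
#' equal to `effect_cv` times its mean — the default `effect_cv = 1` encodes
#' the SD-equals-mean convention used when no effect-size variance data
#' exist), which rescales every cohort's BMI shift; each disease's relative
#' risk (lognormal around its point estimate with its log-scale SE); each
#' cohort's BMI log-mean (normal with its `bmi_mu_se`); and every cost item
#' (Pert over its range, gamma for the legislation item). The comparator arm
#' involves none of these quantities, so it is computed once and shared by
#' all iterations; only the intervention arm and cost aggregation are rerun.
#'
#' Iterations that raise a model-consistency error are recorded as `NA` rows
#' and counted in `n_failed`, never silently dropped. A fixed `seed` makes
#' the whole result reproducible, and iteration `k` uses its own
#' deterministically derived substream.
#'
#' @param inputs A `fopl_inputs` list (see [simulate_inputs()]) or any list
#'   with `products`, `consumption`, `population`, `diseases`, `costs`.
#' @param scenario `"voluntary"` or `"mandatory"`.
#' @param attributable_fraction Share of the observed reformulation
#'   differential credited to the scheme.
#' @param n_iter Number of Monte Carlo iterations (2000 for full runs).
#' @param seed Master seed.
#' @param config A [pmslt_config()].
#' @param wtp Willingness-to-pay threshold (A$/HALY).
#' @param labelling_cycle Industry labelling-cycle length in years.
#' @param effect_cv Coefficient of variation of the weight-change effect
#'   draw; 0 makes the draw degenerate at the point estimate.
#' @return A list of class `fopl_psa`: `iterations` (tibble with one row per
#'   iteration: draws' `halys`, `intervention_cost`, `cost_offsets`,
#'   `net_cost`, `icer`, `quadrant`), `point` (the deterministic `fopl_ce`),
#'   `n_failed`, and the call's settings.
#' @examples
#' psa <- run_psa(fixture_inputs(800), n_iter = 5, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(inputs, scenario = c("voluntary", "mandatory"),
                    attributable_fraction = 1, n_iter = 2000, seed = 1,
                    config = pmslt_config(), wtp = 50000,
                    labelling_cycle = 3, effect_cv = 1) {
  scenario <- match.arg(scenario)
  n_iter <- check_count(n_iter, "n_iter")
  check_number(effect_cv, "effect_cv", lower = 0)
  pt <- point_pipeline(inputs, scenario, attributable_fraction, config, wtp,
                       labelling_cycle)
  ctx <- pt$ctx
  rows <- vector("list", n_iter)
  n_failed <- 0L
  for (k in seq_len(n_iter)) {
    set.seed(iter_seed(seed, k))
    m <- sample_parameter(list(family = "normal", mean = 1, sd = effect_cv))
    rr_k <- if (ctx$D > 0) {
      rlnorm(ctx$D, log(ctx$rr), ctx$rr_log_se)
    } else numeric()
    mu_se <- ctx$cohorts$bmi_mu_se %||% rep(0, ctx$C)
    mu_k <- rnorm(ctx$C, ctx$cohorts$bmi_mu, mu_se)
    costs_k <- draw_costs(pt$costs_scen)
    row <- tryCatch({
      int_k <- run_arm(ctx, pif_matrix(ctx, pt$reduction * m, rr = rr_k,
                                       bmi_mu = mu_k),
                       ref = pt$comparator)
      halys_k <- incremental_halys(pt$comparator, int_k)
      offsets_k <- compute_cost_offsets(pt$comparator, int_k)
      cost_k <- 1e6 * aggregate_intervention_costs(
        costs_k, horizon = config$horizon_age,
        discount_rate = config$discount_rate,
        labelling_cycle = labelling_cycle
      )
      net_k <- cost_k + offsets_k
      tibble::tibble(
        iter = k, effect_multiplier = m, halys = halys_k,
        intervention_cost = cost_k, cost_offsets = offsets_k,
        net_cost = net_k,
        icer = ifelse(halys_k != 0, net_k / halys_k, NA_real_)
      )
    }, foplcea_model_error = function(e) {
      n_failed <<- n_failed + 1L
      tibble::tibble(iter = k, effect_multiplier = m, halys = NA_real_,
                     intervention_cost = NA_real_, cost_offsets = NA_real_,
                     net_cost = NA_real_, icer = NA_real_)
    })
    rows[[k]] <- row
  }
  iterations <- dplyr::bind_rows(rows)
  iterations$quadrant <- ce_quadrant(iterations$halys, iterations$net_cost)
  structure(
    list(iterations = iterations, point = pt$ce, n_failed = n_failed,
         scenario = scenario, attributable_fraction = attributable_fraction,
         n_iter = n_iter, seed = seed, wtp = wtp, config = config),
    class = "fopl_psa"
  )
}

#' Cost-effectiveness plane quadrant of an iteration
#'
#' Quadrants follow the CE-plane convention: incremental HALYs on the
#' horizontal axis (East = health gained), incremental net cost on the
#' vertical (North = costs more). Boundary iterations are assigned to the
#' positive-cost (N) and positive-effect (E) sides.
#'
#' @param halys,net_cost Numeric vectors.
#' @return Character vector in `{"NE", "NW", "SE", "SW"}` (`NA` propagates).
#' @export
ce_quadrant <- function(halys, net_cost) {
  ifelse(is.na(halys) | is.na(net_cost), NA_character_,
         paste0(ifelse(net_cost >= 0, "N", "S"),
                ifelse(halys >= 0, "E", "W")))
}

#' Summarise a PSA
#'
#' Means and percentile 95% uncertainty intervals (2.5th/97.5th) for
#' incremental HALYs, intervention costs, offsets and net costs over the
#' successful iterations, CE-plane quadrant shares, and the ICER summary. The
#' mean ICER averages per-iteration ICERs across iterations with positive
#' health gain (dominant iterations contribute their negative ratio); its
#' interval lower bound is labelled dominant when the 2.5th-percentile
#' iteration is cost-saving.
#'
#' @param psa A `fopl_psa` object (or its `iterations` tibble).
#' @return A list of class `fopl_psa_summary` with `summary` (tibble:
#'   quantity, mean, ui_low, ui_high), `icer` (mean, ui_low, ui_high,
#'   `ui_low_dominant` flag) and `quadrant_shares` (named proportions summing
#'   to 1 over non-failed iterations).
#' @export
summarize_psa <- function(psa) {
  it <- if (inherits(psa, "fopl_psa")) psa$iterations else psa
  if (!"quadrant" %in% names(it)) {
    it$quadrant <- ce_quadrant(it$halys, it$net_cost)
  }
  ok <- it[!is.na(it$halys), ]
  if (nrow(ok) < 2L) stop_invalid("need at least 2 successful iterations")
  summarise_one <- function(x, name) {
    tibble::tibble(quantity = name, mean = mean(x),
                   ui_low = unname(quantile(x, 0.025)),
                   ui_high = unname(quantile(x, 0.975)))
  }
  summary <- dplyr::bind_rows(
    summarise_one(ok$halys, "halys"),
    summarise_one(ok$intervention_cost, "intervention_cost"),
    summarise_one(ok$cost_offsets, "cost_offsets"),
    summarise_one(ok$net_cost, "net_cost")
  )
  gain <- ok[ok$halys > 0, ]
  icer <- if (nrow(gain) >= 2L) {
    lo <- unname(quantile(gain$icer, 0.025))
    list(mean = mean(gain$icer), ui_low = lo,
         ui_high = unname(quantile(gain$icer, 0.975)),
         ui_low_dominant = lo < 0)
  } else {
    list(mean = NA_real_, ui_low = NA_real_, ui_high = NA_real_,
         ui_low_dominant = NA)
  }
  shares <- table(factor(ok$quadrant, levels = c("NE", "NW", "SE", "SW")))
  shares <- as.numeric(shares) / nrow(ok)
  names(shares) <- c("NE", "NW", "SE", "SW")
  structure(list(summary = summary, icer = icer, quadrant_shares = shares,
                 n = nrow(ok)),
            class = "fopl_psa_summary")
}

#' @export
print.fopl_psa_summary <- function(x, ...) {
  cat(sprintf("PSA summary over %d iterations\n", x$n))
  print(x$summary)
  lo <- if (isTRUE(x$icer$ui_low_dominant)) "dominant" else
    format(round(x$icer$ui_low))
  cat(sprintf("Mean ICER (health-gaining iterations): %s (95%% UI %s to %s) per HALY\n",
              format(round(x$icer$mean)), lo, format(round(x$icer$ui_high))))
  cat("Quadrant shares:",
      paste(sprintf("%s %.1f%%", names(x$quadrant_shares),
                    100 * x$quadrant_shares), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fopl_psa <- function(x, ...) {
  cat(sprintf("<fopl_psa> %s scenario, attributable fraction %.2f, %d iterations (%d failed)\n",
              x$scenario, x$attributable_fraction, x$n_iter, x$n_failed))
  print(summarize_psa(x))
  invisible(x)
}

#' Tidy PSA iterations
#'
#' @param x A `fopl_psa` object.
#' @param ... Unused.
#' @return The per-iteration tibble (one row per Monte Carlo iteration).
#' @method tidy fopl_psa
#' @export
tidy.fopl_psa <- function(x, ...) {
  x$iterations
}

#' One-row PSA summary
#'
#' @param x A `fopl_psa` object.
#' @param ... Unused.
#' @return A one-row tibble: scenario, attributable fraction, iteration
#'   counts, mean and 95% UI of HALYs and net cost, mean ICER and quadrant
#'   shares.
#' @method glance fopl_psa
#' @export
glance.fopl_psa <- function(x, ...) {
  s <- summarize_psa(x)
  g <- function(q, f) s$summary[[f]][s$summary$quantity == q]
  tibble::tibble(
    scenario = x$scenario,
    attributable_fraction = x$attributable_fraction,
    n_iter = x$n_iter,
    n_failed = x$n_failed,
    halys_mean = g("halys", "mean"),
    halys_ui_low = g("halys", "ui_low"),
    halys_ui_high = g("halys", "ui_high"),
    net_cost_mean = g("net_cost", "mean"),
    net_cost_ui_low = g("net_cost", "ui_low"),
    net_cost_ui_high = g("net_cost", "ui_high"),
    icer_mean = s$icer$mean,
    icer_ui_low = s$icer$ui_low,
    icer_ui_low_dominant = s$icer$ui_low_dominant,
    icer_ui_high = s$icer$ui_high,
    share_ne = s$quadrant_shares[["NE"]],
    share_nw = s$quadrant_shares[["NW"]],
    share_se = s$quadrant_shares[["SE"]],
    share_sw = s$quadrant_shares[["SW"]]
  )
}
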