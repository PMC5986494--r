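#' Per-category difference-in-difference reformulation effects
#'
#' Splits each food category into a labelled arm (products displaying the
#' front-of-pack label in the post year) and an unlabelled arm, computes
#' unweighted mean energy densities per arm and year, and forms the
#' difference-in-difference: the labelled arm's percent energy-density change
#' minus the unlabelled arm's, interpreted as the percentage-point change
#' attributable to the label.
#'
#' A category with an empty arm gets `NA` for that arm's columns and an
#' undefined `pct_attributable`; a warning names it, and downstream weighting
#' drops it.
#'
#' @param products Product table with columns `category`, `labelled`,
#'   `ed_year0`, `ed_year1` (see [simulate_products()] for the schema).
#' @param exclude Character vector of categories to drop before analysis
#'   (non-reformulable or label-ineligible categories).
#' @return A tibble of class `fopl_category_effects`, one row per retained
#'   category: arm means per year, absolute changes (kJ/100 g), percent
#'   changes (% of the arm's year-0 baseline), label share, and
#'   `pct_attributable` (percentage points).
#' @examples
#' prods <- simulate_products(sim_config(seed = 3, n_products = 2000))
#' compute_category_effects(prods)
#' @export
compute_category_effects <- function(products, exclude = NULL) {
  req <- c("category", "labelled", "ed_year0", "ed_year1")
  missing_cols <- setdiff(req, names(products))
  if (length(missing_cols)) {
    stop_invalid(paste("product table missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  dat <- dplyr::filter(products, !.data$category %in% exclude)
  if (nrow(dat) == 0L) stop_invalid("no products left after exclusions")

  arm <- dat |>
    dplyr::group_by(.data$category, .data$labelled) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_y0 = mean(.data$ed_year0),
      mean_y1 = mean(.data$ed_year1),
      .groups = "drop"
    )
  eff <- arm |>
    dplyr::mutate(arm = ifelse(.data$labelled, "labelled", "unlabelled")) |>
    dplyr::select(-"labelled") |>
    tidyr::pivot_wider(
      names_from = "arm",
      values_from = c("n", "mean_y0", "mean_y1"),
      values_fill = list(n_labelled = 0L, n_unlabelled = 0L)
    )
  for (col in c("n_labelled", "n_unlabelled", "mean_y0_labelled",
                "mean_y0_unlabelled", "mean_y1_labelled",
                "mean_y1_unlabelled")) {
    if (!col %in% names(eff)) eff[[col]] <- NA_real_
  }
  eff <- eff |>
    dplyr::mutate(
      abs_change_labelled = .data$mean_y1_labelled - .data$mean_y0_labelled,
      abs_change_unlabelled = .data$mean_y1_unlabelled - .data$mean_y0_unlabelled,
      pct_change_labelled = 100 * .data$abs_change_labelled / .data$mean_y0_labelled,
      pct_change_unlabelled = 100 * .data$abs_change_unlabelled / .data$mean_y0_unlabelled,
      pct_attributable = .data$pct_change_labelled - .data$pct_change_unlabelled,
      label_share = dplyr::coalesce(.data$n_labelled, 0L) /
        (dplyr::coalesce(.data$n_labelled, 0L) + dplyr::coalesce(.data$n_unlabelled, 0L))
    ) |>
    dplyr::arrange(.data$category)
  bad <- eff$category[!is.finite(eff$pct_attributable)]
  if (length(bad)) {
    warn(paste("categories with an empty arm, attributable effect undefined:",
               paste(bad, collapse = ", ")))
  }
  class(eff) <- c("fopl_category_effects", class(eff))
  eff
}

#' Label uptake with 95% binomial confidence interval
#'
#' Proportion of products displaying the label in the post year, with a Wald
#' (normal-approximation) 95% interval clipped to `[0, 1]`.
#'
#' @param products Product table with a logical `labelled` column, or `NULL`
#'   when `n_labelled`/`n_total` are given directly.
#' @param n_labelled,n_total Direct counts, used when `products` is `NULL`.
#' @return A list of class `fopl_uptake` with fields `n_labelled`, `n_total`,
#'   `proportion`, `ci_low`, `ci_high`.
#' @examples
#' estimate_uptake(n_labelled = 1004, n_total = 14986)
#' @export
estimate_uptake <- function(products = NULL, n_labelled = NULL, n_total = NULL) {
  if (!is.null(products)) {
    n_labelled <- sum(products$labelled)
    n_total <- nrow(products)
  }
  if (is.null(n_total) || n_total <= 0) {
    stop_invalid("`n_total` must be positive")
  }
  p <- n_labelled / n_total
  half <- qnorm(0.975) * sqrt(p * (1 - p) / n_total)
  structure(
    list(
      n_labelled = n_labelled,
      n_total = n_total,
      proportion = p,
      ci_low = max(0, p - half),
      ci_high = min(1, p + half)
    ),
    class = "fopl_uptake"
  )
}

#' @export
print.fopl_uptake <- function(x, ...) {
  cat(sprintf("Label uptake: %d / %d = %.1f%% (95%% CI %.1f%% to %.1f%%)\n",
              x$n_labelled, x$n_total, 100 * x$proportion,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Paired t-test on matched energy densities
#'
#' Two-sided paired t-test of the post-minus-pre energy-density differences of
#' products present in both years, the standard significance test for an
#' overall reformulation shift.
#'
#' @param y0,y1 Equal-length numeric vectors: pre and post energy densities of
#'   the same products, in matching order.
#' @return A list of class `fopl_paired_test` with `mean_diff`, `ci_low`,
#'   `ci_high`, `t_stat`, `df`, `p_value`, `n`.
#' @examples
#' paired_energy_test(c(1, 2, 3), c(2, 4, 3))
#' @export
paired_energy_test <- function(y0, y1) {
  if (length(y0) != length(y1)) stop_invalid("`y0` and `y1` must be the same length")
  if (length(y0) < 2L) stop_invalid("need at least 2 matched pairs")
  d <- y1 - y0
  if (sd(d) == 0) {
    abort("differences have zero variance; t statistic undefined",
          class = "foplcea_degenerate_variance")
  }
  fit <- t.test(y1, y0, paired = TRUE)
  structure(
    list(
      mean_diff = unname(fit$estimate),
      ci_low = fit$conf.int[1],
      ci_high = fit$conf.int[2],
      t_stat = unname(fit$statistic),
      df = unname(fit$parameter),
      p_value = fit$p.value,
      n = length(d)
    ),
    class = "fopl_paired_test"
  )
}

#' @export
print.fopl_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: mean diff %.2f (95%% CI %.2f to %.2f), t = %.3f, df = %d, p = %.4g\n",
    x$mean_diff, x$ci_low, x$ci_high, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Scenario energy-density effect per category
#'
#' Converts per-category difference-in-difference estimates into the
#' per-category energy-density change (kJ/g) a scenario applies to the food
#' supply. The attributable absolute change per labelled product is the
#' labelled arm's baseline times `pct_attributable`/100; under the voluntary
#' scenario only the labelled share of the category reformulates, so the
#' category-average change is that times the category's label share. Dividing
#' by the label share ([scale_to_mandatory()]) then gives the 100%-uptake
#' (mandatory) change. Categories with an undefined effect (empty arm) are
#' dropped with a warning.
#'
#' @param effects A [compute_category_effects()] result.
#' @param scenario `"voluntary"` or `"mandatory"`.
#' @param attributable_fraction Fraction of the observed differential credited
#'   to the labelling scheme (sensitivity lever in `[0, 1]`; default 1).
#' @return A tibble of class `fopl_scenario_effect` with columns `category`,
#'   `delta_kj_per_g`, `label_share`, plus `scenario` and
#'   `attributable_fraction` attributes carried as columns.
#' @export
scenario_effect <- function(effects, scenario = c("voluntary", "mandatory"),
                            attributable_fraction = 1) {
  scenario <- match.arg(scenario)
  check_number(attributable_fraction, "attributable_fraction", 0, 1)
  ok <- is.finite(effects$pct_attributable)
  if (any(!ok)) {
    warn(paste("dropping categories with undefined attributable effect:",
               paste(effects$category[!ok], collapse = ", ")))
  }
  eff <- effects[ok, ]
  # attributable change per labelled product, kJ/100 g
  attr_abs <- eff$mean_y0_labelled * eff$pct_attributable / 100
  out <- tibble::tibble(
    category = eff$category,
    scenario = "voluntary",
    attributable_fraction = attributable_fraction,
    label_share = eff$label_share,
    delta_kj_per_g = eff$label_share * attr_abs / 100 * attributable_fraction
  )
  class(out) <- c("fopl_scenario_effect", class(out))
  if (scenario == "mandatory") out <- scale_to_mandatory(out) else out
}

#' Rescale a voluntary effect to 100% (mandatory) uptake
#'
#' Cross-multiplication: each category's voluntary energy-density change is
#' divided by that category's label-uptake fraction, i.e. multiplied by
#' 100% / uptake%, giving the change expected if every product in the category
#' reformulated the way labelled products did.
#'
#' @param effect A `fopl_scenario_effect` tibble (voluntary).
#' @param uptake Optional per-category uptake fractions in `(0, 1]`; defaults
#'   to the `label_share` column carried on `effect`.
#' @return The effect tibble with `delta_kj_per_g` rescaled and `scenario`
#'   set to `"mandatory"`.
#' @export
scale_to_mandatory <- function(effect, uptake = NULL) {
  uptake <- uptake %||% effect$label_share
  bad <- uptake <= 0 & effect$delta_kj_per_g != 0
  if (any(bad)) {
    abort(paste("zero uptake with nonzero change; mandatory scaling undefined for:",
                paste(effect$category[bad], collapse = ", ")),
          class = "foplcea_undefined_scaling")
  }
  effect$delta_kj_per_g <- ifelse(effect$delta_kj_per_g == 0, 0,
                                  effect$delta_kj_per_g / uptake)
  effect$scenario <- "mandatory"
  effect
}

#' Apply an attributable-fraction sensitivity multiplier
#'
#' Multiplies every category's energy-density change by `fraction`, the share
#' of the observed labelled-vs-unlabelled differential assumed attributable to
#' the labelling scheme (1 = all of it, 0 = none).
#'
#' @param effect A `fopl_scenario_effect` tibble.
#' @param fraction Number in `[0, 1]`.
#' @return The rescaled effect tibble.
#' @export
apply_attributable_fraction <- function(effect, fraction) {
  check_number(fraction, "fraction", 0, 1)
  base <- effect$attributable_fraction
  if (any(base == 0) && fraction != 0) {
    stop_invalid("effect was built at attributable fraction 0; cannot rescale upward")
  }
  effect$delta_kj_per_g <- if (fraction == 0) {
    0 * effect$delta_kj_per_g
  } else {
    effect$delta_kj_per_g / base * fraction
  }
  effect$attributable_fraction <- fraction
  effect
}
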