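#' Validate the five input tables
#'
#' Schema and invariant checks across the product, consumption, population,
#' disease and cost tables: required columns, nonnegative consumption,
#' positive energy densities, rate ranges, heights, min <= point <= max cost
#' ranges, known schedules, zero incidence below each disease's minimum age,
#' and age-group consistency across tables (every table must use the
#' population's age groups, which must start at 0 and be shared by both
#' sexes). Every violation is reported with the offending table and rows.
#'
#' @param inputs A `fopl_inputs` list or any list with elements `products`,
#'   `consumption`, `population`, `diseases`, `costs`.
#' @return A tibble of class `fopl_validation` with columns `table`, `check`,
#'   `detail`; zero rows means the inputs are valid.
#' @examples
#' validate_inputs(fixture_inputs(500))
#' @export
validate_inputs <- function(inputs) {
  v <- list()
  add <- function(table, check, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(table = table, check = check,
                                           detail = detail)
  }
  need <- function(tab, name, cols) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) {
      add(name, "missing_column", paste(miss, collapse = ", "))
      return(FALSE)
    }
    TRUE
  }
  rows_of <- function(idx) paste(utils::head(which(idx), 5), collapse = ", ")

  pr <- inputs$products
  if (need(pr, "products", c("category", "labelled", "ed_year0", "ed_year1"))) {
    if (any(pr$ed_year0 <= 0 | pr$ed_year1 <= 0)) {
      add("products", "nonpositive_energy_density",
          rows_of(pr$ed_year0 <= 0 | pr$ed_year1 <= 0))
    }
    if (!is.logical(pr$labelled)) add("products", "label_flag_not_logical", "")
  }

  cons <- inputs$consumption
  if (need(cons, "consumption", c("age_lo", "sex", "category", "grams_day"))) {
    if (any(cons$grams_day < 0)) {
      add("consumption", "negative_grams_day", rows_of(cons$grams_day < 0))
    }
  }

  pop <- inputs$population
  pop_ok <- need(pop, "population",
                 c("age_lo", "sex", "size", "bmi_mu", "bmi_sigma", "height_m",
                   "mortality", "yld_rate"))
  if (pop_ok) {
    if (any(pop$size <= 0)) add("population", "nonpositive_size", rows_of(pop$size <= 0))
    if (any(pop$bmi_sigma <= 0)) add("population", "nonpositive_bmi_sigma",
                                     rows_of(pop$bmi_sigma <= 0))
    if (any(pop$height_m < 0.5 | pop$height_m > 2.1)) {
      add("population", "height_out_of_range",
          rows_of(pop$height_m < 0.5 | pop$height_m > 2.1))
    }
    if (any(pop$mortality <= 0 | pop$mortality >= 1)) {
      add("population", "mortality_out_of_range",
          rows_of(pop$mortality <= 0 | pop$mortality >= 1))
    }
    if (any(pop$yld_rate < 0 | pop$yld_rate >= 1)) {
      add("population", "yld_out_of_range",
          rows_of(pop$yld_rate < 0 | pop$yld_rate >= 1))
    }
    groups <- sort(unique(pop$age_lo))
    if (length(groups) == 0 || groups[1] != 0) {
      add("population", "age_groups_not_partition",
          "age groups must start at 0")
    }
    by_sex <- split(pop$age_lo, pop$sex)
    if (length(by_sex) == 2 &&
        !identical(sort(by_sex[[1]]), sort(by_sex[[2]]))) {
      add("population", "age_groups_not_partition",
          "sexes carry different age groups")
    }
    for (nm in c("consumption", "diseases")) {
      tab <- inputs[[nm]]
      if (!is.null(tab) && "age_lo" %in% names(tab)) {
        extra <- setdiff(unique(tab$age_lo), groups)
        gaps <- setdiff(groups, unique(tab$age_lo))
        if (length(extra) || length(gaps)) {
          add(nm, "age_groups_not_partition",
              paste("age groups differ from population:",
                    paste(c(extra, gaps), collapse = ", ")))
        }
      }
    }
  }

  dis <- inputs$diseases
  if (!is.null(dis) && nrow(dis) &&
      need(dis, "diseases",
           c("disease", "age_lo", "sex", "incidence", "case_fatality",
             "remission", "disability_weight", "rr_per_5bmi",
             "cost_per_case_year", "min_age"))) {
    for (col in c("incidence", "case_fatality", "remission")) {
      if (any(dis[[col]] < 0 | dis[[col]] >= 1)) {
        add("diseases", paste0(col, "_out_of_range"),
            rows_of(dis[[col]] < 0 | dis[[col]] >= 1))
      }
    }
    if (any(dis$disability_weight <= 0 | dis$disability_weight >= 1)) {
      add("diseases", "disability_weight_out_of_range",
          rows_of(dis$disability_weight <= 0 | dis$disability_weight >= 1))
    }
    if (any(dis$rr_per_5bmi <= 0)) {
      add("diseases", "nonpositive_rr", rows_of(dis$rr_per_5bmi <= 0))
    }
    if (any(dis$cost_per_case_year <= 0)) {
      add("diseases", "nonpositive_cost", rows_of(dis$cost_per_case_year <= 0))
    }
    young <- dis$age_lo < dis$min_age & dis$incidence > 0
    if (any(young)) add("diseases", "incidence_below_min_age", rows_of(young))
  }

  co <- inputs$costs
  if (need(co, "costs", c("item", "scenario", "point_m", "min_m", "max_m",
                          "schedule", "family"))) {
    bad <- !(co$min_m <= co$point_m & co$point_m <= co$max_m)
    if (any(bad)) add("costs", "range_violation", rows_of(bad))
    unk <- !co$schedule %in% c("one_off", "annual", "per_cycle")
    if (any(unk)) add("costs", "unknown_schedule", rows_of(unk))
  }

  out <- if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(table = character(), check = character(),
                   detail = character())
  }
  class(out) <- c("fopl_validation", class(out))
  out
}

#' Run a full scenario end to end
#'
#' Orchestrates the whole pipeline on one input set: validation, label-uptake
#' estimation, per-category difference-in-difference effects, scenario
#' scaling, cohort intake/weight/BMI changes, the proportional multi-state
#' life table under both arms, cost aggregation and offsets, the
#' cost-effectiveness outcome, and (when `n_iter > 0`) the Monte Carlo
#' probabilistic sensitivity analysis.
#'
#' @inheritParams run_psa
#' @param n_iter PSA iterations; 0 skips the PSA.
#' @param ew_params Energy-to-weight coefficients,
#'   see [energy_weight_params()].
#' @param validate Run [validate_inputs()] first and fail on violations.
#' @return A list of class `fopl_run`: `scenario`, `attributable_fraction`,
#'   `uptake`, `effects`, `scenario_effect`, `anthro`, `lifetable`
#'   (`fopl_lifetable_pair`), `ce` (point estimates), `psa` (or `NULL`), and
#'   the settings used. Summarise with [glance()]; plot the PSA with
#'   [autoplot()].
#' @examples
#' run <- run_scenario(fixture_inputs(800), "voluntary", n_iter = 0)
#' glance(run)
#' @export
run_scenario <- function(inputs, scenario = c("voluntary", "mandatory"),
                         attributable_fraction = 1, n_iter = 0, seed = 1,
                         config = pmslt_config(), wtp = 50000,
                         labelling_cycle = 3,
                         ew_params = energy_weight_params(),
                         validate = TRUE) {
  scenario <- match.arg(scenario)
  check_number(attributable_fraction, "attributable_fraction", 0, 1)
  if (validate) {
    viol <- validate_inputs(inputs)
    if (nrow(viol) > 0) {
      stop_invalid(paste0(
        "input validation failed with ", nrow(viol), " violation(s): ",
        paste(sprintf("[%s] %s (%s)", viol$table, viol$check, viol$detail),
              collapse = "; ")
      ))
    }
  }
  uptake <- estimate_uptake(inputs$products)
  pt <- point_pipeline(inputs, scenario, attributable_fraction, config, wtp,
                       labelling_cycle, ew_params)
  psa <- if (n_iter > 0) {
    run_psa(inputs, scenario, attributable_fraction, n_iter = n_iter,
            seed = seed, config = config, wtp = wtp,
            labelling_cycle = labelling_cycle)
  }
  structure(
    list(
      scenario = scenario, attributable_fraction = attributable_fraction,
      uptake = uptake, effects = pt$effects,
      scenario_effect = pt$scenario_effect, anthro = pt$anthro,
      lifetable = structure(list(comparator = pt$comparator,
                                 intervention = pt$intervention,
                                 context = pt$ctx,
                                 delta_bmi = -pt$reduction),
                            class = "fopl_lifetable_pair"),
      ce = pt$ce, psa = psa,
      seed = seed, wtp = wtp, config = config,
      labelling_cycle = labelling_cycle
    ),
    class = "fopl_run"
  )
}

#' @export
print.fopl_run <- function(x, ...) {
  cat(sprintf("<fopl_run> %s scenario, attributable fraction %.0f%%\n",
              x$scenario, 100 * x$attributable_fraction))
  cat(sprintf("  uptake: %.1f%% (%.1f%% to %.1f%%)\n",
              100 * x$uptake$proportion, 100 * x$uptake$ci_low,
              100 * x$uptake$ci_high))
  cat(sprintf("  intervention cost: A$%.1f m | offsets: A$%.1f m | net: A$%.1f m\n",
              x$ce$intervention_cost / 1e6, x$ce$cost_offsets / 1e6,
              x$ce$net_cost / 1e6))
  icer_txt <- if (identical(x$ce$dominance, "dominant")) "dominant"
  else if (is.na(x$ce$icer)) "undefined"
  else sprintf("A$%s per HALY", format(round(x$ce$icer), big.mark = ","))
  cat(sprintf("  incremental HALYs: %s | ICER: %s\n",
              format(round(x$ce$halys), big.mark = ","), icer_txt))
  if (!is.null(x$psa)) {
    cat(sprintf("  PSA: %d iterations (seed %d)\n", x$psa$n_iter, x$psa$seed))
  }
  invisible(x)
}

#' Attributable-fraction sensitivity analysis
#'
#' Reruns a scenario at several attributable fractions (the share of the
#' observed reformulation differential credited to the labelling scheme) and
#' stacks the one-row summaries, the standard univariate sensitivity table
#' for this intervention.
#'
#' @inheritParams run_scenario
#' @param fractions Attributable fractions to evaluate.
#' @return A tibble with one [glance()] row per fraction.
#' @export
sensitivity_analysis <- function(inputs, fractions = c(1, 0.5, 0.3, 0.1),
                                 scenario = "voluntary", n_iter = 0,
                                 seed = 1, config = pmslt_config(),
                                 wtp = 50000, labelling_cycle = 3) {
  purrr::map_dfr(fractions, function(f) {
    glance(run_scenario(inputs, scenario, attributable_fraction = f,
                        n_iter = n_iter, seed = seed, config = config,
                        wtp = wtp, labelling_cycle = labelling_cycle,
                        validate = FALSE))
  })
}

#' Write / read an input set as CSV files
#'
#' Writes the five tables of a `fopl_inputs` list as plain CSVs
#' (`products.csv`, `consumption.csv`, `population.csv`, `diseases.csv`,
#' `costs.csv`) into a directory, and reads them back.
#'
#' @param inputs A `fopl_inputs` list.
#' @param dir Directory path.
#' @return `write_inputs()` returns `dir` invisibly; `read_inputs()` returns
#'   a `fopl_inputs` list.
#' @export
write_inputs <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("products", "consumption", "population", "diseases", "costs")) {
    utils::write.csv(inputs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_inputs
#' @export
read_inputs <- function(dir) {
  out <- lapply(
    c("products", "consumption", "population", "diseases", "costs"),
    function(nm) {
      tibble::as_tibble(utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
    }
  )
  names(out) <- c("products", "consumption", "population", "diseases", "costs")
  out$products$labelled <- as.logical(out$products$labelled)
  structure(out, class = "fopl_inputs")
}
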