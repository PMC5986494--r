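#' Energy-to-weight conversion parameters
#'
#' Linear steady-state coefficients linking a permanent change in daily energy
#' intake to the eventual change in body weight: `rho` kJ/day per kg, with
#' separate values for adults and children. The default 100 kJ/day per kg is
#' the commonly used adult steady-state approximation; it is a configurable
#' parameter, not a law.
#'
#' @param rho_adult,rho_child kJ/day of intake change per kg of steady-state
#'   weight change (both > 0).
#' @param adult_age Age threshold (years) separating the two coefficients.
#' @return A list of class `fopl_energy_weight_params`.
#' @export
energy_weight_params <- function(rho_adult = 100, rho_child = 100,
                                 adult_age = 18) {
  check_number(rho_adult, "rho_adult", lower = 1e-9)
  check_number(rho_child, "rho_child", lower = 1e-9)
  check_number(adult_age, "adult_age", 0, 100)
  structure(list(rho_adult = rho_adult, rho_child = rho_child,
                 adult_age = adult_age),
            class = "fopl_energy_weight_params")
}

#' Cohort-level daily energy-intake change
#'
#' Consumption-weighted sum of per-category energy-density changes: for each
#' age group and sex, the kJ/day change is the sum over categories of the
#' scenario's kJ/g change times the grams/day that cohort consumes of the
#' category. Consumed categories without an estimated effect contribute zero
#' (with a message); negative consumption is an error.
#'
#' @param effects A [scenario_effect()] tibble (kJ/g by category).
#' @param consumption Consumption table (`age_lo`, `sex`, `category`,
#'   `grams_day`).
#' @return A tibble with columns `age_lo`, `sex`, `delta_kj_day`.
#' @examples
#' eff <- tibble::tibble(category = "a", scenario = "voluntary",
#'                       attributable_fraction = 1, label_share = 1,
#'                       delta_kj_per_g = -0.01)
#' cons <- tibble::tibble(age_lo = 20, sex = "female", category = "a",
#'                        grams_day = 200)
#' weighted_intake_change(eff, cons)
#' @export
weighted_intake_change <- function(effects, consumption) {
  if (any(consumption$grams_day < 0)) {
    stop_invalid("negative grams/day in consumption table")
  }
  missing_cats <- setdiff(unique(consumption$category), effects$category)
  if (length(missing_cats)) {
    inform(paste("categories consumed but without an estimated effect (treated as zero change):",
                 paste(missing_cats, collapse = ", ")))
  }
  consumption |>
    dplyr::left_join(effects[, c("category", "delta_kj_per_g")],
                     by = "category") |>
    dplyr::mutate(delta_kj_per_g = dplyr::coalesce(.data$delta_kj_per_g, 0)) |>
    dplyr::group_by(.data$age_lo, .data$sex) |>
    dplyr::summarise(
      delta_kj_day = sum(.data$delta_kj_per_g * .data$grams_day),
      .groups = "drop"
    )
}

#' Convert a daily energy-intake change to a body-weight change
#'
#' Steady-state linear conversion: `delta_kg = delta_kj / rho`, with `rho`
#' chosen by age relative to the adult threshold. The resulting weight change
#' is interpreted as a permanent shift.
#'
#' @param delta_kj kJ/day change (vectorised).
#' @param age Age in years (vectorised, recycled against `delta_kj`).
#' @param params An [energy_weight_params()] list.
#' @return Weight change in kg.
#' @export
energy_to_weight <- function(delta_kj, age, params = energy_weight_params()) {
  if (any(!is.finite(delta_kj))) stop_invalid("`delta_kj` must be finite")
  rho <- ifelse(age >= params$adult_age, params$rho_adult, params$rho_child)
  delta_kj / rho
}

#' Convert a weight change to a BMI change
#'
#' `delta_bmi = delta_kg / height_m^2`, the exact arithmetic relation between
#' a weight shift and the BMI shift at fixed height.
#'
#' @param delta_kg Weight change in kg (vectorised).
#' @param height_m Height in metres (> 0).
#' @return BMI change in kg/m^2.
#' @export
weight_to_bmi <- function(delta_kg, height_m) {
  if (any(height_m <= 0)) stop_invalid("`height_m` must be positive")
  delta_kg / height_m^2
}

#' Full intake-to-anthropometry chain for every cohort
#'
#' Runs [weighted_intake_change()], [energy_to_weight()] and
#' [weight_to_bmi()] across the population: one row per age group and sex
#' with the scenario's kJ/day, kg and BMI changes. The BMI change is later
#' applied as a uniform location shift to the cohort's BMI distribution.
#'
#' @param effects A [scenario_effect()] tibble.
#' @param consumption Consumption table.
#' @param population Population table (provides heights and the age-group
#'   scaffold).
#' @param params An [energy_weight_params()] list.
#' @return A tibble with columns `age_lo`, `sex`, `delta_kj_day`, `delta_kg`,
#'   `delta_bmi`.
#' @export
cohort_anthro_changes <- function(effects, consumption, population,
                                  params = energy_weight_params()) {
  intake <- weighted_intake_change(effects, consumption)
  population[, c("age_lo", "sex", "height_m")] |>
    dplyr::left_join(intake, by = c("age_lo", "sex")) |>
    dplyr::mutate(
      delta_kj_day = dplyr::coalesce(.data$delta_kj_day, 0),
      delta_kg = energy_to_weight(.data$delta_kj_day, .data$age_lo, params),
      delta_bmi = weight_to_bmi(.data$delta_kg, .data$height_m)
    ) |>
    dplyr::select("age_lo", "sex", "delta_kj_day", "delta_kg", "delta_bmi")
}
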