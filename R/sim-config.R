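#' Configuration for the synthetic input generator
#'
#' Bundles every knob of the synthetic data generator that emulates the five
#' tables the cost-effectiveness pipeline consumes: a pre/post product table,
#' a consumption table, a population table, a disease table and a cost table.
#' Defaults describe the study conditions the pipeline targets: roughly 15,000
#' pre-packaged products in 13 reformulable categories, a 6.7% voluntary label
#' uptake, a mean extra energy-density reduction of -7.11 kJ/100 g among
#' labelled products, nine adult-onset obesity-related diseases, and a 3%
#' annual discount rate.
#'
#' @param seed Integer seed controlling all randomness in the generator.
#' @param n_products Number of products present in both survey years.
#' @param n_categories Number of food categories (label-eligible only).
#' @param uptake_target Probability that a product displays the label in the
#'   post year (voluntary uptake).
#' @param labelled_reform_mean Mean *extra* year1 - year0 energy-density change
#'   (kJ/100 g) among labelled products, on top of the secular drift shared by
#'   all products. Negative means labelled products reformulate downwards.
#' @param secular_drift_mean Mean energy-density change (kJ/100 g) affecting
#'   all products regardless of labelling.
#' @param ed_noise_sd Standard deviation (kJ/100 g) of product-level noise on
#'   the year1 - year0 change. Set to 0 for a noise-free generator.
#' @param age_breaks Increasing vector of ages partitioning `[0, 100)` into
#'   age groups; the default is 5-year groups.
#' @param n_diseases Number of obesity-related disease slots.
#' @param discount_rate Annual discount rate applied to health and cost
#'   streams.
#' @param adult_age Age (years) below which disease incidence is zero and the
#'   child energy-to-weight coefficient applies.
#'
#' @return A list of class `fopl_sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_products = 500)
#' cfg$uptake_target
#' @export
sim_config <- function(seed = 1L,
                       n_products = 14986,
                       n_categories = 13,
                       uptake_target = 0.067,
                       labelled_reform_mean = -7.11,
                       secular_drift_mean = -2,
                       ed_noise_sd = 25,
                       age_breaks = seq(0, 100, by = 5),
                       n_diseases = 9,
                       discount_rate = 0.03,
                       adult_age = 18) {
  n_products <- check_count(n_products, "n_products")
  n_categories <- check_count(n_categories, "n_categories")
  n_diseases <- check_count(n_diseases, "n_diseases")
  check_number(uptake_target, "uptake_target", lower = 1e-12, upper = 1)
  check_number(labelled_reform_mean, "labelled_reform_mean")
  check_number(ed_noise_sd, "ed_noise_sd", lower = 0)
  check_number(discount_rate, "discount_rate", lower = 0, upper = 1)
  check_number(adult_age, "adult_age", lower = 0, upper = 100)
  if (length(age_breaks) < 2L || age_breaks[1] != 0 ||
      age_breaks[length(age_breaks)] != 100 || any(diff(age_breaks) <= 0)) {
    stop_invalid("`age_breaks` must increase from 0 to 100 (a partition of [0, 100))")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_products = n_products,
      n_categories = n_categories,
      uptake_target = uptake_target,
      labelled_reform_mean = labelled_reform_mean,
      secular_drift_mean = secular_drift_mean,
      ed_noise_sd = ed_noise_sd,
      age_breaks = age_breaks,
      n_diseases = n_diseases,
      discount_rate = discount_rate,
      adult_age = adult_age
    ),
    class = "fopl_sim_config"
  )
}

#' @export
print.fopl_sim_config <- function(x, ...) {
  cat("<fopl_sim_config>\n")
  cat(sprintf("  seed %d | %d products, %d categories, uptake %.1f%%\n",
              x$seed, x$n_products, x$n_categories, 100 * x$uptake_target))
  cat(sprintf("  labelled reformulation %.2f kJ/100g, noise sd %.1f\n",
              x$labelled_reform_mean, x$ed_noise_sd))
  cat(sprintf("  %d diseases, %d age groups, discount %.1f%%\n",
              x$n_diseases, length(x$age_breaks) - 1L, 100 * x$discount_rate))
  invisible(x)
}

# age-group scaffold shared by the generators: lower bound and midpoint
age_group_table <- function(cfg) {
  lo <- cfg$age_breaks[-length(cfg$age_breaks)]
  hi <- cfg$age_breaks[-1]
  tibble::tibble(age_lo = lo, age_hi = hi, age_mid = (lo + hi) / 2)
}
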