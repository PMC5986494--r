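#' Simulate a pre/post product table
#'
#' Products are assigned to categories whose baseline energy densities span
#' roughly 200-3100 kJ/100 g (beverages up to oils), the realistic range for
#' pre-packaged foods. Each product's post-year energy density moves by a
#' secular drift shared by all products plus, for labelled products, an extra
#' reduction with mean `labelled_reform_mean` — the label-attributable
#' reformulation signal the difference-in-difference estimator is meant to
#' recover. The label flag is Bernoulli(`uptake_target`).
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `product_id`, `category`, `labelled`,
#'   `ed_year0`, `ed_year1` (kJ/100 g).
#' @examples
#' prods <- simulate_products(sim_config(seed = 2, n_products = 200))
#' mean(prods$labelled)
#' @export
simulate_products <- function(cfg) {
  stopifnot(inherits(cfg, "fopl_sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_products
  baselines <- exp(seq(log(200), log(3100), length.out = cfg$n_categories))
  cat_names <- sprintf("category_%02d", seq_len(cfg$n_categories))
  cat_idx <- sample.int(cfg$n_categories, n, replace = TRUE)
  ed0 <- baselines[cat_idx] * rlnorm(n, 0, 0.25)
  labelled <- rbinom(n, 1L, cfg$uptake_target) == 1L
  change <- rnorm(n, cfg$secular_drift_mean, cfg$ed_noise_sd) +
    labelled * (cfg$labelled_reform_mean + rnorm(n, 0, cfg$ed_noise_sd / 2))
  tibble::tibble(
    product_id = sprintf("p%05d", seq_len(n)),
    category = cat_names[cat_idx],
    labelled = labelled,
    ed_year0 = ed0,
    ed_year1 = pmax(ed0 + change, 0.1)
  )
}

#' Simulate a consumption table
#'
#' Grams/day of each food category by age group and sex. Total pre-packaged
#' intake is around 1.4 kg/day for adults, split across categories with
#' category shares drawn once, scaled down for young children and slightly up
#' for males, with mild cohort-level noise. All entries are nonnegative by
#' construction.
#'
#' @inheritParams simulate_products
#' @return A tibble with columns `age_lo`, `sex`, `category`, `grams_day`.
#' @export
simulate_consumption <- function(cfg) {
  stopifnot(inherits(cfg, "fopl_sim_config"))
  set.seed(cfg$seed + 2L)
  ages <- age_group_table(cfg)
  cat_names <- sprintf("category_%02d", seq_len(cfg$n_categories))
  shares <- rgamma(cfg$n_categories, shape = 2)
  shares <- shares / sum(shares)
  grid <- tidyr::expand_grid(
    age_lo = ages$age_lo,
    sex = c("female", "male"),
    category = cat_names
  ) |>
    dplyr::left_join(ages, by = "age_lo")
  age_factor <- 0.45 + 0.55 * stats::plogis((grid$age_mid - 10) / 4)
  sex_factor <- ifelse(grid$sex == "male", 1.1, 1.0)
  base <- 1400 * shares[match(grid$category, cat_names)]
  grid$grams_day <- base * age_factor * sex_factor *
    rlnorm(nrow(grid), 0, 0.15)
  grid[, c("age_lo", "sex", "category", "grams_day")]
}

#' Simulate a population table
#'
#' One row per age group and sex for a closed 2010-style national population:
#' cohort size, lognormal BMI parameters (log-scale mean and SD, plus a small
#' standard error on the log-mean used by the probabilistic sensitivity
#' analysis), mean height, annual all-cause mortality probability and a total
#' years-lived-with-disability (YLD) morbidity rate. Mean natural-scale BMI
#' rises from ~17 in childhood to ~27.5 in mid-adulthood, matching the
#' positively skewed adult BMI distributions national surveys report.
#' Mortality is Gompertz-shaped, hence nondecreasing in age.
#'
#' @inheritParams simulate_products
#' @return A tibble with columns `age_lo`, `sex`, `size`, `bmi_mu`,
#'   `bmi_sigma`, `bmi_mu_se`, `height_m`, `mortality`, `yld_rate`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "fopl_sim_config"))
  set.seed(cfg$seed + 3L)
  ages <- age_group_table(cfg)
  grid <- tidyr::expand_grid(age_lo = ages$age_lo, sex = c("female", "male")) |>
    dplyr::left_join(ages, by = "age_lo")
  mid <- grid$age_mid
  male <- grid$sex == "male"

  size <- 700000 * stats::plogis((86 - mid) / 7) *
    (grid$age_hi - grid$age_lo) / 5 * rlnorm(nrow(grid), 0, 0.03)

  mean_bmi <- 15.5 + 12 * stats::plogis((mid - 16) / 6) +
    rnorm(nrow(grid), 0, 0.3)
  bmi_sigma <- pmax(rnorm(nrow(grid), 0.155, 0.01), 0.05)
  bmi_mu <- log(mean_bmi) - bmi_sigma^2 / 2

  adult_height <- ifelse(male, 1.76, 1.62)
  height <- adult_height * (0.35 + 0.65 * stats::plogis((mid - 11) / 3))

  hazard <- 3e-4 + 6e-5 * exp(0.085 * mid) * ifelse(male, 1.3, 1.0)
  mortality <- 1 - exp(-hazard)

  yld <- 0.04 + 0.2 * stats::plogis((mid - 65) / 15)

  tibble::tibble(
    age_lo = grid$age_lo,
    sex = grid$sex,
    size = size,
    bmi_mu = bmi_mu,
    bmi_sigma = bmi_sigma,
    bmi_mu_se = 0.01,
    height_m = height,
    mortality = mortality,
    yld_rate = yld
  )
}

#' Simulate a disease table
#'
#' `n_diseases` anonymous obesity-related disease slots, each with annual
#' incidence, case fatality and remission rates by age group and sex, a
#' disability weight, a relative risk per 5 BMI units (all > 1) with a
#' log-scale standard error, and an annual treatment cost per prevalent case.
#' Incidence is zero below `adult_age` (adult-onset rule) and rises
#' exponentially with age; remission defaults to zero for every disease.
#'
#' @inheritParams simulate_products
#' @return A tibble with one row per disease x age group x sex and columns
#'   `disease`, `age_lo`, `sex`, `incidence`, `case_fatality`, `remission`,
#'   `disability_weight`, `rr_per_5bmi`, `rr_log_se`, `cost_per_case_year`,
#'   `min_age`.
#' @export
simulate_diseases <- function(cfg) {
  stopifnot(inherits(cfg, "fopl_sim_config"))
  set.seed(cfg$seed + 4L)
  nd <- cfg$n_diseases
  ages <- age_group_table(cfg)
  dis <- tibble::tibble(
    disease = sprintf("disease_%02d", seq_len(nd)),
    peak_inc = runif(nd, 5e-4, 4e-3),
    cf_base = runif(nd, 0.01, 0.06),
    disability_weight = runif(nd, 0.05, 0.35),
    rr_per_5bmi = exp(runif(nd, log(1.10), log(2.2))),
    rr_log_se = runif(nd, 0.02, 0.08),
    cost_per_case_year = runif(nd, 1000, 12000)
  )
  grid <- tidyr::expand_grid(
    disease = dis$disease,
    age_lo = ages$age_lo,
    sex = c("female", "male")
  ) |>
    dplyr::left_join(dis, by = "disease") |>
    dplyr::left_join(ages, by = "age_lo")
  mid <- grid$age_mid
  sexf <- ifelse(grid$sex == "male", 1.15, 1.0)
  adult <- mid >= cfg$adult_age
  grid$incidence <- ifelse(
    adult, pmin(grid$peak_inc * sexf * exp(0.04 * (mid - 50)), 0.08), 0
  )
  grid$case_fatality <- pmin(grid$cf_base * exp(0.02 * pmax(mid - 50, 0)), 0.4)
  grid$remission <- 0
  grid$min_age <- cfg$adult_age
  grid[, c("disease", "age_lo", "sex", "incidence", "case_fatality",
           "remission", "disability_weight", "rr_per_5bmi", "rr_log_se",
           "cost_per_case_year", "min_age")]
}

#' Intervention cost table
#'
#' Point estimates with elicitation ranges (2010 A$ millions) for the cost
#' items of a voluntary and a mandatory labelling scheme: recurrent industry
#' relabelling costs incurred once per labelling cycle, annual government
#' administration/monitoring costs, and (mandatory only) a one-off cost of
#' passing legislation. Industry and government items carry Pert uncertainty;
#' the legislation item a gamma. These are the published scheme costings the
#' model takes as inputs, not simulated quantities, so this generator is
#' deterministic.
#'
#' @param cfg A [sim_config()] (accepted for interface symmetry; unused).
#' @return A tibble with columns `item`, `scenario`, `point_m`, `min_m`,
#'   `max_m`, `schedule`, `family`.
#' @export
simulate_costs <- function(cfg = NULL) {
  tibble::tribble(
    ~item,          ~scenario,   ~point_m, ~min_m, ~max_m, ~schedule,   ~family,
    "industry",     "voluntary", 2.5,      1.2,    3.7,    "per_cycle", "pert",
    "government",   "voluntary", 1.2,      0.6,    1.8,    "annual",    "pert",
    "industry",     "mandatory", 37.0,     18.5,   55.4,   "per_cycle", "pert",
    "government",   "mandatory", 17.8,     8.9,    26.7,   "annual",    "pert",
    "legislation",  "mandatory", 1.1,      1.0,    1.2,    "one_off",   "gamma"
  )
}

#' Simulate the full five-table input set
#'
#' Convenience wrapper returning all five tables the pipeline consumes, each
#' generated from its own deterministic substream of `cfg$seed`.
#'
#' @inheritParams simulate_products
#' @return A list of class `fopl_inputs` with elements `products`,
#'   `consumption`, `population`, `diseases`, `costs` and the `config`.
#' @examples
#' inputs <- simulate_inputs(sim_config(seed = 7, n_products = 300))
#' names(inputs)
#' @export
simulate_inputs <- function(cfg) {
  structure(
    list(
      products = simulate_products(cfg),
      consumption = simulate_consumption(cfg),
      population = simulate_population(cfg),
      diseases = simulate_diseases(cfg),
      costs = simulate_costs(cfg),
      config = cfg
    ),
    class = "fopl_inputs"
  )
}

#' Reference synthetic fixture
#'
#' The fixed input set used throughout the package's regression tests and
#' examples: seed 20100614 with 4000 products. Smaller than the default
#' product universe so tests stay fast, but with the same statistical
#' structure.
#'
#' @param n_products Product count for the fixture.
#' @return A `fopl_inputs` list; see [simulate_inputs()].
#' @export
fixture_inputs <- function(n_products = 4000) {
  simulate_inputs(sim_config(seed = 20100614L, n_products = n_products))
}
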