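# a one-cohort population whose simulated life starts at `start`, with the
# age group arranged so the cohort midpoint is exactly `start`
one_cohort_population <- function(start = 50, mortality = 0.02, yld = 0.1,
                                  size = 1000) {
  tibble::tibble(
    age_lo = 0, sex = "female", size = size,
    bmi_mu = log(27), bmi_sigma = 0.15, bmi_mu_se = 0,
    height_m = 1.65, mortality = mortality, yld_rate = yld
  )
}

test_that("PIF closed-form and degenerate cases behave", {
  expect_identical(compute_pif(log(27), 0.15, 0, 1.3), 0)

  # (near) point mass at BMI 30, RR 2, reference 21, shift 5:
  # 1 - 2^(4/5) / 2^(9/5) = 1 - 2^-1 = 0.5
  expect_equal(compute_pif(log(30), 1e-9, 5, 2, ref_bmi = 21), 0.5,
               tolerance = 1e-6)

  expect_error(compute_pif(log(27), 0, 1, 1.3), class = "foplcea_invalid_input")
  expect_error(compute_pif(log(27), 0.15, 1, 0), class = "foplcea_invalid_input")
})

test_that("PIF grid integration agrees with a large Monte Carlo oracle", {
  got <- compute_pif(log(27), 0.15, 0.5, 1.3, ref_bmi = 21)
  mc <- pif_mc_oracle(log(27), 0.15, 0.5, 1.3, ref = 21, n = 1e6)
  expect_lt(abs(got - mc$pif), 3 * mc$se)
})

test_that("PIF sign follows the direction of the BMI shift", {
  for (delta in c(0.1, 0.5, 2)) {
    up <- compute_pif(log(27), 0.15, delta, 1.5)
    down <- compute_pif(log(27), 0.15, -delta, 1.5)
    expect_gt(up, 0)
    expect_lt(up, 1)
    expect_lt(down, 0)
  }
})

test_that("disease sub-model steps do the annual arithmetic and conserve people", {
  s0 <- list(healthy = 1000, cases = 0, dead = 0)
  expect_identical(disease_model_step(s0, 0, 0, 0), s0)

  s1 <- disease_model_step(s0, 0.1, 0, 0)
  expect_equal(s1$healthy, 900)
  expect_equal(s1$cases, 100)
  expect_equal(s1$dead, 0)

  set.seed(7)
  s <- list(healthy = 850, cases = 120, dead = 30)
  total <- s$healthy + s$cases + s$dead
  for (i in 1:50) {
    s <- disease_model_step(s, runif(1, 0, 0.3), runif(1, 0, 0.3),
                            runif(1, 0, 0.3))
  }
  expect_lt(abs(s$healthy + s$cases + s$dead - total), 1e-9)

  expect_error(disease_model_step(s0, 1.2, 0, 0),
               class = "foplcea_invalid_input")
})

test_that("disease-free survivorship matches the closed-form geometric sum", {
  m <- 0.02; r <- 0.03; yld <- 0.1; size <- 1000
  pop <- one_cohort_population(mortality = m, yld = yld, size = size)
  pair <- run_life_table(pop, diseases = NULL, flat_anthro(pop, 0),
                         pmslt_config(discount_rate = r))
  comp <- pair$comparator
  n_cycles <- sum(comp$person_years > 0)
  t <- seq_len(n_cycles) - 1
  expect_equal(sum(comp$person_years), size * sum((1 - m)^t),
               tolerance = 1e-12)
  expect_equal(sum(comp$halys),
               size * (1 - yld) * sum(((1 - m) / (1 + r))^t),
               tolerance = 1e-12)
})

test_that("one-cycle horizon with no discounting gives HALYs = survivors x (1 - YLD)", {
  pop <- one_cohort_population(mortality = 0.02, yld = 0.25, size = 500)
  pair <- run_life_table(pop, NULL, flat_anthro(pop, 0),
                         pmslt_config(discount_rate = 0, horizon_age = 1))
  expect_identical(sum(pair$comparator$halys), 500 * (1 - 0.25))
})

test_that("a null intervention reproduces the comparator bit for bit", {
  inputs <- test_fixture()
  pair <- run_life_table(inputs$population, inputs$diseases,
                         flat_anthro(inputs$population, 0))
  expect_identical(pair$comparator$halys, pair$intervention$halys)
  expect_identical(pair$comparator$prev, pair$intervention$prev)
  expect_identical(incremental_halys(pair), 0)
  expect_identical(compute_cost_offsets(pair), 0)
})

test_that("comparator runs are deterministic across repeated calls", {
  inputs <- test_fixture()
  p1 <- run_life_table(inputs$population, inputs$diseases,
                       flat_anthro(inputs$population, -0.1))
  p2 <- run_life_table(inputs$population, inputs$diseases,
                       flat_anthro(inputs$population, -0.1))
  expect_identical(p1$comparator$halys, p2$comparator$halys)
  expect_identical(p1$intervention$halys, p2$intervention$halys)
})

test_that("a BMI reduction with harmful RRs yields nonnegative health gains", {
  inputs <- test_fixture()
  pair <- run_life_table(inputs$population, inputs$diseases,
                         flat_anthro(inputs$population, -0.1))
  expect_gte(incremental_halys(pair), 0)
  expect_lt(compute_cost_offsets(pair), 0)

  # survivors nonincreasing within every cohort's active span
  for (arm in list(pair$comparator, pair$intervention)) {
    surv <- arm$survivors
    for (i in seq_len(nrow(surv))) {
      active <- which(surv[i, ] > 0)
      expect_true(all(diff(surv[i, active]) <= 1e-9))
    }
  }
  expect_true(all(pair$intervention$halys <= pair$intervention$person_years + 1e-9))
})

test_that("health gains scale near-linearly with the attributable fraction", {
  inputs <- test_fixture()
  eff <- scenario_effect(compute_category_effects(inputs$products))
  h <- purrr::map_dbl(c(1, 0.5), function(f) {
    a <- cohort_anthro_changes(apply_attributable_fraction(eff, f),
                               inputs$consumption, inputs$population)
    incremental_halys(run_life_table(inputs$population, inputs$diseases, a))
  })
  expect_gt(h[2] / h[1], 0.45)
  expect_lt(h[2] / h[1], 0.55)
})

test_that("mismatched cohort sets are rejected when pairing runs", {
  inputs <- test_fixture()
  pop2 <- inputs$population[inputs$population$age_lo < 50, ]
  a <- run_life_table(inputs$population, NULL,
                      flat_anthro(inputs$population, 0))
  b <- run_life_table(pop2, NULL, flat_anthro(pop2, 0))
  expect_error(incremental_halys(a$comparator, b$comparator),
               class = "foplcea_invalid_input")
})

test_that("tidy() exposes per-cohort per-cycle trajectories", {
  pop <- one_cohort_population()
  pair <- run_life_table(pop, NULL, flat_anthro(pop, 0))
  td <- tidy(pair$comparator)
  expect_true(all(c("age_lo", "sex", "cycle", "survivors",
                    "halys_discounted") %in% names(td)))
  expect_equal(nrow(td), 50)  # one age group [0,100): midpoint 50, 50 cycles
})
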