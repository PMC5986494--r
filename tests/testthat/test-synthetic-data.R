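test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_products = 0), class = "foplcea_invalid_input")
  expect_error(sim_config(uptake_target = 0), class = "foplcea_invalid_input")
  expect_error(sim_config(uptake_target = 1.5), class = "foplcea_invalid_input")
  expect_error(sim_config(age_breaks = c(0, 50, 40, 100)),
               class = "foplcea_invalid_input")
  expect_error(sim_config(age_breaks = c(0, 50, 99)),
               class = "foplcea_invalid_input")
})

test_that("product generator hits the target uptake and reformulation signal", {
  prods <- simulate_products(sim_config(seed = 1, n_products = 14986))
  expect_lt(abs(mean(prods$labelled) - 0.067), 0.005)

  all_lab <- simulate_products(sim_config(seed = 2, n_products = 300,
                                          uptake_target = 1))
  expect_true(all(all_lab$labelled))

  # no differential and no noise: both arms change by exactly the drift
  flat <- simulate_products(sim_config(seed = 3, n_products = 500,
                                       labelled_reform_mean = 0,
                                       ed_noise_sd = 0,
                                       secular_drift_mean = -2))
  change <- flat$ed_year1 - flat$ed_year0
  expect_equal(change, rep(-2, nrow(flat)))
})

test_that("labelled-minus-unlabelled change converges to the configured mean", {
  cfg <- sim_config(seed = 11, n_products = 50000)
  prods <- simulate_products(cfg)
  ch <- prods$ed_year1 - prods$ed_year0
  lab <- ch[prods$labelled]
  unlab <- ch[!prods$labelled]
  diff <- mean(lab) - mean(unlab)
  se <- sqrt(stats::var(lab) / length(lab) + stats::var(unlab) / length(unlab))
  expect_lt(abs(diff - cfg$labelled_reform_mean), 3 * se)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_products = 400)
  expect_identical(simulate_inputs(cfg), simulate_inputs(cfg))
})

test_that("population table satisfies its structural invariants", {
  pop <- simulate_population(sim_config(seed = 5, n_products = 10))
  mean_bmi <- exp(pop$bmi_mu + pop$bmi_sigma^2 / 2)
  expect_true(all(mean_bmi >= 14 & mean_bmi <= 40))
  expect_true(all(pop$size > 0))
  expect_true(all(pop$bmi_sigma > 0))
  expect_true(all(pop$height_m >= 0.5 & pop$height_m <= 2.1))
  expect_true(all(pop$mortality > 0 & pop$mortality < 1))
  expect_true(all(pop$yld_rate >= 0 & pop$yld_rate < 1))
  for (s in c("female", "male")) {
    old <- pop$mortality[pop$age_lo == 95 & pop$sex == s]
    mid <- pop$mortality[pop$age_lo == 50 & pop$sex == s]
    expect_gte(old, mid)
  }
})

test_that("disease table has adult-onset diseases with harmful relative risks", {
  cfg <- sim_config(seed = 6, n_products = 10, n_diseases = 9)
  dis <- simulate_diseases(cfg)
  expect_length(unique(dis$disease), 9L)
  expect_true(all(dis$rr_per_5bmi >= 1))
  expect_true(all(dis$incidence[dis$age_lo < 18] == 0))
  expect_true(all(dis$incidence >= 0 & dis$incidence < 1))
  expect_true(all(dis$case_fatality >= 0 & dis$case_fatality < 1))
  expect_true(all(dis$remission == 0))
  expect_true(all(dis$disability_weight > 0 & dis$disability_weight < 1))
  expect_true(all(dis$cost_per_case_year > 0))
})

test_that("consumption table is nonnegative and single-category sums are exact", {
  cons <- simulate_consumption(sim_config(seed = 7, n_products = 10))
  expect_true(all(cons$grams_day >= 0))

  one <- simulate_consumption(sim_config(seed = 8, n_products = 10,
                                         n_categories = 1))
  eff <- tibble::tibble(category = unique(one$category),
                        scenario = "voluntary", attributable_fraction = 1,
                        label_share = 1, delta_kj_per_g = -0.01)
  got <- weighted_intake_change(eff, one)
  expected <- one |>
    dplyr::group_by(age_lo, sex) |>
    dplyr::summarise(x = sum(-0.01 * grams_day), .groups = "drop")
  expect_equal(got$delta_kj_day, expected$x)
})
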