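test_that("difference-in-difference reproduces the reference category summaries", {
  ref <- reference_category_summary()
  eff <- compute_category_effects(products_from_summary(ref))
  eff <- eff[match(ref$category, eff$category), ]
  expect_equal(eff$mean_y0_labelled, ref$b_lab)
  expect_equal(eff$abs_change_labelled, ref$ch_lab, tolerance = 1e-10)
  # per-arm % cells: the reference baselines are printed to whole kJ, so
  # recomputed percentages can sit one rounding unit off the printed value
  expect_true(all(abs(eff$pct_change_labelled - ref$pct_lab) < 0.06))
  expect_true(all(abs(eff$pct_change_unlabelled - ref$pct_unlab) < 0.06))
  expect_equal(round(eff$pct_attributable, 1), ref$att)
})

test_that("equal percentage change in both arms gives a null DiD", {
  prods <- tibble::tibble(
    category = "x", labelled = c(TRUE, FALSE),
    ed_year0 = c(500, 1000), ed_year1 = c(500, 1000) * 0.98
  )
  eff <- compute_category_effects(prods)
  expect_equal(eff$pct_attributable, 0, tolerance = 1e-12)
})

test_that("absolute DiD is invariant to a constant shift of all arm means", {
  ref <- reference_category_summary()[1:4, ]
  base <- compute_category_effects(products_from_summary(ref))
  shifted_prods <- products_from_summary(ref)
  shifted_prods$ed_year0 <- shifted_prods$ed_year0 + 250
  shifted_prods$ed_year1 <- shifted_prods$ed_year1 + 250
  shifted <- compute_category_effects(shifted_prods)
  expect_equal(
    shifted$abs_change_labelled - shifted$abs_change_unlabelled,
    base$abs_change_labelled - base$abs_change_unlabelled,
    tolerance = 1e-9
  )
})

test_that("categories with an empty arm are flagged and excluded downstream", {
  prods <- tibble::tibble(
    category = c("full", "full", "empty_arm", "empty_arm"),
    labelled = c(TRUE, FALSE, FALSE, FALSE),
    ed_year0 = c(500, 600, 700, 800),
    ed_year1 = c(490, 595, 700, 805)
  )
  expect_warning(eff <- compute_category_effects(prods), "empty_arm")
  expect_true(is.na(eff$pct_attributable[eff$category == "empty_arm"]))
  expect_warning(se <- scenario_effect(eff), "empty_arm")
  expect_false("empty_arm" %in% se$category)
})

test_that("uptake estimates match Wald arithmetic and clip degenerate cases", {
  up <- estimate_uptake(n_labelled = 1004, n_total = 14986)
  expect_equal(round(100 * up$proportion, 1), 6.7)
  expect_equal(round(100 * up$ci_low, 1), 6.3)
  expect_equal(round(100 * up$ci_high, 1), 7.1)

  half <- estimate_uptake(n_labelled = 50, n_total = 100)
  expect_equal(round(100 * c(half$ci_low, half$ci_high), 1), c(40.2, 59.8))

  none <- estimate_uptake(n_labelled = 0, n_total = 250)
  expect_equal(c(none$proportion, none$ci_low, none$ci_high), c(0, 0, 0))

  expect_error(estimate_uptake(n_labelled = 0, n_total = 0),
               class = "foplcea_invalid_input")
  expect_true(all(c(up$ci_low <= up$proportion, up$proportion <= up$ci_high)))
})

test_that("paired test matches the brute-force formula to 1e-10", {
  known <- paired_energy_test(c(1, 2, 3), c(2, 4, 3))
  expect_equal(known$mean_diff, 1)
  expect_equal(known$t_stat, sqrt(3), tolerance = 1e-6)
  expect_equal(known$df, 2)
  expect_equal(known$p_value, 0.2254033, tolerance = 1e-6)

  set.seed(314)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    y0 <- stats::rnorm(n, 1000, 200)
    y1 <- y0 + stats::rnorm(n, -5, 20)
    got <- paired_energy_test(y0, y1)
    want <- paired_t_oracle(y0, y1)
    for (f in c("mean_diff", "t_stat", "p_value", "ci_low", "ci_high")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
    }
  }
})

test_that("degenerate paired differences are rejected", {
  expect_error(paired_energy_test(c(1, 2, 3), c(2, 3, 4)),
               class = "foplcea_degenerate_variance")
  expect_error(paired_energy_test(c(1, 2, 3), c(1, 2, 3)),
               class = "foplcea_degenerate_variance")
  expect_error(paired_energy_test(1, 1), class = "foplcea_invalid_input")
  expect_error(paired_energy_test(c(1, 2), c(1, 2, 3)),
               class = "foplcea_invalid_input")
})

test_that("mandatory scaling divides by uptake and round-trips exactly", {
  eff <- tibble::tibble(
    category = c("a", "b"), scenario = "voluntary",
    attributable_fraction = 1, label_share = c(0.10, 1.0),
    delta_kj_per_g = c(-0.020, -0.004)
  )
  class(eff) <- c("fopl_scenario_effect", class(eff))
  mand <- scale_to_mandatory(eff)
  expect_equal(mand$delta_kj_per_g, c(-0.20, -0.004))
  expect_equal(mand$scenario, rep("mandatory", 2))
  # multiplying uptake back recovers the voluntary change exactly
  expect_identical(mand$delta_kj_per_g * eff$label_share, eff$delta_kj_per_g)

  zero <- eff
  zero$delta_kj_per_g <- c(0, 0)
  expect_equal(scale_to_mandatory(zero)$delta_kj_per_g, c(0, 0))

  bad <- eff
  bad$label_share <- c(0, 1)
  expect_error(scale_to_mandatory(bad), class = "foplcea_undefined_scaling")
})

test_that("attributable-fraction rescaling is a clean scalar multiply", {
  eff <- tibble::tibble(
    category = "a", scenario = "voluntary", attributable_fraction = 1,
    label_share = 0.1, delta_kj_per_g = -0.10
  )
  expect_equal(apply_attributable_fraction(eff, 1)$delta_kj_per_g, -0.10)
  expect_equal(apply_attributable_fraction(eff, 0.3)$delta_kj_per_g, -0.03)
  expect_equal(apply_attributable_fraction(eff, 0)$delta_kj_per_g, 0)
  expect_error(apply_attributable_fraction(eff, 1.2),
               class = "foplcea_invalid_input")
})
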