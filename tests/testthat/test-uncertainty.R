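test_that("Pert draws match the (min + 4 mode + max)/6 mean at 1e5 draws", {
  set.seed(1)
  x <- rpert(1e5, 1.2, 2.5, 3.7)
  target <- (1.2 + 4 * 2.5 + 3.7) / 6
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - target), 3 * se)
  expect_true(all(x >= 1.2 & x <= 3.7))
  expect_equal(rpert(3, 2, 2, 2), c(2, 2, 2))
  expect_error(rpert(1, 3, 2, 1), class = "foplcea_invalid_input")
})

test_that("lognormal draws match exp(mu + sigma^2/2) and stay positive", {
  set.seed(2)
  x <- sample_parameter(list(family = "lognormal", meanlog = log(27),
                             sdlog = 0.15), 1e5)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - exp(log(27) + 0.15^2 / 2)), 3 * se)
  expect_true(all(x > 0))
})

test_that("degenerate distributions collapse to their point estimates", {
  expect_identical(sample_parameter(list(family = "normal", mean = 0, sd = 0), 5),
                   rep(0, 5))
  expect_identical(
    sample_parameter(list(family = "gamma", mean = 1.1, sd = 0), 2),
    c(1.1, 1.1)
  )
  expect_error(sample_parameter(list(family = "cauchy")),
               class = "foplcea_invalid_input")
  set.seed(3)
  g <- sample_parameter(list(family = "gamma", mean = 1.1, sd = 0.05), 1e4)
  expect_lt(abs(mean(g) - 1.1), 3 * sd(g) / sqrt(length(g)))
})

degenerate_fixture <- function() {
  inputs <- test_fixture()
  inputs$diseases$rr_log_se <- 0
  inputs$population$bmi_mu_se <- 0
  inputs$costs$min_m <- inputs$costs$point_m
  inputs$costs$max_m <- inputs$costs$point_m
  inputs
}

test_that("a fully degenerate PSA reproduces the deterministic pipeline", {
  inputs <- degenerate_fixture()
  psa <- run_psa(inputs, "voluntary", n_iter = 1, seed = 5, effect_cv = 0)
  expect_identical(psa$iterations$halys, psa$point$halys)
  expect_identical(psa$iterations$net_cost, psa$point$net_cost)
  expect_identical(psa$iterations$cost_offsets, psa$point$cost_offsets)
  expect_equal(psa$iterations$intervention_cost, psa$point$intervention_cost)
})

test_that("PSA results are reproducible under a fixed seed", {
  inputs <- test_fixture()
  a <- run_psa(inputs, "voluntary", n_iter = 8, seed = 17)
  b <- run_psa(inputs, "voluntary", n_iter = 8, seed = 17)
  expect_identical(a$iterations, b$iterations)
})

test_that("quadrant classification and shares follow the sign conventions", {
  it <- tibble::tibble(halys = c(1, -1, 1, -1, 0, 1),
                       net_cost = c(1, 1, -1, -1, 0, 0))
  expect_identical(ce_quadrant(it$halys, it$net_cost),
                   c("NE", "NW", "SE", "SW", "NE", "NE"))
  it$iter <- seq_len(nrow(it)); it$intervention_cost <- 0
  it$cost_offsets <- 0; it$icer <- it$net_cost / pmax(it$halys, 1e-9)
  s <- summarize_psa(it)
  expect_equal(sum(s$quadrant_shares), 1)

  se_only <- it[it$halys > 0 & it$net_cost < 0, ]
  se_only <- dplyr::bind_rows(se_only, se_only)
  expect_equal(summarize_psa(se_only)$quadrant_shares[["SE"]], 1)
})

test_that("quadrant shares match analytic orthant probabilities", {
  set.seed(8)
  n <- 2000
  it <- tibble::tibble(
    iter = 1:n,
    halys = rnorm(n, 1, 1), intervention_cost = 0, cost_offsets = 0,
    net_cost = rnorm(n, 0.5, 1)
  )
  it$icer <- it$net_cost / it$halys
  shares <- summarize_psa(it)$quadrant_shares
  p_e <- pnorm(1); p_n <- pnorm(0.5)
  expected <- c(NE = p_n * p_e, NW = p_n * (1 - p_e),
                SE = (1 - p_n) * p_e, SW = (1 - p_n) * (1 - p_e))
  for (q in names(expected)) {
    se <- sqrt(expected[[q]] * (1 - expected[[q]]) / n)
    expect_lt(abs(shares[[q]] - expected[[q]]), 3 * se)
  }
})

test_that("an SD-equals-mean effect gives the expected share of harmful draws", {
  # Normal(mu, mu) puts ~15.9% of mass below zero; a negative effect
  # multiplier reverses the BMI shift and flips the sign of the health gain
  psa <- run_psa(test_fixture(), "voluntary", n_iter = 200, seed = 31)
  frac_neg <- mean(psa$iterations$halys < 0, na.rm = TRUE)
  expect_gte(frac_neg, 0.10)
  expect_lte(frac_neg, 0.25)
  expect_identical(psa$n_failed, 0L)
})

test_that("the ICER interval lower bound flags dominance when cost-saving", {
  it <- tibble::tibble(
    iter = 1:100, halys = rep(100, 100), intervention_cost = 1e6,
    cost_offsets = seq(-2e6, 0, length.out = 100)
  )
  it$net_cost <- it$intervention_cost + it$cost_offsets
  it$icer <- it$net_cost / it$halys
  s <- summarize_psa(it)
  expect_true(s$icer$ui_low_dominant)
  expect_lt(s$icer$ui_low, 0)
})

test_that("CE-plane plots are well-formed ggplot objects", {
  psa <- run_psa(test_fixture(), "voluntary", n_iter = 5, seed = 2)
  p <- autoplot(psa)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_ce_plane(psa$iterations, wtp = 50000), "ggplot")
  b <- ggplot2::ggplot_build(p)
  expect_equal(nrow(b$data[[4]]), 5)  # one point layer row per iteration
})
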