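# Shared fixtures and oracles for the test suite.

# memoised reference input set (seed 20100614, 2000 products for speed)
.fixture_env <- new.env(parent = emptyenv())
test_fixture <- function() {
  if (is.null(.fixture_env$inputs)) {
    .fixture_env$inputs <- fixture_inputs(n_products = 2000)
  }
  .fixture_env$inputs
}

# Published category-level summaries of the Australian labelling scheme's
# 2013->2016 energy-density changes, used as a frozen regression target for
# the difference-in-difference arithmetic: arm baselines (kJ/100 g), absolute
# changes, the printed per-arm % changes and the printed attributable
# percentage points (all 1 dp).
reference_category_summary <- function() {
  tibble::tribble(
    ~category,       ~b_lab, ~b_unlab, ~ch_lab, ~ch_unlab, ~pct_lab, ~pct_unlab, ~att,
    "bakery",          1585,     1588,    -3.3,      -2.2,     -0.2,       -0.1,  -0.1,
    "cereals",         1521,     1370,    -7.9,     -10.4,     -0.5,       -0.8,   0.2,
    "confectionery",   2070,     1720,    19.7,       4.0,      1.0,        0.2,   0.7,
    "convenience",      444,      512,   -10.9,      -3.2,     -2.5,       -0.6,  -1.8,
    "dairy",            608,      933,   -13.4,      -0.9,     -2.2,       -0.1,  -2.1,
    "oils",            2724,     3066,   -18.1,       5.0,     -0.7,        0.2,  -0.8,
    "fish",             721,      693,    -1.0,       0.0,     -0.1,        0.0,  -0.1,
    "fruit_veg",        881,      998,    -0.6,       0.6,     -0.1,        0.1,  -0.1,
    "meat",             828,      878,    -4.1,       3.9,     -0.5,        0.4,  -0.9,
    "beverages",        213,      197,    -4.6,      -2.1,     -2.1,       -1.1,  -1.1,
    "sauces",          1046,      816,   -64.7,      -5.5,     -6.2,       -0.7,  -5.5,
    "snacks",          2013,     1883,    65.8,      -0.8,      3.3,        0.0,   3.3,
    "sugars",          1454,     1404,   -19.7,       1.6,     -1.4,        0.1,  -1.5
  )
}

# Build a product table whose arm means and changes exactly equal a category
# summary row (two products per arm at baseline +/- 1).
products_from_summary <- function(summary) {
  purrr::pmap_dfr(summary, function(category, b_lab, b_unlab, ch_lab,
                                    ch_unlab, ...) {
    tibble::tibble(
      product_id = paste0(category, "_", 1:4),
      category = category,
      labelled = c(TRUE, TRUE, FALSE, FALSE),
      ed_year0 = c(b_lab - 1, b_lab + 1, b_unlab - 1, b_unlab + 1),
      ed_year1 = ed_year0 + c(ch_lab, ch_lab, ch_unlab, ch_unlab)
    )
  })
}

# Independent brute-force paired t-test (textbook formulas), the oracle for
# paired_energy_test().
paired_t_oracle <- function(y0, y1) {
  d <- y1 - y0
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  tstat <- m / se
  list(
    mean_diff = m,
    t_stat = tstat,
    df = n - 1,
    p_value = 2 * stats::pt(-abs(tstat), n - 1),
    ci_low = m - stats::qt(0.975, n - 1) * se,
    ci_high = m + stats::qt(0.975, n - 1) * se
  )
}

# Monte Carlo potential-impact-fraction oracle with a delta-method standard
# error for the ratio of means.
pif_mc_oracle <- function(bmi_mu, bmi_sigma, delta, rr, ref = 21,
                          n = 1e6, seed = 42) {
  set.seed(seed)
  b <- stats::rlnorm(n, bmi_mu, bmi_sigma)
  x <- rr^(pmax(b - delta - ref, 0) / 5)  # shifted
  y <- rr^(pmax(b - ref, 0) / 5)          # baseline
  ratio <- mean(x) / mean(y)
  v <- ratio^2 * (stats::var(x) / mean(x)^2 + stats::var(y) / mean(y)^2 -
                    2 * stats::cov(x, y) / (mean(x) * mean(y))) / n
  list(pif = 1 - ratio, se = sqrt(v))
}

# an anthro table giving every cohort of a population the same BMI shift
flat_anthro <- function(population, delta_bmi) {
  tibble::tibble(
    age_lo = population$age_lo,
    sex = population$sex,
    delta_bmi = delta_bmi
  )
}
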