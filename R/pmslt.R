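#' Life-table engine configuration
#'
#' @param discount_rate Annual discount rate for HALYs and costs (base year =
#'   cycle 0).
#' @param horizon_age Simulate each cohort until this age (or extinction).
#' @param ref_bmi BMI (kg/m^2) at and below which relative risk is 1 — the
#'   theoretical-minimum-risk floor. Avoids crediting risk reductions to
#'   underweight.
#' @param pif_grid Number of grid points for the potential-impact-fraction
#'   integral.
#' @return A list of class `fopl_pmslt_config`.
#' @export
pmslt_config <- function(discount_rate = 0.03, horizon_age = 100,
                         ref_bmi = 21, pif_grid = 2001) {
  check_number(discount_rate, "discount_rate", 0, 1)
  check_number(horizon_age, "horizon_age", 1, 150)
  check_number(ref_bmi, "ref_bmi", 5, 50)
  structure(list(discount_rate = discount_rate, horizon_age = horizon_age,
                 ref_bmi = ref_bmi, pif_grid = check_count(pif_grid, "pif_grid", 3L)),
            class = "fopl_pmslt_config")
}

#' Potential impact fraction for a lognormal BMI distribution
#'
#' The proportional reduction in disease incidence caused by shifting the
#' whole BMI distribution down by `delta_bmi` units:
#' `PIF = 1 - E[RR(B - delta_bmi)] / E[RR(B)]`, with
#' `RR(b) = rr_per_5bmi^((b - ref_bmi)/5)` above the reference BMI and 1 at or
#' below it, and the expectation taken over `B ~ Lognormal(bmi_mu, bmi_sigma)`.
#' The expectation is evaluated by fixed-grid numerical integration over the
#' central 99.99% of the lognormal mass.
#'
#' Sign convention: `delta_bmi > 0` is a BMI *reduction* and yields a positive
#' PIF when `rr_per_5bmi > 1`; a negative `delta_bmi` (BMI increase) yields a
#' negative PIF (incidence rises).
#'
#' @param bmi_mu,bmi_sigma Log-scale mean and SD of the cohort BMI
#'   distribution (`bmi_sigma > 0`).
#' @param delta_bmi BMI reduction in kg/m^2 (positive = shift down).
#' @param rr_per_5bmi Relative risk per 5 BMI units (> 0).
#' @param ref_bmi Reference BMI below which RR = 1.
#' @param n_grid Number of integration points.
#' @return A single proportion (can be negative for a BMI increase).
#' @examples
#' compute_pif(log(27), 0.15, 0.5, 1.3)
#' @export
compute_pif <- function(bmi_mu, bmi_sigma, delta_bmi, rr_per_5bmi,
                        ref_bmi = 21, n_grid = 2001) {
  if (bmi_sigma <= 0) stop_invalid("`bmi_sigma` must be positive")
  if (any(rr_per_5bmi <= 0)) stop_invalid("`rr_per_5bmi` must be positive")
  if (delta_bmi == 0) return(0)
  pif_lognormal(bmi_mu, bmi_sigma, delta_bmi, rr_per_5bmi, ref_bmi, n_grid)[1]
}

# grid-integration core, vectorised over a vector of relative risks sharing
# one BMI distribution and one shift
pif_lognormal <- function(bmi_mu, bmi_sigma, delta_bmi, rr_vec, ref_bmi,
                          n_grid) {
  b <- seq(qlnorm(5e-5, bmi_mu, bmi_sigma),
           qlnorm(1 - 5e-5, bmi_mu, bmi_sigma), length.out = n_grid)
  w <- dlnorm(b, bmi_mu, bmi_sigma)
  w <- w / sum(w)
  e_base <- pmax(b - ref_bmi, 0) / 5
  e_shift <- pmax(b - delta_bmi - ref_bmi, 0) / 5
  out <- vapply(rr_vec, function(rr) {
    num <- sum(w * rr^e_shift)
    den <- sum(w * rr^e_base)
    if (!is.finite(num) || !is.finite(den) || den <= 0) {
      stop_model("non-finite integrand in PIF computation")
    }
    1 - num / den
  }, numeric(1))
  out
}

#' One annual step of a disease sub-model
#'
#' Difference equations for a healthy/cases/dead disease compartment model:
#' `healthy' = healthy - i*healthy + r*cases`,
#' `cases'   = cases + i*healthy - r*cases - f*cases`,
#' `dead'    = dead + f*cases`,
#' with `i` incidence, `f` case fatality and `r` remission, all annual rates
#' in `[0, 1)`. Person counts are conserved exactly. All arguments vectorise.
#'
#' @param state A list or data frame with numeric fields `healthy`, `cases`,
#'   `dead` (all nonnegative).
#' @param incidence,case_fatality,remission Annual rates in `[0, 1)`.
#' @return A list with updated `healthy`, `cases`, `dead`.
#' @examples
#' disease_model_step(list(healthy = 1000, cases = 0, dead = 0), 0.1, 0, 0)
#' @export
disease_model_step <- function(state, incidence, case_fatality, remission = 0) {
  rates <- c(incidence, case_fatality, remission)
  if (any(rates < 0 | rates >= 1)) stop_invalid("rates must lie in [0, 1)")
  if (any(state$healthy < 0 | state$cases < 0 | state$dead < 0)) {
    stop_invalid("state counts must be nonnegative")
  }
  new_healthy <- state$healthy - incidence * state$healthy + remission * state$cases
  new_cases <- state$cases + incidence * state$healthy -
    (remission + case_fatality) * state$cases
  new_dead <- state$dead + case_fatality * state$cases
  if (any(new_healthy < 0 | new_cases < 0 | new_dead < 0)) {
    stop_model("rate overflow: annual step produced a negative compartment")
  }
  list(healthy = new_healthy, cases = new_cases, dead = new_dead)
}

# ---- internal machinery ----------------------------------------------------

# third-dimension slice that never drops to a vector
slice3 <- function(a, t) {
  d <- dim(a)
  matrix(a[, , t], d[1], d[2])
}

# Precompute everything the per-cycle loop needs: per-cohort/per-cycle rate
# matrices and per-disease arrays, expanded from age-group tables to single
# years of age (rates held constant within a group).
pmslt_context <- function(population, diseases, config = pmslt_config()) {
  pop <- dplyr::arrange(population, .data$sex, .data$age_lo)
  lo <- sort(unique(pop$age_lo))
  breaks <- c(lo, config$horizon_age)
  width <- diff(breaks)
  mid <- floor(lo + width / 2)
  pop$start_age <- mid[match(pop$age_lo, lo)]
  C <- nrow(pop)
  horizon <- config$horizon_age
  n_cycles <- pmax(horizon - pop$start_age, 0L)
  T_max <- max(n_cycles)

  # age of cohort c at cycle t (1-based): start + t - 1
  age_at <- outer(pop$start_age, seq_len(T_max) - 1L, `+`)   # C x T
  grp_at <- matrix(findInterval(age_at, lo), C, T_max)       # group index
  active <- age_at < horizon                                  # logical C x T

  pop_key <- paste(pop$sex, pop$age_lo)
  lookup_pop <- function(col) {
    vals <- matrix(NA_real_, C, T_max)
    for (g in seq_along(lo)) {
      for (s in c("female", "male")) {
        row <- which(pop$sex == s & pop$age_lo == lo[g])
        if (!length(row)) next
        sel <- grp_at == g & matrix(pop$sex == s, C, T_max)
        vals[sel] <- pop[[col]][row]
      }
    }
    vals
  }
  mort <- lookup_pop("mortality")
  yld <- lookup_pop("yld_rate")

  dis_names <- if (!is.null(diseases) && nrow(diseases)) {
    sort(unique(diseases$disease))
  } else character()
  D <- length(dis_names)
  inc <- array(0, c(C, D, max(T_max, 1L)))
  cf <- array(0, c(C, D, max(T_max, 1L)))
  rem <- array(0, c(C, D, max(T_max, 1L)))
  dw <- numeric(D)
  cost <- numeric(D)
  rr <- numeric(D)
  rr_log_se <- numeric(D)
  if (D > 0) {
    for (d in seq_len(D)) {
      dd <- diseases[diseases$disease == dis_names[d], ]
      dw[d] <- dd$disability_weight[1]
      cost[d] <- dd$cost_per_case_year[1]
      rr[d] <- dd$rr_per_5bmi[1]
      rr_log_se[d] <- if ("rr_log_se" %in% names(dd)) dd$rr_log_se[1] else 0
      for (s in c("female", "male")) {
        ds <- dd[dd$sex == s, ]
        rows <- which(pop$sex == s)
        ord <- match(lo, ds$age_lo)
        for (t in seq_len(T_max)) {
          g <- grp_at[rows, t]
          inc[rows, d, t] <- ds$incidence[ord[g]]
          cf[rows, d, t] <- ds$case_fatality[ord[g]]
          rem[rows, d, t] <- ds$remission[ord[g]]
        }
      }
    }
    inc[is.na(inc)] <- 0
    cf[is.na(cf)] <- 0
    rem[is.na(rem)] <- 0
  }

  list(
    cohorts = pop, C = C, D = D, T_max = T_max, active = active,
    mort = mort, yld = yld, inc = inc, cf = cf, rem = rem,
    dw = dw, cost = cost, rr = rr, rr_log_se = rr_log_se,
    disease_names = dis_names, config = config
  )
}

# PIF matrix (cohort x disease) for a vector of per-cohort BMI reductions.
# reduction > 0 means BMI falls. rr may be overridden (PSA draws).
pif_matrix <- function(ctx, reduction, rr = NULL, bmi_mu = NULL) {
  rr <- rr %||% ctx$rr
  bmi_mu <- bmi_mu %||% ctx$cohorts$bmi_mu
  out <- matrix(0, ctx$C, ctx$D)
  if (ctx$D == 0) return(out)
  for (c_i in seq_len(ctx$C)) {
    if (reduction[c_i] == 0) next
    out[c_i, ] <- pif_lognormal(
      bmi_mu[c_i], ctx$cohorts$bmi_sigma[c_i], reduction[c_i], rr,
      ref_bmi = ctx$config$ref_bmi, n_grid = ctx$config$pif_grid
    )
  }
  out
}

# Simulate one arm. `ref` is the comparator arm result (NULL for the
# comparator itself); the intervention arm's all-cause mortality and YLD are
# the baseline rates plus the change in disease mortality / disability-
# weighted prevalence relative to the comparator.
run_arm <- function(ctx, pif = NULL, ref = NULL) {
  C <- ctx$C; D <- ctx$D; T_max <- ctx$T_max
  r <- ctx$config$discount_rate
  if (is.null(pif)) pif <- matrix(0, C, max(D, 1L))
  s <- ctx$cohorts$size
  h <- matrix(1, C, D)
  z <- matrix(0, C, D)
  surv <- matrix(0, C, T_max)
  py <- matrix(0, C, T_max)
  yldr <- matrix(0, C, T_max)
  haly <- matrix(0, C, T_max)
  prev <- array(0, c(C, max(D, 1L), T_max))
  for (t in seq_len(T_max)) {
    act <- ctx$active[, t]
    p <- matrix(0, C, D)
    if (D > 0) {
      alive <- h + z
      p <- ifelse(alive > 0, z / pmax(alive, .Machine$double.xmin), 0)
    }
    if (is.null(ref)) {
      q <- ctx$mort[, t]
      y <- ctx$yld[, t]
    } else if (D == 0) {
      q <- ctx$mort[, t]
      y <- ctx$yld[, t]
    } else {
      dprev <- p - matrix(slice3(ref$prev, t), C, D)
      dm <- rowSums(slice3(ctx$cf, t) * dprev)
      q <- ctx$mort[, t] + dm
      y <- ctx$yld[, t] + as.vector(dprev %*% ctx$dw)
      if (any(q[act] < 0 | q[act] >= 1) || any(y[act] < 0 | y[act] >= 1)) {
        stop_model("adjusted mortality or YLD left [0, 1); disease rates too large")
      }
    }
    surv[, t] <- s * act
    py[, t] <- s * act
    yldr[, t] <- ifelse(act, y, 0)
    haly[, t] <- s * (1 - y) * act * discount_factor(t - 1, r)
    if (D > 0) prev[, , t] <- p
    # advance to next cycle
    if (D > 0) {
      i_eff <- slice3(ctx$inc, t) * (1 - pif)
      f <- slice3(ctx$cf, t)
      rm <- slice3(ctx$rem, t)
      h_new <- h - i_eff * h + rm * z
      z_new <- z + i_eff * h - (rm + f) * z
      if (any(h_new < -1e-12) || any(z_new < -1e-12)) {
        stop_model("disease rates too large for an annual step")
      }
      h <- pmax(h_new, 0)
      z <- pmax(z_new, 0)
    }
    s <- ifelse(act, s * (1 - q), s)
  }
  structure(
    list(survivors = surv, person_years = py, yld = yldr, halys = haly,
         prev = prev, cohorts = ctx$cohorts, disease_names = ctx$disease_names,
         dw = ctx$dw, cost = ctx$cost, config = ctx$config),
    class = "fopl_lifetable"
  )
}

# ---- public entry points ---------------------------------------------------

#' Run the proportional multi-state life table
#'
#' Simulates every age/sex cohort of the baseline population year by year to
#' `horizon_age` under two arms: a comparator ("do nothing") with the observed
#' BMI distribution, and an intervention in which each cohort's BMI
#' distribution is shifted by its `delta_bmi`. The shift enters through the
#' potential impact fraction, which scales each disease's incidence; the
#' resulting change in disease prevalence feeds back into all-cause mortality
#' (via case fatality) and total morbidity (via disability weights).
#' Person-years and morbidity-adjusted, discounted HALYs are accumulated with
#' annual accounting and no half-cycle correction.
#'
#' @param population Population table (see [simulate_population()]).
#' @param diseases Disease table (see [simulate_diseases()]), or `NULL` for a
#'   disease-free life table.
#' @param anthro Cohort BMI changes (`age_lo`, `sex`, `delta_bmi`; negative =
#'   reduction), e.g. from [cohort_anthro_changes()].
#' @param config A [pmslt_config()].
#' @return A list of class `fopl_lifetable_pair` with elements `comparator`
#'   and `intervention` (each a `fopl_lifetable`), plus the context needed by
#'   the costing and uncertainty layers.
#' @examples
#' inputs <- fixture_inputs(800)
#' anthro <- tibble::tibble(age_lo = inputs$population$age_lo,
#'                          sex = inputs$population$sex, delta_bmi = -0.05)
#' pair <- run_life_table(inputs$population, inputs$diseases, anthro)
#' incremental_halys(pair)
#' @export
run_life_table <- function(population, diseases, anthro,
                           config = pmslt_config()) {
  ctx <- pmslt_context(population, diseases, config)
  key_pop <- paste(ctx$cohorts$age_lo, ctx$cohorts$sex)
  key_anthro <- paste(anthro$age_lo, anthro$sex)
  idx <- match(key_pop, key_anthro)
  if (any(is.na(idx))) stop_invalid("`anthro` must cover every population cohort")
  delta <- anthro$delta_bmi[idx]
  reduction <- -delta  # positive reduction lowers incidence
  comparator <- run_arm(ctx)
  intervention <- run_arm(ctx, pif = pif_matrix(ctx, reduction),
                          ref = comparator)
  structure(
    list(comparator = comparator, intervention = intervention,
         context = ctx, delta_bmi = delta),
    class = "fopl_lifetable_pair"
  )
}

check_paired <- function(comparator, intervention) {
  same <- identical(dim(comparator$halys), dim(intervention$halys)) &&
    identical(comparator$cohorts$age_lo, intervention$cohorts$age_lo) &&
    identical(comparator$cohorts$sex, intervention$cohorts$sex)
  if (!same) {
    stop_invalid("comparator and intervention runs have mismatched cohort sets")
  }
}

#' Incremental discounted HALYs
#'
#' Total discounted health-adjusted life years of the intervention arm minus
#' the comparator arm.
#'
#' @param comparator A `fopl_lifetable` run, or a `fopl_lifetable_pair` (in
#'   which case `intervention` is taken from it).
#' @param intervention A `fopl_lifetable` run.
#' @return A single number (HALYs).
#' @export
incremental_halys <- function(comparator, intervention = NULL) {
  if (inherits(comparator, "fopl_lifetable_pair")) {
    intervention <- comparator$intervention
    comparator <- comparator$comparator
  }
  check_paired(comparator, intervention)
  sum(intervention$halys) - sum(comparator$halys)
}

#' Tidy per-cohort per-cycle life-table trajectories
#'
#' @param x A `fopl_lifetable` run.
#' @param ... Unused.
#' @return A tibble with one row per cohort and cycle: `age_lo`, `sex`,
#'   `cycle`, `age`, `survivors`, `person_years`, `yld_rate`,
#'   `halys_discounted`.
#' @method tidy fopl_lifetable
#' @export
tidy.fopl_lifetable <- function(x, ...) {
  C <- nrow(x$survivors); T_max <- ncol(x$survivors)
  tibble::tibble(
    age_lo = rep(x$cohorts$age_lo, T_max),
    sex = rep(x$cohorts$sex, T_max),
    cycle = rep(seq_len(T_max) - 1L, each = C),
    age = rep(x$cohorts$start_age, T_max) + rep(seq_len(T_max) - 1L, each = C),
    survivors = as.vector(x$survivors),
    person_years = as.vector(x$person_years),
    yld_rate = as.vector(x$yld),
    halys_discounted = as.vector(x$halys)
  ) |>
    dplyr::filter(.data$age < x$config$horizon_age)
}

#' @export
print.fopl_lifetable_pair <- function(x, ...) {
  cat("<fopl_lifetable_pair>\n")
  cat(sprintf("  %d cohorts x up to %d annual cycles, %d diseases\n",
              x$context$C, x$context$T_max, x$context$D))
  cat(sprintf("  incremental HALYs (discounted %.1f%%): %.1f\n",
              100 * x$context$config$discount_rate, incremental_halys(x)))
  invisible(x)
}
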