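#' Modified-Pert random draws
#'
#' The Pert distribution is a Beta rescaled to `[min, max]` with shape
#' parameters `alpha = 1 + lambda (mode - min)/(max - min)` and
#' `beta = 1 + lambda (max - mode)/(max - min)`; its mean is
#' `(min + lambda * mode + max)/(lambda + 2)` — with the default `lambda = 4`,
#' the familiar `(min + 4 mode + max)/6`. Used for expert-elicited cost
#' ranges. A degenerate range (`min == max`) returns the point.
#'
#' @param n Number of draws.
#' @param min,mode,max Distribution support and mode (`min <= mode <= max`).
#' @param lambda Mode-concentration parameter (default 4).
#' @return Numeric vector of length `n`.
#' @examples
#' mean(rpert(1e4, 1.2, 2.5, 3.7))  # close to (1.2 + 4*2.5 + 3.7)/6
#' @export
rpert <- function(n, min, mode, max, lambda = 4) {
  if (!(min <= mode && mode <= max)) {
    stop_invalid("Pert parameters must satisfy min <= mode <= max")
  }
  if (min == max) return(rep(min, n))
  alpha <- 1 + lambda * (mode - min) / (max - min)
  beta <- 1 + lambda * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, alpha, beta)
}

#' Draw from a named uncertainty distribution
#'
#' One interface over the four distribution families used in the
#' probabilistic sensitivity analysis: `normal` (`mean`, `sd`; an effect
#' whose SD equals its mean is expressed here directly), `pert`
#' (`min`, `mode`, `max`), `lognormal` (`meanlog`, `sdlog`) and `gamma`
#' (`mean`, `sd`, converted to shape/scale). Zero-spread parameters give
#' degenerate draws at the point estimate.
#'
#' @param dist A list with a `family` element and the family's parameters.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @examples
#' sample_parameter(list(family = "normal", mean = 0, sd = 0), 3)
#' sample_parameter(list(family = "pert", min = 1.2, mode = 2.5, max = 3.7))
#' @export
sample_parameter <- function(dist, n = 1) {
  fam <- dist$family
  if (is.null(fam)) stop_invalid("`dist` needs a `family` element")
  switch(fam,
    normal = {
      if (is.null(dist$mean) || is.null(dist$sd) || dist$sd < 0) {
        stop_invalid("normal needs `mean` and nonnegative `sd`")
      }
      if (dist$sd == 0) rep(dist$mean, n) else rnorm(n, dist$mean, dist$sd)
    },
    pert = rpert(n, dist$min, dist$mode, dist$max),
    lognormal = {
      if (is.null(dist$meanlog) || is.null(dist$sdlog) || dist$sdlog < 0) {
        stop_invalid("lognormal needs `meanlog` and nonnegative `sdlog`")
      }
      if (dist$sdlog == 0) rep(exp(dist$meanlog), n)
      else rlnorm(n, dist$meanlog, dist$sdlog)
    },
    gamma = {
      if (is.null(dist$mean) || is.null(dist$sd) || dist$mean <= 0 ||
          dist$sd < 0) {
        stop_invalid("gamma needs positive `mean` and nonnegative `sd`")
      }
      if (dist$sd == 0) rep(dist$mean, n)
      else rgamma(n, shape = (dist$mean / dist$sd)^2,
                  scale = dist$sd^2 / dist$mean)
    },
    stop_invalid(paste("unknown distribution family:", fam))
  )
}

# one cost-table draw: Pert for ranged items, gamma (mean = point,
# sd = range/3.92) for items flagged gamma; degenerate ranges pass through
draw_costs <- function(costs) {
  drawn <- costs
  for (i in seq_len(nrow(costs))) {
    drawn$point_m[i] <- if (costs$family[i] == "gamma") {
      sample_parameter(list(family = "gamma", mean = costs$point_m[i],
                            sd = (costs$max_m[i] - costs$min_m[i]) / 3.92))
    } else {
      sample_parameter(list(family = "pert", min = costs$min_m[i],
                            mode = costs$point_m[i], max = costs$max_m[i]))
    }
  }
  drawn
}
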