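# Shared synthetic-world helpers for the test suite.

# A minimal one-risk world: 1 super-region, 1 region, 2 countries, one age
# group, one year. Small enough to regenerate inside replicate loops.
mini_world_spec <- function(seed, survey_noise = 1, coverage = 1) {
  world_spec(
    n_super_regions = 1, n_regions_per = 1, n_countries_per = 2,
    age_breaks = c(40, 60), sexes = c("male", "female"), years = 2013,
    risks = default_world_risks()[1, , drop = FALSE],
    rr_pairs = default_world_rr_pairs()[1, , drop = FALSE],
    coverage = c(fruits = coverage),
    survey_noise = survey_noise,
    seed = seed
  )
}

# Independent dense-grid trapezoid oracle for the PAF integral, written
# against the raw distribution functions rather than the package's
# quadrature path.
trapz_paf_oracle <- function(mean, cv, lrr, tmrel_value, direction,
                             n_grid = 1e6) {
  s2 <- log1p(cv^2)
  ml <- log(mean) - s2 / 2
  sl <- sqrt(s2)
  l <- qlnorm(0.001, ml, sl)
  u <- qlnorm(0.999, ml, sl)
  z <- plnorm(u, ml, sl) - plnorm(l, ml, sl)
  x <- seq(l, u, length.out = n_grid + 1)
  fx <- dlnorm(x, ml, sl) / z
  excess <- if (direction == "harmful_high") pmax(x - tmrel_value, 0)
            else pmax(tmrel_value - x, 0)
  integrand <- exp(lrr * excess) * fx
  h <- (u - l) / n_grid
  e_rr <- h * (sum(integrand) - (integrand[1] + integrand[n_grid + 1]) / 2)
  1 - 1 / e_rr
}

# Monte Carlo oracle for the same integral: raw lognormal sampling with
# rejection outside the integration support. Returns the PAF estimate and
# its delta-method standard error.
mc_paf_oracle <- function(mean, cv, lrr, tmrel_value, direction,
                          n = 1e6, seed = 1) {
  s2 <- log1p(cv^2)
  ml <- log(mean) - s2 / 2
  sl <- sqrt(s2)
  l <- qlnorm(0.001, ml, sl)
  u <- qlnorm(0.999, ml, sl)
  set.seed(seed)
  x <- rlnorm(n, ml, sl)
  x <- x[x >= l & x <= u]
  excess <- if (direction == "harmful_high") pmax(x - tmrel_value, 0)
            else pmax(tmrel_value - x, 0)
  rr <- exp(lrr * excess)
  e_rr <- mean(rr)
  se_e <- sd(rr) / sqrt(length(rr))
  list(paf = 1 - 1 / e_rr, se = se_e / e_rr^2)
}

# 20-point parameter grid used by the quadrature/MC agreement checks.
# TMREL sits below the mean so a harmful_high excess is present.
paf_test_grid <- function() {
  g <- expand.grid(
    mean = c(1, 2, 4, 8, 16),
    cv = c(0.2, 0.4),
    rr_per_unit = c(1.1, 1.3),
    stringsAsFactors = FALSE
  )
  g$tmrel <- 0.6 * g$mean
  g$direction <- "harmful_high"
  g
}
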