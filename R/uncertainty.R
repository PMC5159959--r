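# Monte Carlo uncertainty propagation. One root seed; each named parameter
# draws from its own deterministic child stream (derived from a hash of the
# parameter name), so draw vectors are reproducible, independent of the order
# parameters are declared in, and shared across strata/outcomes/periods
# whenever the same parameter name recurs within a run.

#' Describe a normally distributed uncertain parameter
#' @param mean,sd sampling mean and standard deviation (`sd = 0` gives a
#'   degenerate, certain parameter)
#' @return a `param_spec`
#' @export
param_normal <- function(mean, sd) {
  assert_that(sd >= 0, "sd must be non-negative")
  structure(list(law = "normal", mean = mean, sd = sd), class = "param_spec")
}

#' Describe a uniformly distributed uncertain parameter
#' @param lower,upper interval bounds (`lower <= upper`)
#' @return a `param_spec`
#' @export
param_uniform <- function(lower, upper) {
  assert_that(lower <= upper, "lower must not exceed upper")
  structure(list(law = "uniform", lower = lower, upper = upper),
            class = "param_spec")
}

#' Describe TMREL uncertainty: uniform on +/-20% of the optimal intake
#' @param optimal_mean mean optimal intake (> 0)
#' @return a `param_spec` uniform on `[0.8, 1.2] * optimal_mean`
#' @export
param_tmrel <- function(optimal_mean) {
  assert_that(optimal_mean > 0, "optimal_mean must be positive")
  param_uniform(0.8 * optimal_mean, 1.2 * optimal_mean)
}

#' Draw Monte Carlo realizations for a set of named parameters
#'
#' @param params named list of `param_spec`s ([param_normal()],
#'   [param_uniform()], [param_tmrel()])
#' @param n_draws number of draws per parameter (default 1000)
#' @param seed root seed; each parameter's stream seed is derived from it and
#'   the parameter name, so regeneration is bit-identical and insensitive to
#'   parameter ordering
#' @return named list of [draw_set()]s
#' @export
draw_parameters <- function(params, n_draws = 1000L, seed = 1L) {
  assert_that(is.numeric(n_draws) && n_draws >= 1, "n_draws must be positive")
  assert_that(length(params) == 0 || !is.null(names(params)),
              "params must be a named list")
  n_draws <- as.integer(n_draws)
  out <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    s <- stream_seed(seed, nm)
    vals <- with_preserved_rng(s, switch(p$law,
      normal = rnorm(n_draws, p$mean, p$sd),
      uniform = if (p$lower == p$upper) rep(p$lower, n_draws)
                else runif(n_draws, p$lower, p$upper),
      stop_validation(sprintf("unknown sampling law '%s'", p$law))
    ))
    draw_set(vals, seed = s)
  })
  setNames(out, names(params))
}

#' Summarize a draw set into a mean and 95% uncertainty interval
#'
#' Mean plus empirical 2.5th and 97.5th percentiles (linear interpolation).
#'
#' @param draws a [draw_set()] or numeric vector with at least 2 values
#' @return named numeric vector `c(mean, lower, upper)`
#' @export
summarize_ui <- function(draws) {
  v <- if (inherits(draws, "draw_set")) draws$values else draws
  if (length(v) == 0) stop_validation("cannot summarize an empty draw set")
  assert_that(length(v) >= 2, "uncertainty summary needs at least 2 draws")
  q <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(v), lower = q[1], upper = q[2])
}

#' Draw-level PAFs, vectorized over Monte Carlo draws
#'
#' For each draw d, rebuilds the exposure distribution at the drawn mean
#' (holding the coefficient of variation fixed), anchors the log-linear RR
#' curve at the drawn TMREL, and evaluates the PAF integral by fixed-node
#' Gauss-Legendre quadrature on that draw's support (0.001-0.999 quantiles).
#' Direct risks use `lrr_draws`; mediated risks supply `slope_draws` and
#' `mediator_lrr_draws` instead, composing the effective log-RR per exposure
#' unit as `slope * mediator_lrr`. All draw vectors are recycled to a common
#' length.
#'
#' @param mean_draws exposure mean per draw (values <= 0 are floored at a
#'   small positive epsilon)
#' @param cv fixed coefficient of variation of intake (sd = cv * mean);
#'   `cv = 0` treats each draw as a point mass
#' @param tmrel_draws TMREL per draw
#' @param lrr_draws log-RR per exposure unit per draw (direct risks)
#' @param slope_draws,mediator_lrr_draws mediated-risk components
#' @param direction `"harmful_high"` or `"harmful_low"`
#' @param cap_at_tmrel clamp RR at 1 beyond the TMREL
#' @param family exposure distribution family
#' @param nodes quadrature nodes (fixed; no adaptive refinement inside the
#'   draw loop)
#' @return numeric vector of PAFs, one per draw
#' @export
paf_draws <- function(mean_draws, cv, tmrel_draws,
                      lrr_draws = NULL, slope_draws = NULL,
                      mediator_lrr_draws = NULL,
                      direction = c("harmful_high", "harmful_low"),
                      cap_at_tmrel = TRUE,
                      family = c("lognormal", "gamma", "truncated_normal"),
                      nodes = 256L) {
  direction <- match.arg(direction)
  family <- match.arg(family)
  if (is.null(lrr_draws)) {
    assert_that(!is.null(slope_draws) && !is.null(mediator_lrr_draws),
                "supply lrr_draws, or slope_draws with mediator_lrr_draws")
    lrr_eff <- slope_draws * mediator_lrr_draws
  } else {
    lrr_eff <- lrr_draws
  }
  nd <- max(length(mean_draws), length(tmrel_draws), length(lrr_eff))
  mean_d <- pmax(rep_len(mean_draws, nd), 1e-9)
  tmrel_d <- rep_len(tmrel_draws, nd)
  lrr_d <- rep_len(lrr_eff, nd)
  if (cv == 0) {
    excess <- if (direction == "harmful_high") mean_d - tmrel_d
              else tmrel_d - mean_d
    if (cap_at_tmrel) excess <- pmax(excess, 0)
    e_rr <- exp(lrr_d * excess)
    return(1 - 1 / e_rr)
  }
  # Per-draw support bounds and renormalization, all vectorized (length nd).
  qlo <- 0.001
  qhi <- 0.999
  if (family == "lognormal") {
    s2 <- log1p(cv^2)
    sl <- sqrt(s2)
    ml <- log(mean_d) - s2 / 2
    l <- qlnorm(qlo, ml, sl); u <- qlnorm(qhi, ml, sl)
    z <- plnorm(u, ml, sl) - plnorm(l, ml, sl)
    dens <- function(x) dlnorm(x, ml, sl)
  } else if (family == "gamma") {
    shape <- 1 / cv^2
    rate <- shape / mean_d
    l <- qgamma(qlo, shape, rate); u <- qgamma(qhi, shape, rate)
    z <- pgamma(u, shape, rate) - pgamma(l, shape, rate)
    dens <- function(x) dgamma(x, shape, rate)
  } else {
    sd_d <- cv * mean_d
    l <- pmax(0, qnorm(qlo, mean_d, sd_d)); u <- qnorm(qhi, mean_d, sd_d)
    z <- pnorm(u, mean_d, sd_d) - pnorm(l, mean_d, sd_d)
    dens <- function(x) dnorm(x, mean_d, sd_d)
  }
  ref <- gl_reference(nodes)
  mid <- (l + u) / 2
  half <- (u - l) / 2
  # nd x nodes matrices; per-draw vectors recycle down columns.
  x <- outer(mid, rep(1, nodes)) + outer(half, ref$x)
  fx <- dens(x) / z
  excess <- if (direction == "harmful_high") x - tmrel_d else tmrel_d - x
  if (cap_at_tmrel) excess <- pmax(excess, 0)
  rr <- exp(lrr_d * excess)
  e_rr <- rowSums(rr * fx * outer(half, ref$w))
  1 - 1 / e_rr
}
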