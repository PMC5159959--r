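#' @importFrom stats dlnorm plnorm qlnorm dgamma pgamma qgamma dnorm pnorm qnorm
#'   lm coef vcov predict residuals weighted.mean rnorm runif quantile rlnorm
#'   setNames aggregate reformulate model.matrix complete.cases
NULL

RISK_DIRECTIONS <- c("harmful_low", "harmful_high")
MEDIATORS <- c("none", "sbp", "bmi")

#' Define a dietary risk factor
#'
#' A risk factor is "harmful_low" when disease risk rises as intake falls below
#' the optimum (e.g. diet low in fruits) and "harmful_high" when risk rises as
#' intake exceeds it (e.g. diet high in sodium). Risks whose effect on outcomes
#' is modeled through an intermediate factor carry a mediator tag: sodium via
#' systolic blood pressure (sbp), sugar-sweetened beverages via body mass
#' index (bmi).
#'
#' @param name risk name (unique within a registry)
#' @param direction `"harmful_low"` or `"harmful_high"`
#' @param exposure_unit free-text unit, e.g. `"g/day"`
#' @param mediator `"none"`, `"sbp"` or `"bmi"`
#' @param category optional grouping label (e.g. food / nutrient / fibre)
#' @return a `risk_factor` object
#' @export
risk_factor <- function(name, direction, exposure_unit = "g/day",
                        mediator = "none", category = NA_character_) {
  assert_that(is.character(name) && length(name) == 1 && nzchar(name),
              "risk name must be a non-empty string")
  if (!direction %in% RISK_DIRECTIONS) {
    stop_validation(sprintf("unknown risk direction '%s' (expected one of: %s)",
                            direction, paste(RISK_DIRECTIONS, collapse = ", ")))
  }
  if (!mediator %in% MEDIATORS) {
    stop_validation(sprintf("unknown mediator '%s' (expected one of: %s)",
                            mediator, paste(MEDIATORS, collapse = ", ")))
  }
  structure(list(name = name, direction = direction,
                 exposure_unit = exposure_unit, mediator = mediator,
                 category = category),
            class = "risk_factor")
}

#' Load a risk registry from configuration
#'
#' The registry is a list of named risks with direction, unit, optional
#' category and mediator. Accepts a YAML file path or an already-parsed list
#' with a top-level `risks` entry (or a bare list of risk entries).
#'
#' @param config path to a YAML file, or a list
#' @return data.frame of class `risk_registry` with columns
#'   `name`, `direction`, `exposure_unit`, `category`, `mediator`
#' @export
load_risk_registry <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_missing_input(sprintf("registry config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  entries <- config$risks %||% config
  if (length(entries) == 0) {
    return(empty_registry())
  }
  rows <- lapply(entries, function(e) {
    rf <- risk_factor(e$name,
                      direction = e$direction %||% stop_validation("risk entry missing direction"),
                      exposure_unit = e$exposure_unit %||% "g/day",
                      mediator = e$mediator %||% "none",
                      category = e$category %||% NA_character_)
    as.data.frame(unclass(rf), stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  dup <- reg$name[duplicated(reg$name)]
  if (length(dup)) {
    stop_validation(sprintf("duplicate risk name(s) in registry: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  class(reg) <- c("risk_registry", "data.frame")
  reg
}

empty_registry <- function() {
  reg <- data.frame(name = character(), direction = character(),
                    exposure_unit = character(), category = character(),
                    mediator = character(), stringsAsFactors = FALSE)
  class(reg) <- c("risk_registry", "data.frame")
  reg
}

#' Write a risk registry back to YAML
#'
#' Inverse of [load_risk_registry()]; the two round-trip losslessly.
#'
#' @param registry a `risk_registry`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_risk_registry <- function(registry, path) {
  risks <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    out <- list(name = r$name, direction = r$direction,
                exposure_unit = r$exposure_unit, mediator = r$mediator)
    if (!is.na(r$category)) out$category <- r$category
    out
  })
  yaml::write_yaml(list(risks = risks), path)
  invisible(path)
}

#' Build contiguous age groups from break points
#'
#' Groups are half-open `[lower, upper)` intervals that partition the modeled
#' age range without overlap.
#'
#' @param breaks increasing numeric vector of ages; group i is
#'   `[breaks[i], breaks[i+1])`
#' @return data.frame with columns `age_group`, `age_lower`, `age_upper`
#' @export
make_age_groups <- function(breaks) {
  assert_that(length(breaks) >= 2 && all(diff(breaks) > 0),
              "age breaks must be strictly increasing with at least two values")
  data.frame(age_group = paste0(breaks[-length(breaks)], "-", breaks[-1]),
             age_lower = breaks[-length(breaks)],
             age_upper = breaks[-1],
             stringsAsFactors = FALSE)
}

#' Validate that age groups partition a range
#'
#' @param age_groups data.frame as from [make_age_groups()]
#' @return TRUE invisibly; errors on gaps or overlaps
#' @export
validate_age_groups <- function(age_groups) {
  require_columns(age_groups, c("age_group", "age_lower", "age_upper"), "age groups")
  g <- age_groups[order(age_groups$age_lower), ]
  assert_that(all(g$age_upper > g$age_lower), "each age group needs upper > lower")
  if (nrow(g) > 1) {
    assert_that(all(abs(g$age_lower[-1] - g$age_upper[-nrow(g)]) < 1e-9),
                "age groups must partition the range without gaps or overlaps")
  }
  invisible(TRUE)
}

#' Parametric exposure distribution for one stratum
#'
#' Intake distributions are right-skewed; the default family is lognormal,
#' with gamma and truncated normal selectable per risk. The distribution is
#' parameterized by its (untruncated) mean and standard deviation in exposure
#' units and then restricted to an integration support `[l, u]`, defaulting to
#' the 0.001 and 0.999 quantiles, over which the density is renormalized.
#' `sd = 0` gives an explicit point mass at `mean` (degenerate stratum).
#'
#' @param mean mean intake (> 0), exposure units
#' @param sd standard deviation of intake (>= 0), exposure units
#' @param family `"lognormal"`, `"gamma"` or `"truncated_normal"`
#' @param support optional `c(l, u)` override, `0 <= l < u`
#' @return an `exposure_distribution` object
#' @export
exposure_distribution <- function(mean, sd,
                                  family = c("lognormal", "gamma", "truncated_normal"),
                                  support = NULL) {
  assert_that(is.numeric(mean) && length(mean) == 1 && is.finite(mean) && mean > 0,
              "exposure mean must be a positive finite scalar")
  assert_that(is.numeric(sd) && length(sd) == 1 && is.finite(sd) && sd >= 0,
              "exposure sd must be a non-negative finite scalar")
  if (sd == 0) {
    return(structure(list(family = "point", mean = mean, sd = 0,
                          support = c(mean, mean)),
                     class = "exposure_distribution"))
  }
  family <- match.arg(family)
  core <- switch(family,
    lognormal = {
      s2 <- log1p((sd / mean)^2)
      ml <- log(mean) - s2 / 2
      sl <- sqrt(s2)
      list(d = function(x) dlnorm(x, ml, sl),
           p = function(q) plnorm(q, ml, sl),
           q = function(p) qlnorm(p, ml, sl),
           pars = c(meanlog = ml, sdlog = sl))
    },
    gamma = {
      shape <- (mean / sd)^2
      rate <- mean / sd^2
      list(d = function(x) dgamma(x, shape, rate),
           p = function(q) pgamma(q, shape, rate),
           q = function(p) qgamma(p, shape, rate),
           pars = c(shape = shape, rate = rate))
    },
    truncated_normal = {
      list(d = function(x) dnorm(x, mean, sd),
           p = function(q) pnorm(q, mean, sd),
           q = function(p) qnorm(p, mean, sd),
           pars = c(mean = mean, sd = sd))
    })
  if (is.null(support)) {
    l <- core$q(0.001)
    u <- core$q(0.999)
    if (family == "truncated_normal") l <- max(0, l)
  } else {
    assert_that(length(support) == 2, "support must be c(l, u)")
    l <- support[1]
    u <- support[2]
  }
  assert_that(l >= 0 && u > l, "support must satisfy 0 <= l < u")
  pl <- core$p(l)
  z <- core$p(u) - pl
  assert_that(z > 0, "no probability mass on the stated support")
  structure(list(family = family, mean = mean, sd = sd,
                 support = c(l, u), core = core, pl = pl, norm = z),
            class = "exposure_distribution")
}

#' Density of a truncated exposure distribution
#'
#' Renormalized so the density integrates to 1 over the support.
#'
#' @param dist an [exposure_distribution()]
#' @param x exposure values
#' @return density values (0 outside the support)
#' @export
exposure_density <- function(dist, x) {
  assert_that(dist$family != "point", "density is undefined for a point mass")
  out <- numeric(length(x))
  inside <- x >= dist$support[1] & x <= dist$support[2]
  out[inside] <- dist$core$d(x[inside]) / dist$norm
  out
}

#' CDF of a truncated exposure distribution
#' @inheritParams exposure_density
#' @param q exposure values
#' @return probabilities in `[0, 1]`
#' @export
exposure_cdf <- function(dist, q) {
  if (dist$family == "point") return(as.numeric(q >= dist$mean))
  pmin(pmax((dist$core$p(q) - dist$pl) / dist$norm, 0), 1)
}

#' Quantile function of a truncated exposure distribution
#' @inheritParams exposure_density
#' @param p probabilities in `[0, 1]`
#' @return exposure values
#' @export
exposure_quantile <- function(dist, p) {
  assert_that(all(p >= 0 & p <= 1), "probabilities must lie in [0, 1]")
  if (dist$family == "point") return(rep(dist$mean, length(p)))
  dist$core$q(dist$pl + p * dist$norm)
}

#' Log-linear relative-risk curve for one diet-disease pair
#'
#' Relative risk is modeled as `RR(x) = exp(beta * excess(x))` where `beta` is
#' the log-RR per exposure unit and `excess(x)` is the signed distance of `x`
#' from the TMREL on the harmful side: `x - TMREL` for harmful_high risks,
#' `TMREL - x` for harmful_low risks. With `cap_at_tmrel` (the default) the
#' excess is clamped at 0 on the no-excess-risk side, so the curve plateaus at
#' RR = 1 beyond the TMREL. By construction `RR(TMREL) = 1` exactly.
#'
#' @param risk risk name (or a [risk_factor()], from which direction is taken)
#' @param outcome cause name
#' @param log_rr_per_unit log relative risk per exposure unit (>= 0 for a
#'   harmful effect)
#' @param se standard error of `log_rr_per_unit`
#' @param direction `"harmful_high"` or `"harmful_low"`; ignored when `risk`
#'   is a `risk_factor`
#' @param cap_at_tmrel clamp RR at 1 on the protective side of the TMREL
#' @param support exposure interval on which the curve is valid
#' @param age_group,sex optional applicability selectors
#' @return an `rr_curve` object
#' @export
rr_curve <- function(risk, outcome, log_rr_per_unit, se = 0,
                     direction = c("harmful_high", "harmful_low"),
                     cap_at_tmrel = TRUE, support = c(0, Inf),
                     age_group = NA_character_, sex = NA_character_) {
  if (inherits(risk, "risk_factor")) {
    direction <- risk$direction
    risk <- risk$name
  } else {
    direction <- match.arg(direction)
  }
  assert_that(is.finite(log_rr_per_unit), "log_rr_per_unit must be finite")
  assert_that(se >= 0, "se must be non-negative")
  structure(list(risk = risk, outcome = outcome,
                 log_rr_per_unit = log_rr_per_unit, se = se,
                 direction = direction, cap_at_tmrel = cap_at_tmrel,
                 support = support, age_group = age_group, sex = sex),
            class = "rr_curve")
}

#' Two-stage mediated relative-risk chain
#'
#' For risks whose outcome link is quantified indirectly (sodium through
#' systolic blood pressure, sugar-sweetened beverages through body mass
#' index): a unit of excess exposure shifts the mediator by `slope` mediator
#' units, and the mediator carries its own log-linear RR curve. The composed
#' curve is `RR(x) = RR_med(slope * excess(x))`, which equals 1 at the TMREL
#' and reduces to `exp(slope * beta_med * excess(x))`.
#'
#' @param mediator `"sbp"` or `"bmi"`
#' @param slope mediator units per exposure unit of excess
#' @param slope_se standard error of `slope`
#' @param mediator_rr an [rr_curve()] on the mediator-change scale (its
#'   `log_rr_per_unit` is per mediator unit; direction harmful_high,
#'   reference at zero mediator change)
#' @param direction direction of the *exposure* risk
#' @param cap_at_tmrel clamp at the TMREL as for direct curves
#' @return a `mediation_chain` object
#' @export
mediation_chain <- function(mediator = c("sbp", "bmi"), slope, slope_se = 0,
                            mediator_rr,
                            direction = c("harmful_high", "harmful_low"),
                            cap_at_tmrel = TRUE) {
  mediator <- match.arg(mediator)
  direction <- match.arg(direction)
  assert_that(inherits(mediator_rr, "rr_curve"),
              "mediator_rr must be an rr_curve on the mediator scale")
  structure(list(mediator = mediator, slope = slope, slope_se = slope_se,
                 mediator_rr = mediator_rr, direction = direction,
                 cap_at_tmrel = cap_at_tmrel,
                 risk = mediator_rr$risk, outcome = mediator_rr$outcome),
            class = "mediation_chain")
}

#' Theoretical minimum risk exposure level
#'
#' The exposure level associated with the lowest risk across outcomes, with a
#' uniform uncertainty band of 20% below and above the mean optimal intake.
#'
#' @param risk risk name
#' @param optimal_mean mean optimal intake, exposure units (> 0)
#' @return a `tmrel` object with `lower = 0.8 * optimal_mean`,
#'   `upper = 1.2 * optimal_mean`
#' @export
tmrel <- function(risk, optimal_mean) {
  assert_that(is.numeric(optimal_mean) && optimal_mean > 0,
              "optimal_mean must be positive")
  structure(list(risk = risk, optimal_mean = optimal_mean,
                 lower = 0.8 * optimal_mean, upper = 1.2 * optimal_mean),
            class = "tmrel")
}

#' Load a TMREL table from YAML configuration
#'
#' @param config YAML path or list with a `tmrel` entry mapping risk name to
#'   `optimal_mean` (and optionally `unit`)
#' @return data.frame with columns `risk`, `optimal_mean`, `lower`, `upper`,
#'   `unit`
#' @export
load_tmrel_table <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_missing_input(sprintf("TMREL config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  entries <- config$tmrel %||% config
  rows <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    m <- if (is.list(e)) e$optimal_mean else e
    tm <- tmrel(nm, m)
    data.frame(risk = nm, optimal_mean = m, lower = tm$lower, upper = tm$upper,
               unit = if (is.list(e)) e$unit %||% NA_character_ else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a TMREL table to YAML
#' @param tab data.frame as from [load_tmrel_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tmrel_table <- function(tab, path) {
  entries <- setNames(lapply(seq_len(nrow(tab)), function(i) {
    out <- list(optimal_mean = tab$optimal_mean[i])
    if (!is.na(tab$unit[i])) out$unit <- tab$unit[i]
    out
  }), tab$risk)
  yaml::write_yaml(list(tmrel = entries), path)
  invisible(path)
}

#' Validate a burden-envelope table
#'
#' Envelopes carry the total count of deaths/DALYs/YLLs/YLDs for one
#' cause-stratum together with its population; attributable burden is a PAF
#' share of the envelope.
#'
#' @param env data.frame with columns `outcome`, `metric`, `location`, `year`,
#'   `sex`, `age_group`, `count`, `population`
#' @return `env`, invisibly; errors on negative counts or non-positive
#'   populations
#' @export
validate_envelopes <- function(env) {
  require_columns(env, c("outcome", "metric", "location", "year", "sex",
                         "age_group", "count", "population"),
                  "burden envelope table")
  if (any(env$count < 0)) stop_validation("envelope counts must be non-negative")
  if (any(env$population <= 0)) stop_validation("envelope populations must be positive")
  assert_that(all(env$metric %in% c("deaths", "dalys", "ylls", "ylds")),
              "metric must be one of deaths, dalys, ylls, ylds")
  invisible(env)
}

#' Ordered Monte Carlo draw set
#'
#' @param values numeric vector of realizations
#' @param seed the stream seed that produced the values (for provenance)
#' @return a `draw_set` object with fields `values`, `n_draws`, `seed`
#' @export
draw_set <- function(values, seed = NA_integer_) {
  assert_that(is.numeric(values) && length(values) >= 1,
              "a draw set needs at least one numeric value")
  structure(list(values = as.numeric(values), n_draws = length(values),
                 seed = seed),
            class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  cat(sprintf("<draw_set: %d draws, seed %s, mean %.4g>\n",
              x$n_draws, format(x$seed), mean(x$values)))
  invisible(x)
}
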