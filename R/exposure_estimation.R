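# Exposure estimation: a simplified two-component cascade meta-regression.
# Component 1: inverse-variance-weighted mixed-effect-style regression of
# survey means on sex, age-group midpoint, year and covariates (global fit).
# Component 2: a cascade that walks the location hierarchy, restricting data
# to one stratum cell and one subtree at a time, carrying the parent estimate
# down as a prior that local data update by precision weighting.

HIERARCHY_LEVELS <- c("global", "super_region", "region", "country")

#' Read a location hierarchy from an edge-list file
#'
#' @param path tab-delimited file with columns `name`, `level`, `parent`
#'   (empty/NA parent for the global root)
#' @return validated hierarchy data.frame
#' @export
read_hierarchy <- function(path) {
  h <- read_tsv_file(path)
  require_columns(h, c("name", "level", "parent"), "hierarchy file")
  h$parent[h$parent %in% c("", "NA")] <- NA_character_
  validate_hierarchy(h)
}

#' Validate a four-level location hierarchy
#'
#' Checks: exactly one global root, known level labels, every non-global node
#' has a parent one level up, and every country reaches the root through a
#' region and super-region.
#'
#' @param h data.frame with columns `name`, `level`, `parent`
#' @return `h` invisibly (returned visibly for piping convenience)
#' @export
validate_hierarchy <- function(h) {
  require_columns(h, c("name", "level", "parent"), "hierarchy")
  assert_that(all(h$level %in% HIERARCHY_LEVELS),
              sprintf("hierarchy levels must be among: %s",
                      paste(HIERARCHY_LEVELS, collapse = ", ")))
  assert_that(sum(h$level == "global") == 1, "hierarchy needs exactly one global root")
  assert_that(!any(duplicated(h$name)), "hierarchy node names must be unique")
  root <- h$name[h$level == "global"]
  assert_that(is.na(h$parent[h$level == "global"]), "the global root has no parent")
  up <- setNames(h$parent, h$name)
  lev <- setNames(h$level, h$name)
  for (nm in h$name[h$level != "global"]) {
    p <- up[[nm]]
    assert_that(!is.na(p) && p %in% h$name,
                sprintf("node '%s' has no valid parent", nm))
    expected <- HIERARCHY_LEVELS[match(lev[[nm]], HIERARCHY_LEVELS) - 1]
    assert_that(lev[[p]] == expected,
                sprintf("parent of '%s' must be a %s node", nm, expected))
  }
  h
}

# Named chain of ancestors from a node up to the global root (inclusive).
hierarchy_ancestors <- function(h, name) {
  up <- setNames(h$parent, h$name)
  chain <- character()
  cur <- name
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- up[[cur]]
  }
  chain
}

# All country names in the subtree rooted at `node` (node itself if a country).
subtree_countries <- function(h, node) {
  countries <- h$name[h$level == "country"]
  countries[vapply(countries, function(cc) node %in% hierarchy_ancestors(h, cc),
                   logical(1))]
}

#' Inverse-variance-weighted global meta-regression of survey means
#'
#' Fits `reported_mean ~ sex + age_mid + year + covariates` by weighted least
#' squares with weights `1 / standard_error^2`. Terms with no variation in the
#' data are dropped automatically. Residual heterogeneity beyond the stated
#' sampling errors is estimated by a method-of-moments tau-squared and folded
#' into prediction uncertainty.
#'
#' @param data survey data.frame with columns `reported_mean`,
#'   `standard_error`, `sample_size`, `sex`, `age_lower`, `age_upper`, `year`
#'   plus any covariate columns
#' @param covariate_names character vector of covariate column names
#' @return an `exposure_fit` object (lm fit + tau2 + retained terms)
#' @export
fit_global <- function(data, covariate_names = character()) {
  if (is.null(data) || nrow(data) == 0) stop_validation("no survey data to fit")
  require_columns(data, c("reported_mean", "standard_error", "sample_size",
                          "sex", "age_lower", "age_upper", "year"),
                  "survey table")
  assert_that(nrow(data) >= 2, "global fit needs at least 2 data points")
  assert_that(all(data$standard_error > 0), "standard_error must be positive")
  assert_that(all(data$sample_size >= 1), "sample_size must be >= 1")
  data <- as.data.frame(data)
  data$age_mid <- (data$age_lower + data$age_upper) / 2
  candidates <- c("sex", "age_mid", "year", covariate_names)
  terms <- candidates[vapply(candidates, function(tt) {
    tt %in% names(data) && length(unique(data[[tt]])) > 1
  }, logical(1))]
  f <- if (length(terms)) reformulate(terms, response = "reported_mean")
       else reformulate("1", response = "reported_mean")
  w <- 1 / data$standard_error^2
  fit <- lm(f, data = data, weights = w)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_validation(sprintf("design matrix is rank deficient; collinear columns: %s",
                            paste(bad, collapse = ", ")))
  }
  r <- residuals(fit)
  tau2 <- max(0, weighted.mean(r^2 - data$standard_error^2, w))
  structure(list(fit = fit, terms = terms, covariate_names = covariate_names,
                 tau2 = tau2,
                 residual_var = if (length(r) > length(coef(fit)))
                   sum(w * r^2) / (length(r) - length(coef(fit))) else 0,
                 coefficients = coef(fit),
                 # degenerate all-identical data fit perfectly; the summary
                 # warning is expected there and the zero vcov is correct
                 vcov = suppressWarnings(vcov(fit))),
            class = "exposure_fit")
}

#' Predict a stratum mean from the global fit
#'
#' @param fit an [fit_global()] result
#' @param newdata data.frame with the stratum selectors (`sex`, `age_lower`,
#'   `age_upper`, `year`, covariates)
#' @return data.frame with `posterior_mean` and `posterior_sd` (prediction SE
#'   combined with between-location heterogeneity)
#' @export
predict_exposure <- function(fit, newdata) {
  newdata <- as.data.frame(newdata)
  if (!"age_mid" %in% names(newdata) &&
      all(c("age_lower", "age_upper") %in% names(newdata))) {
    newdata$age_mid <- (newdata$age_lower + newdata$age_upper) / 2
  }
  pr <- predict(fit$fit, newdata = newdata, se.fit = TRUE)
  data.frame(posterior_mean = as.numeric(pr$fit),
             posterior_sd = sqrt(as.numeric(pr$se.fit)^2 + fit$tau2))
}

#' One exposure estimate at one hierarchy node
#'
#' @param node node name
#' @param level node level
#' @param posterior_mean,posterior_sd estimate and its uncertainty
#' @param source_level the hierarchy level the information came from
#'   (ancestor-or-self of `level`)
#' @return an `exposure_estimate` object
#' @export
exposure_estimate <- function(node, level, posterior_mean, posterior_sd,
                              source_level = level) {
  assert_that(posterior_sd > 0, "posterior_sd must be positive")
  structure(list(node = node, level = level,
                 posterior_mean = posterior_mean, posterior_sd = posterior_sd,
                 source_level = source_level),
            class = "exposure_estimate")
}

#' One cascade step: update a parent estimate with local data
#'
#' The parent posterior acts as a prior with variance
#' `parent_sd^2 / prior_strength`; local survey means enter by inverse-variance
#' weighting. With no local data the child inherits the parent estimate
#' unchanged (and the parent's source level); with local data the posterior is
#' the precision-weighted combination and the source level is the child's own.
#'
#' @param parent an [exposure_estimate()] (or list with `posterior_mean`,
#'   `posterior_sd`, `level`, `source_level`)
#' @param local_data data.frame of survey rows for this subtree and stratum
#'   cell (may be empty) with columns `reported_mean`, `standard_error`
#' @param prior_strength positive multiplier on the prior precision
#' @param node,level identity of the child node (defaults: parent's)
#' @return an `exposure_estimate` for the child
#' @export
cascade_fit <- function(parent, local_data, prior_strength = 1,
                        node = parent$node, level = parent$level) {
  assert_that(prior_strength > 0, "prior_strength must be positive")
  assert_that(is.finite(parent$posterior_mean) && is.finite(parent$posterior_sd),
              "parent posterior must be finite")
  if (is.null(local_data) || nrow(local_data) == 0) {
    return(exposure_estimate(node, level,
                             parent$posterior_mean, parent$posterior_sd,
                             source_level = parent$source_level %||% parent$level))
  }
  assert_that(all(local_data$standard_error > 0), "standard_error must be positive")
  wi <- 1 / local_data$standard_error^2
  prior_prec <- prior_strength / parent$posterior_sd^2
  post_prec <- prior_prec + sum(wi)
  post_mean <- (prior_prec * parent$posterior_mean +
                  sum(wi * local_data$reported_mean)) / post_prec
  exposure_estimate(node, level, post_mean, sqrt(1 / post_prec),
                    source_level = level)
}

#' Run the full exposure cascade for one risk
#'
#' Fits the global meta-regression on all survey rows, predicts each stratum
#' cell at the global level, then walks super-regions, regions and countries,
#' at each node combining the parent estimate with the survey rows located in
#' that node's subtree for that cell.
#'
#' @param surveys survey table for one risk (see [fit_global()] for columns;
#'   `location` must name hierarchy nodes)
#' @param hierarchy validated hierarchy data.frame
#' @param strata data.frame of cells to estimate: columns `sex`, `age_group`,
#'   `age_lower`, `age_upper`, `year`
#' @param prior_strength cascade prior strength per step
#' @param covariate_names covariates passed to [fit_global()]
#' @return data.frame with one row per country x stratum: `location`, `level`,
#'   stratum columns, `posterior_mean`, `posterior_sd`, `source_level`
#' @export
estimate_exposure <- function(surveys, hierarchy, strata, prior_strength = 1,
                              covariate_names = character()) {
  validate_hierarchy(hierarchy)
  fit <- fit_global(surveys, covariate_names)
  countries <- hierarchy$name[hierarchy$level == "country"]
  # Pre-compute subtree country membership for every non-global node.
  nodes_by_level <- split(hierarchy$name, hierarchy$level)
  subtree <- lapply(setNames(hierarchy$name, hierarchy$name),
                    function(nn) subtree_countries(hierarchy, nn))
  up <- setNames(hierarchy$parent, hierarchy$name)
  out <- vector("list", nrow(strata) * length(countries))
  k <- 0L
  for (i in seq_len(nrow(strata))) {
    cell <- strata[i, , drop = FALSE]
    in_cell <- surveys$sex == cell$sex &
      surveys$year == cell$year &
      abs(surveys$age_lower - cell$age_lower) < 1e-9
    cell_rows <- surveys[in_cell, , drop = FALSE]
    g <- predict_exposure(fit, cell)
    global_est <- exposure_estimate(nodes_by_level$global, "global",
                                    g$posterior_mean, g$posterior_sd,
                                    source_level = "global")
    ests <- list()
    ests[[global_est$node]] <- global_est
    for (lv in c("super_region", "region", "country")) {
      for (nn in nodes_by_level[[lv]]) {
        parent_est <- ests[[up[[nn]]]]
        # The prior a child sees is the parent's estimate of *its own* mean
        # plus the between-location spread at the next level down; without
        # the tau2 inflation the same subtree data would be double-counted
        # through the parent posterior and swamp the local data.
        prior <- parent_est
        prior$posterior_sd <- sqrt(parent_est$posterior_sd^2 + fit$tau2)
        local <- cell_rows[cell_rows$location %in% subtree[[nn]], , drop = FALSE]
        ests[[nn]] <- cascade_fit(prior, local, prior_strength,
                                  node = nn, level = lv)
      }
    }
    for (cc in countries) {
      e <- ests[[cc]]
      k <- k + 1L
      out[[k]] <- data.frame(location = cc, level = "country",
                             sex = cell$sex, age_group = cell$age_group,
                             age_lower = cell$age_lower, age_upper = cell$age_upper,
                             year = cell$year,
                             posterior_mean = e$posterior_mean,
                             posterior_sd = e$posterior_sd,
                             source_level = e$source_level,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Energy-adjust intakes by the residual method
#'
#' Regresses intake on total energy and reports each observation's residual
#' plus the predicted intake at the target energy (2000 kcal/day), removing
#' between-person differences that merely reflect total consumption. With
#' fewer than two distinct energy values the intakes are returned unchanged
#' (adjustment is undefined and unnecessary); the operation is therefore
#' idempotent once all observations sit at the target energy.
#'
#' @param intake numeric intakes, exposure units
#' @param energy total energy intakes, kcal/day (> 0)
#' @param target_energy adjustment target, kcal/day
#' @return adjusted intakes, same length and order as `intake`
#' @export
energy_adjust <- function(intake, energy, target_energy = 2000) {
  assert_that(length(intake) == length(energy), "intake and energy lengths differ")
  if (any(!is.finite(energy) | energy <= 0)) {
    stop_validation("energy values must be positive")
  }
  if (length(unique(energy)) < 2) return(intake)
  fit <- lm(intake ~ energy)
  as.numeric(residuals(fit) +
               predict(fit, newdata = data.frame(energy = target_energy)))
}

#' Estimate the dietary-to-urinary sodium multiplier
#'
#' From surveys reporting both dietary and 24-h urinary sodium, estimates the
#' proportional conversion factor as the regression-through-origin slope of
#' urinary on dietary sodium.
#'
#' @param dietary dietary sodium values (> 0)
#' @param urinary paired urinary sodium values (> 0)
#' @return the multiplier (dimensionless ratio)
#' @export
estimate_sodium_multiplier <- function(dietary, urinary) {
  assert_that(length(dietary) == length(urinary) && length(dietary) >= 1,
              "need at least one dietary/urinary pair")
  if (any(dietary <= 0) || any(urinary <= 0)) {
    stop_validation("sodium values must be positive")
  }
  sum(dietary * urinary) / sum(dietary^2)
}

#' Convert dietary sodium to urinary-equivalent units
#' @param dietary dietary sodium values
#' @param multiplier ratio from [estimate_sodium_multiplier()]
#' @return urinary-equivalent sodium
#' @export
convert_sodium <- function(dietary, multiplier) multiplier * dietary

#' Data representativeness index
#'
#' The fraction of countries with at least one exposure datum for a risk.
#'
#' @param nodes_with_data character vector of locations carrying data
#' @param all_countries character vector of all country names (non-empty)
#' @return fraction in `[0, 1]`
#' @export
data_representativeness <- function(nodes_with_data, all_countries) {
  assert_that(length(all_countries) > 0, "all_countries must be non-empty")
  length(intersect(unique(nodes_with_data), unique(all_countries))) /
    length(unique(all_countries))
}
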