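# Burden accounting: attributable counts from envelopes and PAFs, crude and
# age-standardized rates per 100,000, proportions, and period changes.
# Internal arithmetic is never rounded; report formatting rounds counts and
# rates to integers and percentages to one decimal.

#' Total attributable burden per stratum
#'
#' Applies each outcome's PAF to its burden envelope and sums over outcomes
#' within each stratum and metric:
#' `total_ast = sum_o Burden_oast * PAF_oast`.
#' Envelope outcomes with no matching PAF contribute 0 with a warning.
#'
#' @param envelopes data.frame per [validate_envelopes()]
#' @param pafs data.frame with columns `outcome`, `location`, `year`, `sex`,
#'   `age_group`, `paf` (one row per outcome-stratum; typically the combined
#'   PAF across risks)
#' @return data.frame with one row per stratum and metric: stratum columns,
#'   `metric`, `count` (attributable), `envelope_count`, `population`, `rate`
#'   (attributable per 100,000)
#' @export
attributable_burden <- function(envelopes, pafs) {
  validate_envelopes(envelopes)
  require_columns(pafs, c("outcome", "location", "year", "sex", "age_group", "paf"),
                  "PAF table")
  key <- function(d) paste(d$outcome, d$location, d$year, d$sex, d$age_group,
                           sep = "\r")
  paf_map <- setNames(pafs$paf, key(pafs))
  ek <- key(envelopes)
  matched <- ek %in% names(paf_map)
  if (!all(matched)) {
    warning(sprintf("%d envelope rows have no matching PAF; treating PAF as 0",
                    sum(!matched)))
  }
  paf_o <- ifelse(matched, paf_map[ek], 0)
  env <- envelopes
  env$attr <- env$count * paf_o
  agg <- aggregate(cbind(count = attr, envelope_count = count) ~
                     location + year + sex + age_group + metric,
                   data = env, FUN = sum)
  pop <- aggregate(population ~ location + year + sex + age_group + metric,
                   data = env, FUN = max)
  out <- merge(agg, pop,
               by = c("location", "year", "sex", "age_group", "metric"))
  out$rate <- rate_per_100k(out$count, out$population)
  out
}

#' Rate per 100,000 population
#'
#' @param count event count (persons or person-years)
#' @param population population at risk (> 0)
#' @return `count / population * 100000`
#' @export
rate_per_100k <- function(count, population) {
  if (any(population <= 0)) stop_validation("population must be positive")
  count / population * 1e5
}

#' Standard population weights for age-standardization
#'
#' @param age_groups character vector of age-group labels
#' @param weights optional weights (default: equal); must be non-negative and
#'   are normalized to sum to 1
#' @return named numeric vector of weights
#' @export
standard_population <- function(age_groups, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(age_groups))
  assert_that(length(weights) == length(age_groups),
              "one weight per age group required")
  assert_that(all(weights >= 0) && sum(weights) > 0,
              "weights must be non-negative and not all zero")
  setNames(weights / sum(weights), age_groups)
}

#' Age-standardized rate
#'
#' Weights age-specific rates by a fixed standard population:
#' `sum_a w_a * rate_a`. Always lies between the minimum and maximum
#' age-specific rate.
#'
#' @param stratum_rates named numeric vector: age-group label -> rate
#' @param std standard population weights from [standard_population()]
#' @return the standardized rate (scalar)
#' @export
age_standardize <- function(stratum_rates, std) {
  missing <- setdiff(names(std), names(stratum_rates))
  if (length(missing)) {
    stop_validation(sprintf("missing rates for age group(s): %s",
                            paste(missing, collapse = ", ")))
  }
  sum(std * stratum_rates[names(std)])
}

#' Percentage change between two periods
#'
#' @param v_start baseline value (non-zero)
#' @param v_end final value
#' @return `100 * (v_end - v_start) / v_start` (unrounded; report formatting
#'   rounds to one decimal)
#' @export
pct_change <- function(v_start, v_end) {
  if (any(v_start == 0)) stop_validation("percentage change undefined for a zero baseline")
  100 * (v_end - v_start) / v_start
}

#' Proportion as a percentage
#'
#' @param part numerator (>= 0)
#' @param whole denominator (> 0)
#' @return `100 * part / whole` (unrounded)
#' @export
proportion <- function(part, whole) {
  if (any(whole <= 0)) stop_validation("proportion needs a positive denominator")
  if (any(part < 0)) stop_validation("proportion needs a non-negative numerator")
  100 * part / whole
}

#' Flag printed change cells inconsistent with their own start/end values
#'
#' Recomputes each row's percentage change from its (possibly rounded)
#' start/end columns and flags rows where the printed change differs from the
#' recomputed one by more than `tol` percentage points. Published tables
#' sometimes carry change cells computed from unrounded internals that cannot
#' be recovered from the printed neighbors; this makes such cells explicit
#' instead of chasing them.
#'
#' @param tab data.frame with columns `start`, `end`, `change_pct`
#' @param tol tolerance in percentage points (default 0.15, i.e. printed
#'   one-decimal rounding plus a safety margin)
#' @return `tab` with logical column `flagged` and numeric `recomputed_pct`
#' @export
flag_inconsistent_changes <- function(tab, tol = 0.15) {
  require_columns(tab, c("start", "end", "change_pct"), "change table")
  tab$recomputed_pct <- round(pct_change(tab$start, tab$end), 1)
  tab$flagged <- abs(tab$recomputed_pct - tab$change_pct) > tol
  tab
}
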