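# Synthetic-world generator: a complete, seeded bundle (hierarchy, true
# exposures, noisy surveys with sparse country coverage, RR and TMREL tables,
# multiplicative burden envelopes) with ground-truth PAFs computed by
# quadrature from the true parameters, so every pipeline stage can be tested
# against known truth without any external data.

#' Specify a synthetic world
#'
#' Defaults give a small world (2 super-regions x 2 regions x 3 countries,
#' 5 age groups, 2 sexes, the periods 1990 and 2013, 4 risks of which sodium
#' is mediated through systolic blood pressure, 3 outcomes) that runs through
#' the full pipeline in well under a minute. Country coverage fractions span
#' the sparse-to-dense range seen in practice (17% to 94% of countries with
#' any data). True country means are region means times lognormal noise;
#' surveys observe them with standard error `survey_noise * cv * mean /
#' sqrt(n)`.
#'
#' @param n_super_regions,n_regions_per,n_countries_per hierarchy shape
#' @param age_breaks age-group break points (years)
#' @param sexes sex labels
#' @param years modeled periods
#' @param risks risk definition table (see [default_world_risks()])
#' @param rr_pairs diet-disease RR table (see [default_world_rr_pairs()])
#' @param coverage named per-risk fraction of countries with survey data
#' @param survey_n survey sample size per stratum
#' @param survey_noise multiplier on survey sampling error (0 = noise-free)
#' @param intake_cv coefficient of variation of intake within a stratum
#' @param region_noise_sdlog,country_noise_sdlog lognormal sd of the
#'   multiplicative location effects
#' @param exposure_drift multiplicative drift in true exposure means per year
#' @param pop_growth population growth factor per year
#' @param rate_drift multiplicative drift in age-specific envelope rates per
#'   year
#' @param family exposure distribution family
#' @param prior_strength cascade prior strength
#' @param seed world seed (all randomness in the bundle derives from it)
#' @return a `world_spec` list
#' @export
world_spec <- function(n_super_regions = 2, n_regions_per = 2,
                       n_countries_per = 3,
                       age_breaks = c(25, 40, 50, 60, 70, 85),
                       sexes = c("male", "female"),
                       years = c(1990, 2013),
                       risks = default_world_risks(),
                       rr_pairs = default_world_rr_pairs(),
                       coverage = c(fruits = 0.75, vegetables = 0.94,
                                    sodium = 0.50, red_meat = 0.17),
                       survey_n = 200, survey_noise = 1,
                       intake_cv = 0.4,
                       region_noise_sdlog = 0.15, country_noise_sdlog = 0.10,
                       exposure_drift = 1.0, pop_growth = 1.03,
                       rate_drift = 0.99,
                       family = "lognormal", prior_strength = 1,
                       seed = 4242L) {
  assert_that(n_super_regions >= 1 && n_regions_per >= 1 && n_countries_per >= 1,
              "hierarchy counts must be at least 1")
  assert_that(all(coverage >= 0 & coverage <= 1), "coverage must lie in [0, 1]")
  assert_that(all(risks$name %in% names(coverage)),
              "every risk needs a coverage fraction")
  spec <- list(n_super_regions = n_super_regions,
               n_regions_per = n_regions_per,
               n_countries_per = n_countries_per,
               age_breaks = age_breaks, sexes = sexes, years = years,
               risks = risks, rr_pairs = rr_pairs, coverage = coverage,
               survey_n = survey_n, survey_noise = survey_noise,
               intake_cv = intake_cv,
               region_noise_sdlog = region_noise_sdlog,
               country_noise_sdlog = country_noise_sdlog,
               exposure_drift = exposure_drift, pop_growth = pop_growth,
               rate_drift = rate_drift, family = family,
               prior_strength = prior_strength, seed = as.integer(seed))
  class(spec) <- "world_spec"
  spec
}

#' Default synthetic risk set
#'
#' Four risks spanning both directions and the mediation mechanism: diets low
#' in fruits and vegetables (harmful_low), diet high in red meat
#' (harmful_high, direct) and diet high in sodium (harmful_high, mediated
#' through systolic blood pressure). Global means sit on the harmful side of
#' the TMREL, as for the corresponding real intakes.
#'
#' @return data.frame with columns `name`, `direction`, `exposure_unit`,
#'   `mediator`, `category`, `global_mean`, `tmrel_optimal`
#' @export
default_world_risks <- function() {
  data.frame(
    name = c("fruits", "vegetables", "sodium", "red_meat"),
    direction = c("harmful_low", "harmful_low", "harmful_high", "harmful_high"),
    exposure_unit = c("g/day", "g/day", "g/day urinary equivalent", "g/day"),
    mediator = c("none", "none", "sbp", "none"),
    category = c("food", "food", "nutrient", "food"),
    global_mean = c(80, 150, 4, 50),
    tmrel_optimal = c(250, 360, 2, 20),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic diet-disease RR table
#'
#' Log-linear effects per exposure unit with meta-analysis-style standard
#' errors. The sodium rows carry the two-stage components instead: an
#' exposure-to-SBP slope (mmHg per g/day) and the SBP log-RR per mmHg.
#'
#' @return data.frame with columns `risk`, `outcome`, `log_rr_per_unit`,
#'   `rr_se`, `slope`, `slope_se`, `mediator_log_rr_per_unit`, `mediator_se`
#' @export
default_world_rr_pairs <- function() {
  data.frame(
    risk = c("fruits", "fruits", "vegetables", "sodium", "red_meat", "red_meat"),
    outcome = c("cvd", "cancer", "cvd", "cvd", "cancer", "diabetes"),
    log_rr_per_unit = c(log(1.30) / 100, log(1.12) / 100, log(1.25) / 100,
                        NA, log(1.15) / 100, log(1.20) / 100),
    rr_se = c(log(1.30) / 400, log(1.12) / 400, log(1.25) / 400,
              NA, log(1.15) / 400, log(1.20) / 400),
    slope = c(NA, NA, NA, 1.5, NA, NA),
    slope_se = c(NA, NA, NA, 0.2, NA, NA),
    mediator_log_rr_per_unit = c(NA, NA, NA, log(1.25) / 10, NA, NA),
    mediator_se = c(NA, NA, NA, log(1.25) / 40, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Build an rr_curve or mediation_chain from one RR-table row.
build_curve <- function(rr_row, direction) {
  if (!is.na(rr_row$slope)) {
    med <- rr_curve(rr_row$risk, rr_row$outcome,
                    log_rr_per_unit = rr_row$mediator_log_rr_per_unit,
                    se = rr_row$mediator_se %||% 0,
                    direction = "harmful_high", cap_at_tmrel = FALSE,
                    support = c(-Inf, Inf))
    mediation_chain(mediator = "sbp", slope = rr_row$slope,
                    slope_se = rr_row$slope_se, mediator_rr = med,
                    direction = direction, cap_at_tmrel = TRUE)
  } else {
    rr_curve(rr_row$risk, rr_row$outcome,
             log_rr_per_unit = rr_row$log_rr_per_unit, se = rr_row$rr_se,
             direction = direction, cap_at_tmrel = TRUE)
  }
}

#' Generate a complete synthetic world
#'
#' Produces hierarchy, risk registry, true exposure table, noisy survey
#' table, RR table, TMREL table, burden envelopes and a ground-truth PAF
#' table (exact quadrature from the true parameters). Per-risk country
#' coverage matches the spec fraction to within rounding (one country).
#' Regeneration with the same spec (including its seed) is byte-identical.
#'
#' @param spec a [world_spec()]
#' @return a `cra_world` list of tables plus the spec
#' @export
generate_world <- function(spec) {
  assert_that(inherits(spec, "world_spec"), "spec must be a world_spec")
  n_countries <- spec$n_super_regions * spec$n_regions_per * spec$n_countries_per
  assert_that(n_countries >= 1, "world must contain at least one country")
  age_groups <- make_age_groups(spec$age_breaks)
  with_preserved_rng(spec$seed, {
    hierarchy <- build_hierarchy(spec)
    countries <- hierarchy$name[hierarchy$level == "country"]
    registry <- load_risk_registry(lapply(seq_len(nrow(spec$risks)), function(i) {
      r <- spec$risks[i, ]
      list(name = r$name, direction = r$direction,
           exposure_unit = r$exposure_unit, mediator = r$mediator,
           category = r$category)
    }))
    truth_exposure <- build_truth_exposure(spec, hierarchy, age_groups)
    surveys <- build_surveys(spec, truth_exposure, countries)
    tmrel_tab <- do.call(rbind, lapply(seq_len(nrow(spec$risks)), function(i) {
      r <- spec$risks[i, ]
      tm <- tmrel(r$name, r$tmrel_optimal)
      data.frame(risk = r$name, optimal_mean = r$tmrel_optimal,
                 lower = tm$lower, upper = tm$upper, unit = r$exposure_unit,
                 stringsAsFactors = FALSE)
    }))
    envelopes <- build_envelopes(spec, countries, age_groups)
    truth_paf <- build_truth_paf(spec, truth_exposure)
    structure(list(spec = spec, hierarchy = hierarchy, registry = registry,
                   age_groups = age_groups, surveys = surveys,
                   rr = spec$rr_pairs, tmrel = tmrel_tab,
                   envelopes = envelopes, truth_exposure = truth_exposure,
                   truth_paf = truth_paf),
              class = "cra_world")
  })
}

build_hierarchy <- function(spec) {
  rows <- list(data.frame(name = "global", level = "global",
                          parent = NA_character_, stringsAsFactors = FALSE))
  for (s in seq_len(spec$n_super_regions)) {
    sr <- sprintf("sr%d", s)
    rows[[length(rows) + 1]] <- data.frame(name = sr, level = "super_region",
                                           parent = "global",
                                           stringsAsFactors = FALSE)
    for (r in seq_len(spec$n_regions_per)) {
      rg <- sprintf("%s_r%d", sr, r)
      rows[[length(rows) + 1]] <- data.frame(name = rg, level = "region",
                                             parent = sr,
                                             stringsAsFactors = FALSE)
      for (cc in seq_len(spec$n_countries_per)) {
        rows[[length(rows) + 1]] <- data.frame(
          name = sprintf("%s_c%d", rg, cc), level = "country", parent = rg,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_hierarchy(do.call(rbind, rows))
}

# True stratum means: global mean x location effects (lognormal) x a mild
# deterministic age profile x sex ratio x multiplicative year drift.
build_truth_exposure <- function(spec, hierarchy, age_groups) {
  countries <- hierarchy$name[hierarchy$level == "country"]
  regions <- hierarchy$name[hierarchy$level == "region"]
  srs <- hierarchy$name[hierarchy$level == "super_region"]
  up <- setNames(hierarchy$parent, hierarchy$name)
  n_age <- nrow(age_groups)
  age_mult <- 1 + 0.05 * (seq_len(n_age) - (n_age + 1) / 2)
  sex_mult <- setNames(c(1.05, 0.95)[seq_along(spec$sexes)], spec$sexes)
  out <- list()
  for (i in seq_len(nrow(spec$risks))) {
    r <- spec$risks[i, ]
    sr_eff <- setNames(exp(rnorm(length(srs), 0, spec$region_noise_sdlog)), srs)
    rg_eff <- setNames(exp(rnorm(length(regions), 0, spec$region_noise_sdlog)),
                       regions)
    cc_eff <- setNames(exp(rnorm(length(countries), 0, spec$country_noise_sdlog)),
                       countries)
    for (cc in countries) {
      base <- r$global_mean * sr_eff[[up[[up[[cc]]]]]] * rg_eff[[up[[cc]]]] *
        cc_eff[[cc]]
      for (sx in spec$sexes) for (a in seq_len(n_age)) for (yr in spec$years) {
        m <- base * age_mult[a] * sex_mult[[sx]] *
          spec$exposure_drift^(yr - spec$years[1])
        out[[length(out) + 1]] <- data.frame(
          risk = r$name, location = cc, sex = sx,
          age_group = age_groups$age_group[a],
          age_lower = age_groups$age_lower[a],
          age_upper = age_groups$age_upper[a],
          year = yr, true_mean = m, true_sd = spec$intake_cv * m,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

build_surveys <- function(spec, truth_exposure, countries) {
  out <- list()
  for (rk in spec$risks$name) {
    k <- round(spec$coverage[[rk]] * length(countries))
    covered <- if (k == 0) character() else sample(countries, k)
    tr <- truth_exposure[truth_exposure$risk == rk &
                           truth_exposure$location %in% covered, , drop = FALSE]
    if (nrow(tr) == 0) next
    se_eff <- spec$survey_noise * spec$intake_cv * tr$true_mean /
      sqrt(spec$survey_n)
    reported <- pmax(tr$true_mean + rnorm(nrow(tr), 0, se_eff),
                     1e-6 * tr$true_mean)
    out[[length(out) + 1]] <- data.frame(
      risk = rk, location = tr$location, level = "country",
      sex = tr$sex, age_group = tr$age_group,
      age_lower = tr$age_lower, age_upper = tr$age_upper, year = tr$year,
      reported_mean = reported,
      standard_error = pmax(se_eff, 1e-8),
      sample_size = spec$survey_n, mean_energy = 2000,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    stop_validation("no surveys generated; raise coverage or country count")
  }
  do.call(rbind, out)
}

# Multiplicative envelopes: population pyramid x age-graded cause rates,
# with population growth and age-specific rate drift across years. Aggregate
# all-NCD and all-cause rows let reports compute proportions.
build_envelopes <- function(spec, countries, age_groups) {
  n_age <- nrow(age_groups)
  age_w <- 0.8^(seq_len(n_age) - 1)
  age_w <- age_w / sum(age_w)
  outcome_scale <- c(cvd = 40, cancer = 15, diabetes = 6)
  outcomes <- unique(spec$rr_pairs$outcome)
  assert_that(all(outcomes %in% names(outcome_scale)),
              "default envelope rates only cover cvd, cancer, diabetes")
  sex_mult <- setNames(c(1.1, 0.9)[seq_along(spec$sexes)], spec$sexes)
  rle <- pmax(90 - (age_groups$age_lower + age_groups$age_upper) / 2, 5)
  out <- list()
  for (ci in seq_along(countries)) {
    base_pop <- 2e6 * (1 + 0.2 * (ci - 1))
    for (sx in spec$sexes) for (a in seq_len(n_age)) for (yr in spec$years) {
      pop <- base_pop * age_w[a] * 0.5 * spec$pop_growth^(yr - spec$years[1])
      drift <- spec$rate_drift^(yr - spec$years[1])
      death_rates <- outcome_scale[outcomes] * 2^(a - 1) * sex_mult[[sx]] * drift
      deaths <- pop * death_rates / 1e5
      ylls <- deaths * rle[a]
      ylds <- ylls * 0.08
      dalys <- ylls + ylds
      counts <- rbind(deaths = deaths, ylls = ylls, ylds = ylds, dalys = dalys)
      for (metric in rownames(counts)) {
        spec_counts <- counts[metric, ]
        ncd_total <- sum(spec_counts) / 0.6
        all_cause <- ncd_total / 0.35
        out[[length(out) + 1]] <- data.frame(
          outcome = c(outcomes, "all_ncd", "all_cause"),
          group = c(rep("specific", length(outcomes)), "all_ncd", "all_cause"),
          metric = metric, location = countries[ci], year = yr, sex = sx,
          age_group = age_groups$age_group[a],
          count = c(unname(spec_counts), ncd_total, all_cause),
          population = pop, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

build_truth_paf <- function(spec, truth_exposure) {
  out <- list()
  for (j in seq_len(nrow(spec$rr_pairs))) {
    rr_row <- spec$rr_pairs[j, ]
    risk_def <- spec$risks[spec$risks$name == rr_row$risk, ]
    curve <- build_curve(rr_row, risk_def$direction)
    tm <- risk_def$tmrel_optimal
    tr <- truth_exposure[truth_exposure$risk == rr_row$risk, , drop = FALSE]
    paf <- vapply(seq_len(nrow(tr)), function(i) {
      d <- exposure_distribution(tr$true_mean[i], tr$true_sd[i],
                                 family = spec$family)
      compute_paf(d, curve, tm, nodes = 256L, refine = FALSE)
    }, numeric(1))
    out[[length(out) + 1]] <- data.frame(
      risk = rr_row$risk, outcome = rr_row$outcome,
      location = tr$location, sex = tr$sex, age_group = tr$age_group,
      year = tr$year, true_paf = paf, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a two-period world with an exposure trend
#'
#' Convenience wrapper: sets the multiplicative per-year drift in true
#' exposure means and regenerates. Period-2 true means equal period-1 means
#' times `exposure_trend^(years apart)`; population growth and rate drift act
#' on the envelopes, so worlds where attributable counts rise while crude
#' rates fall are directly constructible.
#'
#' @param spec a [world_spec()] with two years
#' @param exposure_trend multiplicative drift per year
#' @return a `cra_world`
#' @export
generate_two_period_world <- function(spec, exposure_trend = 1.0) {
  assert_that(length(spec$years) == 2, "spec must contain exactly two years")
  spec$exposure_drift <- exposure_trend
  generate_world(spec)
}

#' Write a world bundle to a directory of delimited-text files
#'
#' Files: `hierarchy.tsv`, `risk_registry.yaml`, `surveys.tsv`,
#' `relative_risks.tsv`, `tmrel.yaml`, `envelopes.tsv`,
#' `truth_exposure.tsv`, `truth_paf.tsv`, `config.yaml`, and a
#' `manifest.tsv` with per-file MD5 checksums and row counts.
#'
#' @param world a `cra_world`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_file(world$hierarchy, p("hierarchy.tsv"))
  write_risk_registry(world$registry, p("risk_registry.yaml"))
  write_tsv_file(world$surveys, p("surveys.tsv"))
  write_tsv_file(world$rr, p("relative_risks.tsv"))
  write_tmrel_table(world$tmrel, p("tmrel.yaml"))
  write_tsv_file(world$envelopes, p("envelopes.tsv"))
  write_tsv_file(world$truth_exposure, p("truth_exposure.tsv"))
  write_tsv_file(world$truth_paf, p("truth_paf.tsv"))
  cfg <- world$spec
  cfg$risks <- NULL
  cfg$rr_pairs <- NULL
  cfg$coverage <- as.list(cfg$coverage)
  class(cfg) <- NULL
  yaml::write_yaml(c(cfg, list(risk_table = "risk_registry.yaml")), p("config.yaml"))
  write_tsv_file(risks_table_for_io(world), p("risk_params.tsv"))
  files <- c("hierarchy.tsv", "risk_registry.yaml", "surveys.tsv",
             "relative_risks.tsv", "tmrel.yaml", "envelopes.tsv",
             "truth_exposure.tsv", "truth_paf.tsv", "config.yaml",
             "risk_params.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  write_tsv_file(manifest, p("manifest.tsv"))
  invisible(dir)
}

# risk parameter table for serialization (global means, TMRELs, coverage).
risks_table_for_io <- function(world) {
  r <- world$spec$risks
  r$coverage <- unname(world$spec$coverage[r$name])
  r
}

#' Read a world bundle from a directory
#'
#' Inverse of [write_world()]; verifies the manifest checksums.
#'
#' @param dir bundle directory
#' @return a `cra_world`
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("hierarchy.tsv", "surveys.tsv", "relative_risks.tsv",
              "envelopes.tsv", "config.yaml")) {
    if (!file.exists(p(f))) stop_missing_input(sprintf("bundle file missing: %s", p(f)))
  }
  if (file.exists(p("manifest.tsv"))) {
    manifest <- read_tsv_file(p("manifest.tsv"))
    now <- unname(tools::md5sum(file.path(dir, manifest$file)))
    bad <- manifest$file[!is.na(now) & now != manifest$md5]
    if (length(bad)) {
      warning(sprintf("bundle files changed since manifest: %s",
                      paste(bad, collapse = ", ")))
    }
  }
  cfg <- yaml::read_yaml(p("config.yaml"))
  risk_params <- read_tsv_file(p("risk_params.tsv"))
  spec <- world_spec(
    n_super_regions = cfg$n_super_regions, n_regions_per = cfg$n_regions_per,
    n_countries_per = cfg$n_countries_per,
    age_breaks = unlist(cfg$age_breaks), sexes = unlist(cfg$sexes),
    years = unlist(cfg$years),
    risks = risk_params[, c("name", "direction", "exposure_unit", "mediator",
                            "category", "global_mean", "tmrel_optimal")],
    rr_pairs = read_tsv_file(p("relative_risks.tsv")),
    coverage = setNames(risk_params$coverage, risk_params$name),
    survey_n = cfg$survey_n, survey_noise = cfg$survey_noise,
    intake_cv = cfg$intake_cv,
    region_noise_sdlog = cfg$region_noise_sdlog,
    country_noise_sdlog = cfg$country_noise_sdlog,
    exposure_drift = cfg$exposure_drift, pop_growth = cfg$pop_growth,
    rate_drift = cfg$rate_drift, family = cfg$family,
    prior_strength = cfg$prior_strength, seed = cfg$seed)
  structure(list(spec = spec,
                 hierarchy = validate_hierarchy(read_tsv_file(p("hierarchy.tsv"))),
                 registry = load_risk_registry(p("risk_registry.yaml")),
                 age_groups = make_age_groups(unlist(cfg$age_breaks)),
                 surveys = read_tsv_file(p("surveys.tsv")),
                 rr = read_tsv_file(p("relative_risks.tsv")),
                 tmrel = load_tmrel_table(p("tmrel.yaml")),
                 envelopes = read_tsv_file(p("envelopes.tsv")),
                 truth_exposure = read_tsv_file(p("truth_exposure.tsv")),
                 truth_paf = read_tsv_file(p("truth_paf.tsv"))),
            class = "cra_world")
}
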