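test_that("same seed gives a byte-identical bundle", {
  spec <- world_spec(seed = 777)
  d1 <- file.path(tempdir(), "w1"); d2 <- file.path(tempdir(), "w2")
  write_world(generate_world(spec), d1)
  write_world(generate_world(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("bundles round-trip through disk", {
  w <- generate_world(world_spec(seed = 31))
  dir <- file.path(tempdir(), "roundtrip")
  write_world(w, dir)
  w2 <- read_world(dir)
  expect_equal(w2$hierarchy, w$hierarchy)
  expect_equal(w2$registry, w$registry)
  expect_equal(w2$surveys$reported_mean, w$surveys$reported_mean,
               tolerance = 1e-12)
  expect_equal(w2$truth_paf$true_paf, w$truth_paf$true_paf, tolerance = 1e-12)
  expect_equal(w2$spec$coverage, w$spec$coverage)
  # a second write of the re-read bundle reproduces the files byte for byte
  dir2 <- file.path(tempdir(), "roundtrip2")
  write_world(w2, dir2)
  for (f in setdiff(list.files(dir), "manifest.tsv")) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)), label = f)
  }
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("per-risk country coverage matches the spec fraction", {
  w <- generate_world(world_spec(seed = 5))
  countries <- w$hierarchy$name[w$hierarchy$level == "country"]
  for (rk in names(w$spec$coverage)) {
    have <- unique(w$surveys$location[w$surveys$risk == rk])
    expect_lte(abs(length(have) - w$spec$coverage[[rk]] * length(countries)), 1)
  }
  # sparse risk: >= 80% of countries carry no data for it
  red <- unique(w$surveys$location[w$surveys$risk == "red_meat"])
  expect_gte(mean(!countries %in% red), 0.8)
})

test_that("the noise-free full-coverage world recovers truth through the pipeline", {
  spec <- world_spec(survey_noise = 0,
                     coverage = c(fruits = 1, vegetables = 1, sodium = 1,
                                  red_meat = 1),
                     seed = 11)
  w <- generate_world(spec)
  res <- run_pipeline(w, seed = 1, n_draws = 2)
  est <- merge(res$exposures, w$truth_exposure,
               by = c("risk", "location", "sex", "age_group", "year"))
  expect_lt(max(abs(est$posterior_mean - est$true_mean) / est$true_mean), 1e-6)
  paf <- merge(res$paf_table, w$truth_paf,
               by = c("risk", "outcome", "location", "sex", "age_group",
                      "year"))
  expect_equal(nrow(paf), nrow(w$truth_paf))
  expect_lt(max(abs(paf$paf_point - paf$true_paf)), 1e-6)
})

test_that("ground-truth PAFs are reproducible from the true-parameter table", {
  w <- generate_world(world_spec(seed = 23))
  idx <- seq(1, nrow(w$truth_paf), by = 97)
  for (i in idx) {
    row <- w$truth_paf[i, ]
    tr <- w$truth_exposure[w$truth_exposure$risk == row$risk &
                             w$truth_exposure$location == row$location &
                             w$truth_exposure$sex == row$sex &
                             w$truth_exposure$age_group == row$age_group &
                             w$truth_exposure$year == row$year, ]
    rr_row <- w$rr[w$rr$risk == row$risk & w$rr$outcome == row$outcome, ]
    direction <- w$spec$risks$direction[w$spec$risks$name == row$risk]
    lrr <- if (!is.na(rr_row$slope)) {
      rr_row$slope * rr_row$mediator_log_rr_per_unit
    } else rr_row$log_rr_per_unit
    tm <- w$tmrel$optimal_mean[w$tmrel$risk == row$risk]
    again <- paf_draws(tr$true_mean, w$spec$intake_cv, tm, lrr_draws = lrr,
                       direction = direction)
    expect_lt(abs(again - row$true_paf), 1e-10)
  }
})

test_that("survey error shrinks exposure RMSE as sample size grows", {
  rmse_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      spec <- world_spec(survey_n = n, seed = s,
                         coverage = c(fruits = 1, vegetables = 1, sodium = 1,
                                      red_meat = 1))
      w <- generate_world(spec)
      m <- merge(w$surveys, w$truth_exposure,
                 by = c("risk", "location", "sex", "age_group", "year"))
      sqrt(mean((m$reported_mean - m$true_mean)^2 / m$true_mean^2))
    }, numeric(1))
  }
  seeds <- 100 + 1:10
  expect_true(all(rmse_at(1000, seeds) < rmse_at(50, seeds)))
})

test_that("two-period worlds express trends as specified", {
  # no drift, no growth: every true change is zero
  flat_spec <- world_spec(pop_growth = 1, rate_drift = 1, survey_noise = 0,
                          seed = 17)
  flat <- generate_two_period_world(flat_spec, exposure_trend = 1.0)
  tp <- reshape(flat$truth_paf, idvar = c("risk", "outcome", "location",
                                          "sex", "age_group"),
                timevar = "year", direction = "wide")
  expect_equal(tp$true_paf.1990, tp$true_paf.2013, tolerance = 1e-12)
  env <- aggregate(count ~ metric + year, flat$envelopes, sum)
  e90 <- env$count[env$year == 1990]
  expect_equal(env$count[env$year == 2013], e90, tolerance = 1e-12)
  # drift shifts period-2 means by drift^(years apart)
  drift <- generate_two_period_world(world_spec(seed = 17),
                                     exposure_trend = 1.01)
  te <- reshape(drift$truth_exposure,
                idvar = c("risk", "location", "sex", "age_group"),
                timevar = "year", direction = "wide")
  expect_equal(te$true_mean.2013 / te$true_mean.1990,
               rep(1.01^23, nrow(te)), tolerance = 1e-12)
})

test_that("infeasible world specs are rejected", {
  expect_error(world_spec(n_countries_per = 0), "at least 1")
  expect_error(world_spec(coverage = c(fruits = 2, vegetables = 1,
                                       sodium = 1, red_meat = 1)),
               "\\[0, 1\\]")
  expect_error(world_spec(risks = default_world_risks(),
                          coverage = c(fruits = 1)), "coverage")
})
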