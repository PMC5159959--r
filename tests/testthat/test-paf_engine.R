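test_that("direct RR evaluation matches closed forms", {
  cv <- rr_curve("sodium", "cvd", log_rr_per_unit = log(1.25) / 10,
                 direction = "harmful_high")
  expect_identical(evaluate_rr(cv, 5, tmrel_value = 5), 1)
  expect_equal(evaluate_rr(cv, 15, tmrel_value = 5), 1.25)
  # harmful_low risk plateaus at 1 above the TMREL when capped
  fruit <- rr_curve("fruits", "cvd", log_rr_per_unit = log(1.3) / 100,
                    direction = "harmful_low")
  expect_equal(evaluate_rr(fruit, c(250, 300, 400), tmrel_value = 250),
               c(1, 1, 1))
  expect_equal(evaluate_rr(fruit, 150, tmrel_value = 250), 1.3)
  expect_error(evaluate_rr(fruit, -5, tmrel_value = 250), "support")
})

test_that("mediated RR composes slope and mediator effect", {
  med <- rr_curve("sodium", "cvd", log_rr_per_unit = log(1.25) / 10,
                  direction = "harmful_high", cap_at_tmrel = FALSE,
                  support = c(-Inf, Inf))
  chain <- mediation_chain("sbp", slope = 2, mediator_rr = med,
                           direction = "harmful_high")
  expect_identical(compose_mediated_rr(chain, 3, tmrel_value = 3), 1)
  # 2 mmHg per g/day, RR 1.25 per 10 mmHg, 1 g/day excess -> 1.25^(2/10)
  expect_equal(compose_mediated_rr(chain, 4, tmrel_value = 3), 1.25^0.2,
               tolerance = 1e-12)
  # zero slope: RR identically 1
  flat <- mediation_chain("sbp", slope = 0, mediator_rr = med,
                          direction = "harmful_high")
  expect_equal(compose_mediated_rr(flat, c(0, 3, 10), tmrel_value = 3),
               c(1, 1, 1))
  # uncapped chains are log-linear: RR(+d) * RR(-d) = 1
  uncapped <- mediation_chain("sbp", slope = 2, mediator_rr = med,
                              direction = "harmful_high",
                              cap_at_tmrel = FALSE)
  d <- 1.7
  expect_equal(compose_mediated_rr(uncapped, 3 + d, 3) *
                 compose_mediated_rr(uncapped, 3 - d, 3), 1,
               tolerance = 1e-12)
})

test_that("PAF vanishes with no excess risk", {
  curve <- rr_curve("r", "o", log_rr_per_unit = log(1.3),
                    direction = "harmful_high")
  # all exposure mass at the TMREL
  pt <- exposure_distribution(1.0, 0)
  expect_equal(compute_paf(pt, curve, tmrel_value = 1.0), 0)
  # flat RR curve
  flat <- rr_curve("r", "o", log_rr_per_unit = 0, direction = "harmful_high")
  d <- exposure_distribution(2.0, 0.8)
  expect_equal(compute_paf(d, flat, tmrel_value = 1.0), 0)
})

test_that("quadrature PAF matches a dense trapezoid oracle", {
  d <- exposure_distribution(2.0, 0.5, family = "lognormal")
  curve <- rr_curve("r", "o", log_rr_per_unit = log(1.3),
                    direction = "harmful_high")
  got <- compute_paf(d, curve, tmrel_value = 1.0)
  want <- trapz_paf_oracle(2.0, 0.25, log(1.3), 1.0, "harmful_high")
  expect_lt(abs(got - want), 1e-6)
})

test_that("PAF is monotone under upward exposure shifts for harmful_high", {
  curve <- rr_curve("r", "o", log_rr_per_unit = log(1.2),
                    direction = "harmful_high")
  pafs <- vapply(seq(1, 3, by = 0.25), function(m) {
    compute_paf(exposure_distribution(m, 0.4 * m), curve, tmrel_value = 1.0)
  }, numeric(1))
  expect_true(all(diff(pafs) >= -1e-12))
})

test_that("PAF is invariant to rescaling exposure units", {
  for (sc in c(10, 0.01)) {
    a <- compute_paf(exposure_distribution(2, 0.8),
                     rr_curve("r", "o", log(1.3), direction = "harmful_high"),
                     tmrel_value = 1)
    b <- compute_paf(exposure_distribution(2 * sc, 0.8 * sc),
                     rr_curve("r", "o", log(1.3) / sc,
                              direction = "harmful_high"),
                     tmrel_value = sc)
    expect_lt(abs(a - b), 1e-10)
  }
})

test_that("capped curves keep the PAF inside [0, 1)", {
  g <- paf_test_grid()
  for (i in seq_len(nrow(g))) {
    d <- exposure_distribution(g$mean[i], g$cv[i] * g$mean[i])
    curve <- rr_curve("r", "o", log(g$rr_per_unit[i]),
                      direction = g$direction[i])
    p <- compute_paf(d, curve, tmrel_value = g$tmrel[i], refine = FALSE)
    expect_gte(p, 0)
    expect_lt(p, 1)
  }
})

test_that("mediated and direct curves integrate identically when slopes align", {
  # slope * mediator log-RR equals the direct per-unit log-RR
  d <- exposure_distribution(4, 1.6)
  med <- rr_curve("sodium", "cvd", log_rr_per_unit = log(1.25) / 10,
                  direction = "harmful_high", cap_at_tmrel = FALSE,
                  support = c(-Inf, Inf))
  chain <- mediation_chain("sbp", slope = 1.5, mediator_rr = med,
                           direction = "harmful_high")
  direct <- rr_curve("sodium", "cvd",
                     log_rr_per_unit = 1.5 * log(1.25) / 10,
                     direction = "harmful_high")
  expect_equal(compute_paf(d, chain, tmrel_value = 2),
               compute_paf(d, direct, tmrel_value = 2), tolerance = 1e-12)
})

test_that("multi-risk combination uses the multiplicative complement", {
  expect_equal(combine_pafs(0.3), 0.3)
  expect_equal(combine_pafs(c(0.2, 0.3)), 0.44)
  expect_equal(combine_pafs(rep(0, 10)), 0)
  expect_message(expect_equal(combine_pafs(c(0.5, 1)), 1), "degenerate")
  expect_error(combine_pafs(c(0.2, 1.1)), "exceed")
  # bounds: never above the sum, never below the max
  set.seed(21)
  for (r in 1:20) {
    p <- runif(4, 0, 0.5)
    cp <- combine_pafs(p)
    expect_lte(cp, min(1, sum(p)) + 1e-12)
    expect_gte(cp, max(p) - 1e-12)
  }
})
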