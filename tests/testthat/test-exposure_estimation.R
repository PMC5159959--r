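make_survey_df <- function(n, beta = NULL, seed = 1) {
  # Survey rows with a known covariate effect; SEs vary so weighting matters.
  set.seed(seed)
  df <- data.frame(
    location = sample(paste0("c", 1:5), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_lower = 40, age_upper = 60,
    year = sample(c(1990, 2013), n, replace = TRUE),
    sdi = runif(n, 0, 1),
    standard_error = runif(n, 0.5, 2),
    sample_size = 100
  )
  mu <- 50 + 5 * (df$sex == "male") + 0.1 * (df$year - 1990)
  if (!is.null(beta)) mu <- mu + beta * df$sdi
  df$reported_mean <- rnorm(n, mu, df$standard_error)
  df
}

test_that("global fit matches an independent WLS solve and recovers the truth", {
  beta_true <- 12
  df <- make_survey_df(200, beta = beta_true, seed = 42)
  fit <- fit_global(df, covariate_names = "sdi")
  # independent weighted-least-squares computation on the same design
  X <- cbind(1, df$sex == "male", (df$age_lower + df$age_upper) / 2,
             df$year, df$sdi)
  X <- X[, apply(X, 2, function(cc) length(unique(cc)) > 1) | seq_len(5) == 1]
  W <- diag(1 / df$standard_error^2)
  bhat <- solve(t(X) %*% W %*% X, t(X) %*% W %*% df$reported_mean)
  est <- fit$coefficients[["sdi"]]
  expect_equal(est, bhat[length(bhat)], tolerance = 1e-8)
  se <- sqrt(fit$vcov["sdi", "sdi"])
  expect_lt(abs(est - beta_true), 3 * se)
})

test_that("identical observations give the common value with zero residual variance", {
  df <- data.frame(location = "c1", sex = "male", age_lower = 40,
                   age_upper = 60, year = 2013, reported_mean = 7.5,
                   standard_error = 0.5, sample_size = 50)
  df <- df[rep(1, 10), ]
  fit <- fit_global(df)
  expect_equal(unname(fit$coefficients[1]), 7.5)
  expect_equal(fit$residual_var, 0)
  expect_equal(fit$tau2, 0)
})

test_that("a null covariate's 95% CI covers zero in at least 90% of replicates", {
  hits <- 0
  for (r in 1:100) {
    df <- make_survey_df(500, beta = 0, seed = 1000 + r)
    fit <- fit_global(df, covariate_names = "sdi")
    est <- fit$coefficients[["sdi"]]
    se <- sqrt(fit$vcov["sdi", "sdi"])
    if (abs(est) <= 1.96 * se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  df <- make_survey_df(50, seed = 3)
  df$sdi2 <- df$sdi  # exact duplicate covariate
  expect_error(fit_global(df, covariate_names = c("sdi", "sdi2")),
               "sdi2")
  expect_error(fit_global(df[0, ]), "data")
})

test_that("cascade combines parent and local data by precision weighting", {
  parent <- exposure_estimate("region_a", "region", 10, 2,
                              source_level = "region")
  # no local data: the child inherits the parent estimate
  child0 <- cascade_fit(parent, data.frame(), prior_strength = 1,
                        node = "eth", level = "country")
  expect_equal(child0$posterior_mean, 10)
  expect_equal(child0$posterior_sd, 2)
  expect_equal(child0$source_level, "region")
  # one datum with equal precision: exact midpoint (hand computation)
  child1 <- cascade_fit(parent,
                        data.frame(reported_mean = 20, standard_error = 2),
                        prior_strength = 1, node = "eth", level = "country")
  expect_equal(child1$posterior_mean, 15)
  expect_equal(child1$source_level, "country")
  # abundant local data dominates the prior
  local <- data.frame(reported_mean = rep(c(19, 21), 50),
                      standard_error = 0.1)
  childN <- cascade_fit(parent, local, prior_strength = 1)
  local_mean <- weighted.mean(local$reported_mean,
                              1 / local$standard_error^2)
  expect_lt(abs(childN$posterior_mean - local_mean) / local_mean, 0.01)
})

test_that("cascade is contractive: local data never widen the posterior", {
  set.seed(9)
  for (r in 1:20) {
    parent <- exposure_estimate("p", "region", runif(1, 5, 50),
                                runif(1, 0.5, 5))
    local <- data.frame(reported_mean = runif(3, 5, 50),
                        standard_error = runif(3, 0.2, 5))
    child <- cascade_fit(parent, local, prior_strength = 1)
    expect_lte(child$posterior_sd, parent$posterior_sd)
  }
})

test_that("energy adjustment follows the residual method", {
  # all observations already at target energy: identity
  expect_equal(energy_adjust(c(90, 110, 95), c(2000, 2000, 2000)),
               c(90, 110, 95))
  # exact line through two points evaluated at 2000 kcal
  expect_equal(energy_adjust(c(90, 110), c(1800, 2200)), c(100, 100))
  # regression identity: adjusted mean equals the prediction at target
  set.seed(5)
  energy <- runif(100, 1500, 3000)
  intake <- 20 + 0.04 * energy + rnorm(100, 0, 5)
  adj <- energy_adjust(intake, energy)
  fit <- lm(intake ~ energy)
  expect_equal(mean(adj),
               unname(predict(fit, newdata = data.frame(energy = 2000))),
               tolerance = 1e-10)
  # residual ordering is preserved
  expect_equal(order(adj), order(residuals(fit)))
  # idempotent once everything sits at the target energy
  expect_equal(energy_adjust(adj, rep(2000, 100)), adj)
  expect_error(energy_adjust(c(1, 2), c(2000, -1)), "positive")
})

test_that("sodium multiplier is the through-origin regression slope", {
  expect_equal(estimate_sodium_multiplier(c(1, 2, 3), 0.9 * c(1, 2, 3)), 0.9)
  # hand computation: sum(xy)/sum(x^2) = (3.4 + 14) / (4 + 16)
  expect_equal(estimate_sodium_multiplier(c(2, 4), c(1.7, 3.5)), 0.87)
  set.seed(7)
  d <- runif(100, 1, 6)
  u <- 0.85 * d + rnorm(100, 0, 0.2)
  expect_lt(abs(estimate_sodium_multiplier(d, u) - 0.85), 0.05)
  expect_equal(convert_sodium(4, 0.87), 3.48)
  expect_error(estimate_sodium_multiplier(c(2, -1), c(1, 1)), "positive")
})

test_that("data representativeness is the covered-country fraction", {
  countries <- paste0("c", 1:100)
  expect_equal(data_representativeness(countries[1:17], countries), 0.17)
  expect_equal(data_representativeness(countries[1:94], countries), 0.94)
  expect_equal(data_representativeness(character(), countries), 0)
  # nodes outside the country set (e.g. regions) do not count
  expect_equal(data_representativeness(c("region_x", countries[1]), countries),
               0.01)
})

test_that("hierarchy validation catches structural faults", {
  spec <- world_spec()
  w <- generate_world(spec)
  expect_silent(validate_hierarchy(w$hierarchy))
  bad <- w$hierarchy
  bad$parent[bad$name == "sr1_r1_c1"] <- "sr1"  # country under a super-region
  expect_error(validate_hierarchy(bad), "region")
  two_roots <- rbind(w$hierarchy,
                     data.frame(name = "global2", level = "global",
                                parent = NA_character_))
  expect_error(validate_hierarchy(two_roots), "exactly one global")
})
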