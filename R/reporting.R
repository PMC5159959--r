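# End-to-end orchestration: exposures -> PAFs (point + draws) -> attributable
# burden -> yearly summaries -> trend report, with every stage writable to and
# re-readable from delimited text so runs decompose and reproduce exactly.

pipe_key <- function(...) paste(..., sep = "|")

# Write numeric columns at full double precision so staged runs that re-read
# intermediates reproduce the direct run bit for bit.
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write_tsv_file(out, path)
}

#' Estimate exposures for every risk in a world bundle
#'
#' Runs the global fit + cascade per risk over the full stratum grid.
#'
#' @param world a `cra_world`
#' @return data.frame: `risk`, `location`, `sex`, `age_group`, `age_lower`,
#'   `age_upper`, `year`, `posterior_mean`, `posterior_sd`, `source_level`
#' @export
pipeline_exposures <- function(world) {
  ag <- world$age_groups
  strata <- do.call(rbind, lapply(world$spec$years, function(yr) {
    do.call(rbind, lapply(world$spec$sexes, function(sx) {
      data.frame(sex = sx, age_group = ag$age_group, age_lower = ag$age_lower,
                 age_upper = ag$age_upper, year = yr, stringsAsFactors = FALSE)
    }))
  }))
  out <- lapply(unique(world$surveys$risk), function(rk) {
    sv <- world$surveys[world$surveys$risk == rk, , drop = FALSE]
    est <- estimate_exposure(sv, world$hierarchy, strata,
                             prior_strength = world$spec$prior_strength)
    est$posterior_mean <- pmax(est$posterior_mean, 1e-6)
    cbind(risk = rk, est, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compute point and draw-level PAFs for every diet-disease pair
#'
#' Parameter draws come from named streams derived from the root seed:
#' log-RR (or slope and mediator log-RR for mediated risks) per pair, TMREL
#' per risk, and the posterior exposure mean per stratum. RR and TMREL
#' streams are keyed by risk/outcome only, so both periods share them and
#' period contrasts are properly correlated.
#'
#' @param world a `cra_world`
#' @param exposures result of [pipeline_exposures()]
#' @param seed root seed
#' @param n_draws Monte Carlo draws
#' @param nodes quadrature nodes per draw
#' @return list with one element per pair: `risk`, `outcome`, `strata`
#'   (data.frame), `point` (vector), `draws` (strata x n_draws matrix)
#' @export
pipeline_pafs <- function(world, exposures, seed = 1L, n_draws = 1000L,
                          nodes = 256L) {
  rr <- world$rr
  risks <- world$spec$risks
  tmrel_map <- setNames(world$tmrel$optimal_mean, world$tmrel$risk)
  params <- list()
  for (j in seq_len(nrow(rr))) {
    r <- rr[j, ]
    if (!is.na(r$slope)) {
      params[[pipe_key("slope", r$risk)]] <- param_normal(r$slope, r$slope_se)
      params[[pipe_key("medlrr", r$risk, r$outcome)]] <-
        param_normal(r$mediator_log_rr_per_unit, r$mediator_se)
    } else {
      params[[pipe_key("lrr", r$risk, r$outcome)]] <-
        param_normal(r$log_rr_per_unit, r$rr_se)
    }
  }
  for (rk in unique(rr$risk)) {
    params[[pipe_key("tmrel", rk)]] <- param_tmrel(tmrel_map[[rk]])
  }
  for (i in seq_len(nrow(exposures))) {
    e <- exposures[i, ]
    params[[pipe_key("expmean", e$risk, e$location, e$sex, e$age_group, e$year)]] <-
      param_normal(e$posterior_mean, e$posterior_sd)
  }
  dr <- draw_parameters(params, n_draws = n_draws, seed = seed)
  cv <- world$spec$intake_cv
  family <- world$spec$family
  pairs <- vector("list", nrow(rr))
  for (j in seq_len(nrow(rr))) {
    r <- rr[j, ]
    direction <- risks$direction[risks$name == r$risk]
    strata <- exposures[exposures$risk == r$risk, , drop = FALSE]
    tmrel_d <- dr[[pipe_key("tmrel", r$risk)]]$values
    if (!is.na(r$slope)) {
      slope_d <- dr[[pipe_key("slope", r$risk)]]$values
      med_d <- dr[[pipe_key("medlrr", r$risk, r$outcome)]]$values
      lrr_d <- NULL
      lrr_pt <- r$slope * r$mediator_log_rr_per_unit
    } else {
      slope_d <- med_d <- NULL
      lrr_d <- dr[[pipe_key("lrr", r$risk, r$outcome)]]$values
      lrr_pt <- r$log_rr_per_unit
    }
    point <- numeric(nrow(strata))
    draws <- matrix(0, nrow(strata), n_draws)
    for (i in seq_len(nrow(strata))) {
      e <- strata[i, ]
      mean_d <- dr[[pipe_key("expmean", r$risk, e$location, e$sex,
                             e$age_group, e$year)]]$values
      point[i] <- paf_draws(e$posterior_mean, cv, tmrel_map[[r$risk]],
                            lrr_draws = lrr_pt,
                            direction = direction, family = family,
                            nodes = nodes)
      draws[i, ] <- paf_draws(mean_d, cv, tmrel_d,
                              lrr_draws = lrr_d, slope_draws = slope_d,
                              mediator_lrr_draws = med_d,
                              direction = direction, family = family,
                              nodes = nodes)
    }
    pairs[[j]] <- list(risk = r$risk, outcome = r$outcome,
                       strata = strata[, c("location", "sex", "age_group",
                                           "age_lower", "age_upper", "year")],
                       point = point, draws = draws)
  }
  pairs
}

# Flat PAF summary table from pair results.
paf_table_from_pairs <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    ui <- t(apply(p$draws, 1, summarize_ui))
    data.frame(risk = p$risk, outcome = p$outcome,
               location = p$strata$location, year = p$strata$year,
               sex = p$strata$sex, age_group = p$strata$age_group,
               paf_point = p$point, paf_mean = ui[, "mean"],
               paf_lower = ui[, "lower"], paf_upper = ui[, "upper"],
               stringsAsFactors = FALSE)
  }))
}

# Wide draws table (one row per pair-stratum, one column per draw) used to
# hand results between CLI stages at full precision.
paf_draws_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    d <- as.data.frame(p$draws)
    names(d) <- paste0("draw_", seq_len(ncol(d)))
    cbind(data.frame(risk = p$risk, outcome = p$outcome,
                     location = p$strata$location, year = p$strata$year,
                     sex = p$strata$sex, age_group = p$strata$age_group,
                     paf_point = p$point, stringsAsFactors = FALSE),
          d)
  }))
}

pairs_from_draws_table <- function(tab) {
  ids <- unique(tab[, c("risk", "outcome")])
  draw_cols <- grep("^draw_", names(tab), value = TRUE)
  lapply(seq_len(nrow(ids)), function(j) {
    sub <- tab[tab$risk == ids$risk[j] & tab$outcome == ids$outcome[j], ,
               drop = FALSE]
    list(risk = ids$risk[j], outcome = ids$outcome[j],
         strata = sub[, c("location", "sex", "age_group", "year")],
         point = sub$paf_point,
         draws = as.matrix(sub[, draw_cols, drop = FALSE]))
  })
}

# Combine pair PAFs into per-outcome matrices aligned on stratum keys.
combine_pairs_by_outcome <- function(pairs) {
  out <- list()
  for (p in pairs) {
    keys <- pipe_key(p$strata$location, p$strata$sex, p$strata$age_group,
                     p$strata$year)
    o <- p$outcome
    if (is.null(out[[o]])) {
      out[[o]] <- list(keys = keys,
                       surv_point = 1 - p$point,
                       surv_draws = 1 - p$draws)
    } else {
      idx <- match(out[[o]]$keys, keys)
      assert_that(!anyNA(idx), "pair stratum grids are misaligned")
      out[[o]]$surv_point <- out[[o]]$surv_point * (1 - p$point[idx])
      out[[o]]$surv_draws <- out[[o]]$surv_draws * (1 - p$draws[idx, , drop = FALSE])
    }
  }
  lapply(out, function(x) list(keys = x$keys, point = 1 - x$surv_point,
                               draws = 1 - x$surv_draws))
}

#' Attributable burden, yearly summaries and the trend report
#'
#' Applies combined (multi-risk) PAFs to the specific-cause envelopes,
#' accumulates attributable counts at draw level, and summarizes: stratum
#' table, per-year totals (counts, crude and age-standardized rates per
#' 100,000, proportions of all-cause and of NCD burden), and the two-period
#' trend table.
#'
#' @param world a `cra_world`
#' @param pairs result of [pipeline_pafs()]
#' @return list: `burden_by_stratum`, `yearly`, `trend`, `trend_formatted`,
#'   `flags`, `combined_paf`
#' @export
pipeline_burden <- function(world, pairs) {
  env <- world$envelopes
  validate_envelopes(env[, c("outcome", "metric", "location", "year", "sex",
                             "age_group", "count", "population")])
  combined <- combine_pairs_by_outcome(pairs)
  n_draws <- ncol(pairs[[1]]$draws)
  spec_env <- env[env$group == "specific", , drop = FALSE]
  acc <- new.env(hash = TRUE, parent = emptyenv())
  add_to <- function(store, key, vec) {
    cur <- get0(key, envir = store, ifnotfound = NULL)
    assign(key, if (is.null(cur)) vec else cur + vec, envir = store)
  }
  acc_tot <- new.env(hash = TRUE, parent = emptyenv())   # metric|year -> draws
  acc_tot_pt <- new.env(hash = TRUE, parent = emptyenv())
  acc_age <- new.env(hash = TRUE, parent = emptyenv())   # metric|year|age -> draws
  acc_age_pt <- new.env(hash = TRUE, parent = emptyenv())
  acc_str <- new.env(hash = TRUE, parent = emptyenv())   # metric|stratum -> draws
  acc_str_pt <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(spec_env))) {
    row <- spec_env[i, ]
    cd <- combined[[row$outcome]]
    if (is.null(cd)) next  # outcome with no modeled risk: PAF 0
    key <- pipe_key(row$location, row$sex, row$age_group, row$year)
    idx <- match(key, cd$keys)
    if (is.na(idx)) next
    dvec <- row$count * cd$draws[idx, ]
    pt <- row$count * cd$point[idx]
    add_to(acc_tot, pipe_key(row$metric, row$year), dvec)
    add_to(acc_tot_pt, pipe_key(row$metric, row$year), pt)
    add_to(acc_age, pipe_key(row$metric, row$year, row$age_group), dvec)
    add_to(acc_age_pt, pipe_key(row$metric, row$year, row$age_group), pt)
    add_to(acc_str, pipe_key(row$metric, key), dvec)
    add_to(acc_str_pt, pipe_key(row$metric, key), pt)
  }
  # Populations and envelope totals (fixed, not sampled).
  strata_pop <- unique(env[, c("location", "sex", "age_group", "year",
                               "population")])
  pop_by_year <- tapply(strata_pop$population, strata_pop$year, sum)
  pop_by_year_age <- tapply(strata_pop$population,
                            list(strata_pop$year, strata_pop$age_group), sum)
  env_tot <- function(group, metric, year) {
    sum(env$count[env$group == group & env$metric == metric &
                    env$year == year])
  }
  env_tot_age <- function(group, metric, year, age) {
    sum(env$count[env$group == group & env$metric == metric &
                    env$year == year & env$age_group == age])
  }
  ages <- world$age_groups$age_group
  std <- standard_population(ages)
  metrics <- unique(spec_env$metric)
  years <- sort(unique(spec_env$year))
  yearly <- list()
  for (m in metrics) for (yr in years) {
    cnt_d <- get0(pipe_key(m, yr), envir = acc_tot)
    cnt_pt <- get0(pipe_key(m, yr), envir = acc_tot_pt)
    if (is.null(cnt_d)) next
    pop <- pop_by_year[[as.character(yr)]]
    rate_d <- cnt_d / pop * 1e5
    # age-standardized attributable rate, draw level
    std_rate_d <- numeric(n_draws)
    std_env_all <- 0
    std_env_ncd <- 0
    for (a in ages) {
      pa <- pop_by_year_age[as.character(yr), a]
      std_rate_d <- std_rate_d +
        std[[a]] * get0(pipe_key(m, yr, a), envir = acc_age) / pa * 1e5
      std_env_all <- std_env_all +
        std[[a]] * env_tot_age("all_cause", m, yr, a) / pa * 1e5
      std_env_ncd <- std_env_ncd +
        std[[a]] * env_tot_age("all_ncd", m, yr, a) / pa * 1e5
    }
    all_cnt <- env_tot("all_cause", m, yr)
    ncd_cnt <- env_tot("all_ncd", m, yr)
    s_n <- summarize_ui(cnt_d)
    s_r <- summarize_ui(rate_d)
    s_sr <- summarize_ui(std_rate_d)
    s_pa <- summarize_ui(100 * cnt_d / all_cnt)
    s_pn <- summarize_ui(100 * cnt_d / ncd_cnt)
    s_spa <- summarize_ui(100 * std_rate_d / std_env_all)
    s_spn <- summarize_ui(100 * std_rate_d / std_env_ncd)
    yearly[[length(yearly) + 1]] <- data.frame(
      metric = m, year = yr, population = pop,
      number_point = cnt_pt,
      number = s_n["mean"], number_lo = s_n["lower"], number_hi = s_n["upper"],
      rate = s_r["mean"], rate_lo = s_r["lower"], rate_hi = s_r["upper"],
      std_rate = s_sr["mean"], std_rate_lo = s_sr["lower"],
      std_rate_hi = s_sr["upper"],
      prop_all = s_pa["mean"], prop_all_lo = s_pa["lower"],
      prop_all_hi = s_pa["upper"],
      prop_ncd = s_pn["mean"], prop_ncd_lo = s_pn["lower"],
      prop_ncd_hi = s_pn["upper"],
      std_prop_all = s_spa["mean"], std_prop_all_lo = s_spa["lower"],
      std_prop_all_hi = s_spa["upper"],
      std_prop_ncd = s_spn["mean"], std_prop_ncd_lo = s_spn["lower"],
      std_prop_ncd_hi = s_spn["upper"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  yearly <- do.call(rbind, yearly)
  # stratum-level table
  strata_keys <- unique(spec_env[, c("location", "sex", "age_group", "year")])
  bs <- list()
  for (m in metrics) {
    for (i in seq_len(nrow(strata_keys))) {
      sk <- strata_keys[i, ]
      key <- pipe_key(sk$location, sk$sex, sk$age_group, sk$year)
      dvec <- get0(pipe_key(m, key), envir = acc_str)
      if (is.null(dvec)) next
      pt <- get0(pipe_key(m, key), envir = acc_str_pt)
      pop <- strata_pop$population[strata_pop$location == sk$location &
                                     strata_pop$sex == sk$sex &
                                     strata_pop$age_group == sk$age_group &
                                     strata_pop$year == sk$year][1]
      s <- summarize_ui(dvec)
      bs[[length(bs) + 1]] <- data.frame(
        location = sk$location, sex = sk$sex, age_group = sk$age_group,
        year = sk$year, metric = m, count_point = pt,
        count = s["mean"], count_lo = s["lower"], count_hi = s["upper"],
        population = pop, rate = rate_per_100k(s[["mean"]], pop),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  burden_by_stratum <- do.call(rbind, bs)
  trend <- if (length(years) == 2) build_trend_table(yearly) else {
    list(raw = NULL, formatted = NULL,
         flags = data.frame(metric = character(), standardization = character(),
                            measure = character(), start = numeric(),
                            end = numeric(), change_pct = numeric(),
                            recomputed_pct = numeric(), flagged = logical()))
  }
  combined_paf_tab <- do.call(rbind, lapply(names(combined), function(o) {
    cd <- combined[[o]]
    parts <- strsplit(cd$keys, "|", fixed = TRUE)
    ui <- t(apply(cd$draws, 1, summarize_ui))
    data.frame(outcome = o,
               location = vapply(parts, `[`, "", 1),
               sex = vapply(parts, `[`, "", 2),
               age_group = vapply(parts, `[`, "", 3),
               year = as.numeric(vapply(parts, `[`, "", 4)),
               paf = cd$point, paf_mean = ui[, "mean"],
               paf_lower = ui[, "lower"], paf_upper = ui[, "upper"],
               stringsAsFactors = FALSE)
  }))
  list(burden_by_stratum = burden_by_stratum, yearly = yearly,
       trend = trend$raw, trend_formatted = trend$formatted,
       flags = trend$flags, combined_paf = combined_paf_tab)
}

#' Build a two-period trend table from yearly summaries
#'
#' Rows are metric x {unstandardized, age-standardized} x measure (number,
#' rate per 100,000, proportion of all-cause, proportion of NCD), columns the
#' two periods plus the percentage change computed from the unrounded means.
#' Formatting follows report conventions: counts and rates to integers,
#' percentages to one decimal. Age-standardized counts are not reported
#' (standardization is a rate concept).
#'
#' @param yearly data.frame from [pipeline_burden()]'s `yearly` element
#' @return list: `raw` (numeric), `formatted` (strings), `flags`
#'   (self-check of change cells against their own start/end values)
#' @export
build_trend_table <- function(yearly) {
  years <- sort(unique(yearly$year))
  assert_that(length(years) == 2, "trend table needs exactly two periods")
  measures <- list(
    list(std = "unstandardized", measure = "number", col = "number",
         fmt = fmt_count),
    list(std = "unstandardized", measure = "rate_per_100k", col = "rate",
         fmt = fmt_rate),
    list(std = "unstandardized", measure = "proportion_all_cause",
         col = "prop_all", fmt = fmt_pct),
    list(std = "unstandardized", measure = "proportion_ncd", col = "prop_ncd",
         fmt = fmt_pct),
    list(std = "age_standardized", measure = "rate_per_100k", col = "std_rate",
         fmt = fmt_rate),
    list(std = "age_standardized", measure = "proportion_all_cause",
         col = "std_prop_all", fmt = fmt_pct),
    list(std = "age_standardized", measure = "proportion_ncd",
         col = "std_prop_ncd", fmt = fmt_pct))
  raw <- list()
  formatted <- list()
  for (m in unique(yearly$metric)) {
    sub <- yearly[yearly$metric == m, ]
    if (!all(years %in% sub$year)) {
      stop_validation(sprintf("metric '%s' is missing a period", m))
    }
    r1 <- sub[sub$year == years[1], ]
    r2 <- sub[sub$year == years[2], ]
    for (sp in measures) {
      v1 <- r1[[sp$col]]; v2 <- r2[[sp$col]]
      lo1 <- r1[[paste0(sp$col, "_lo")]]; hi1 <- r1[[paste0(sp$col, "_hi")]]
      lo2 <- r2[[paste0(sp$col, "_lo")]]; hi2 <- r2[[paste0(sp$col, "_hi")]]
      chg <- pct_change(v1, v2)
      raw[[length(raw) + 1]] <- data.frame(
        metric = m, standardization = sp$std, measure = sp$measure,
        start = v1, start_lo = lo1, start_hi = hi1,
        end = v2, end_lo = lo2, end_hi = hi2,
        change_pct = fmt_pct(chg), stringsAsFactors = FALSE)
      f <- sp$fmt
      formatted[[length(formatted) + 1]] <- data.frame(
        metric = m, standardization = sp$std, measure = sp$measure,
        period1 = sprintf("%s (%s-%s)", f(v1), f(lo1), f(hi1)),
        period2 = sprintf("%s (%s-%s)", f(v2), f(lo2), f(hi2)),
        change = sprintf("%.1f%%", fmt_pct(chg)), stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, raw)
  formatted <- do.call(rbind, formatted)
  names(formatted)[names(formatted) == "period1"] <- as.character(years[1])
  names(formatted)[names(formatted) == "period2"] <- as.character(years[2])
  flags <- flag_inconsistent_changes(
    raw[, c("metric", "standardization", "measure", "start", "end",
            "change_pct")])
  list(raw = raw, formatted = formatted, flags = flags[flags$flagged, ,
                                                       drop = FALSE])
}

#' Run the full pipeline on a world bundle
#'
#' Exposure cascade, PAF integration with Monte Carlo draws, burden
#' accounting and the trend report, optionally writing every stage to
#' `output_dir`. Reruns with the same world and seed are byte-identical.
#'
#' @param world a `cra_world` or a bundle directory path
#' @param seed root seed for all draw streams
#' @param n_draws Monte Carlo draws (1000 for production use; tests and
#'   examples use fewer)
#' @param output_dir optional directory for stage outputs
#' @param nodes quadrature nodes
#' @param save_draws also write the wide per-draw PAF table
#' @return list: `exposures`, `paf_table`, `pairs`, plus everything from
#'   [pipeline_burden()]
#' @export
run_pipeline <- function(world, seed = 1L, n_draws = 1000L, output_dir = NULL,
                         nodes = 256L, save_draws = FALSE) {
  if (is.character(world)) world <- read_world(world)
  exposures <- pipeline_exposures(world)
  pairs <- pipeline_pafs(world, exposures, seed = seed, n_draws = n_draws,
                         nodes = nodes)
  paf_tab <- paf_table_from_pairs(pairs)
  burden <- pipeline_burden(world, pairs)
  res <- c(list(exposures = exposures, paf_table = paf_tab, pairs = pairs),
           burden)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_tsv_precise(exposures, p("exposures.tsv"))
    write_tsv_precise(paf_tab, p("paf_table.tsv"))
    if (save_draws) write_tsv_precise(paf_draws_table(pairs), p("paf_draws.tsv"))
    write_tsv_precise(burden$burden_by_stratum, p("burden_by_stratum.tsv"))
    write_tsv_precise(burden$yearly, p("yearly_summary.tsv"))
    if (!is.null(burden$trend_formatted)) {
      write_tsv_file(burden$trend_formatted, p("trend_table.tsv"))
    }
    write_tsv_file(burden$flags, p("flags.tsv"))
    cfg_digest <- string_digest(yaml::as.yaml(unclass(world$spec[
      setdiff(names(world$spec), c("risks", "rr_pairs"))])))
    writeLines(c(sprintf("dietcra %s",
                         as.character(utils::packageVersion("dietcra"))),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("n_draws: %d", as.integer(n_draws)),
                 sprintf("config_digest: %s", cfg_digest)),
               p("run_log.txt"))
  }
  res
}

#' Calibrate envelope counts so attributable totals hit target values
#'
#' Scales the envelope counts of one metric, per year, so the pipeline's
#' point attributable totals equal the given targets. PAFs are unchanged by
#' envelope scaling, so the calibrated world reproduces the target period
#' change exactly through the full pipeline.
#'
#' @param world a `cra_world`
#' @param targets named numeric: year (as name) -> target attributable count
#' @param metric which metric to calibrate (default `"deaths"`)
#' @param seed,n_draws calibration run settings; reproducing the target
#'   period change exactly requires re-running the pipeline with the same
#'   seed and draw count
#' @return the calibrated `cra_world`
#' @export
calibrate_world_counts <- function(world, targets, metric = "deaths",
                                   seed = 1L, n_draws = 100L) {
  res <- run_pipeline(world, seed = seed, n_draws = n_draws)
  y <- res$yearly[res$yearly$metric == metric, ]
  for (yr in names(targets)) {
    cur <- y$number[y$year == as.numeric(yr)]
    assert_that(length(cur) == 1 && cur > 0,
                sprintf("no attributable %s total for year %s", metric, yr))
    sc <- targets[[yr]] / cur
    sel <- world$envelopes$metric == metric &
      world$envelopes$year == as.numeric(yr)
    world$envelopes$count[sel] <- world$envelopes$count[sel] * sc
  }
  world
}

CLI_SUBCOMMANDS <- c("simulate", "estimate-exposure", "paf", "burden",
                     "report", "all")

#' Command-line style entry point
#'
#' Dispatches one pipeline stage (or `all`) against a world bundle
#' directory. Each subcommand reads and writes only documented files; stage
#' outputs regenerate the direct end-to-end result exactly. Returns an exit
#' code instead of raising: 0 success, 2 missing input (with the file named),
#' 3 schema mismatch (with the column diff), 1 other validation failure.
#'
#' @param subcommand one of `simulate`, `estimate-exposure`, `paf`, `burden`,
#'   `report`, `all`
#' @param config optional YAML file of [world_spec()] overrides (simulate)
#' @param input input directory (bundle, or prior stage output)
#' @param output output directory
#' @param seed root seed
#' @param n_draws Monte Carlo draws
#' @return integer exit code, invisibly
#' @export
cli_run <- function(subcommand, config = NULL, input = NULL, output = NULL,
                    seed = 1L, n_draws = 1000L) {
  code <- tryCatch({
    assert_that(subcommand %in% CLI_SUBCOMMANDS,
                sprintf("unknown subcommand '%s' (expected one of: %s)",
                        subcommand, paste(CLI_SUBCOMMANDS, collapse = ", ")))
    switch(subcommand,
      simulate = {
        spec <- if (is.null(config)) world_spec(seed = seed) else {
          cfg <- yaml::read_yaml(config)
          cfg$seed <- cfg$seed %||% seed
          if (!is.null(cfg$age_breaks)) cfg$age_breaks <- unlist(cfg$age_breaks)
          if (!is.null(cfg$years)) cfg$years <- unlist(cfg$years)
          if (!is.null(cfg$sexes)) cfg$sexes <- unlist(cfg$sexes)
          if (!is.null(cfg$coverage)) cfg$coverage <- unlist(cfg$coverage)
          do.call(world_spec, cfg)
        }
        write_world(generate_world(spec), output)
      },
      `estimate-exposure` = {
        world <- read_world(input)
        dir.create(output, recursive = TRUE, showWarnings = FALSE)
        write_tsv_precise(pipeline_exposures(world),
                          file.path(output, "exposures.tsv"))
      },
      paf = {
        world <- read_world(input)
        expo_path <- file.path(input, "exposures.tsv")
        exposures <- if (file.exists(expo_path)) read_tsv_file(expo_path)
                     else pipeline_exposures(world)
        pairs <- pipeline_pafs(world, exposures, seed = seed,
                               n_draws = n_draws)
        dir.create(output, recursive = TRUE, showWarnings = FALSE)
        write_tsv_precise(paf_table_from_pairs(pairs),
                          file.path(output, "paf_table.tsv"))
        write_tsv_precise(paf_draws_table(pairs),
                          file.path(output, "paf_draws.tsv"))
      },
      burden = {
        world <- read_world(input)
        draws_path <- file.path(input, "paf_draws.tsv")
        if (!file.exists(draws_path)) {
          stop_missing_input(sprintf("input file not found: %s", draws_path))
        }
        pairs <- pairs_from_draws_table(read_tsv_file(draws_path))
        burden <- pipeline_burden(world, pairs)
        dir.create(output, recursive = TRUE, showWarnings = FALSE)
        write_tsv_precise(burden$burden_by_stratum,
                          file.path(output, "burden_by_stratum.tsv"))
        write_tsv_precise(burden$yearly, file.path(output, "yearly_summary.tsv"))
        write_tsv_file(burden$trend_formatted,
                       file.path(output, "trend_table.tsv"))
        write_tsv_file(burden$flags, file.path(output, "flags.tsv"))
      },
      report = {
        ypath <- file.path(input, "yearly_summary.tsv")
        if (!file.exists(ypath)) {
          stop_missing_input(sprintf("input file not found: %s", ypath))
        }
        trend <- build_trend_table(read_tsv_file(ypath))
        dir.create(output, recursive = TRUE, showWarnings = FALSE)
        write_tsv_file(trend$formatted, file.path(output, "trend_table.tsv"))
        write_tsv_file(trend$flags, file.path(output, "flags.tsv"))
      },
      all = {
        run_pipeline(input, seed = seed, n_draws = n_draws,
                     output_dir = output, save_draws = TRUE)
      })
    0L
  },
  cra_missing_input_error = function(e) { message(conditionMessage(e)); 2L },
  cra_schema_error = function(e) { message(conditionMessage(e)); 3L },
  cra_error = function(e) { message(conditionMessage(e)); 1L })
  invisible(code)
}
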