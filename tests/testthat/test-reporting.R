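test_that("the full pipeline run writes a complete, populated report", {
  w <- generate_world(world_spec(seed = 301))
  out <- file.path(tempdir(), "report_smoke")
  res <- run_pipeline(w, seed = 3, n_draws = 20, output_dir = out)
  for (f in c("exposures.tsv", "paf_table.tsv", "burden_by_stratum.tsv",
              "yearly_summary.tsv", "trend_table.tsv", "flags.tsv",
              "run_log.txt")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  expect_true(all(res$paf_table$paf_upper >= res$paf_table$paf_lower))
  expect_true(all(res$paf_table$paf_point >= 0 & res$paf_table$paf_point < 1))
  expect_true(all(c("deaths", "dalys", "ylls", "ylds") %in%
                    res$yearly$metric))
  # UI columns populated and ordered
  expect_true(all(res$yearly$number_hi > res$yearly$number_lo))
  # attributable never exceeds the envelope
  expect_true(all(res$yearly$prop_ncd_hi < 100))
  unlink(out, recursive = TRUE)
})

test_that("reruns with the same seed are byte-identical", {
  w <- generate_world(world_spec(seed = 302))
  o1 <- file.path(tempdir(), "rerun1"); o2 <- file.path(tempdir(), "rerun2")
  run_pipeline(w, seed = 5, n_draws = 15, output_dir = o1, save_draws = TRUE)
  run_pipeline(w, seed = 5, n_draws = 15, output_dir = o2, save_draws = TRUE)
  for (f in list.files(o1)) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     label = f)
  }
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("staged CLI runs regenerate the direct end-to-end report", {
  bundle <- file.path(tempdir(), "stage_bundle")
  direct <- file.path(tempdir(), "stage_direct")
  expect_equal(cli_run("simulate", output = bundle, seed = 303), 0L)
  expect_equal(cli_run("estimate-exposure", input = bundle, output = bundle),
               0L)
  expect_equal(cli_run("paf", input = bundle, output = bundle, seed = 7,
                       n_draws = 12), 0L)
  expect_equal(cli_run("burden", input = bundle, output = bundle), 0L)
  expect_equal(cli_run("all", input = bundle, output = direct, seed = 7,
                       n_draws = 12), 0L)
  expect_identical(readLines(file.path(bundle, "trend_table.tsv")),
                   readLines(file.path(direct, "trend_table.tsv")))
  expect_identical(readLines(file.path(bundle, "yearly_summary.tsv")),
                   readLines(file.path(direct, "yearly_summary.tsv")))
  # the report stage rebuilds the trend table from the saved yearly summary
  rep_out <- file.path(tempdir(), "stage_report")
  expect_equal(cli_run("report", input = bundle, output = rep_out), 0L)
  expect_identical(readLines(file.path(rep_out, "trend_table.tsv")),
                   readLines(file.path(bundle, "trend_table.tsv")))
  unlink(c(bundle, direct, rep_out), recursive = TRUE)
})

test_that("CLI maps failure modes to documented exit codes", {
  empty <- file.path(tempdir(), "no_bundle")
  dir.create(empty, showWarnings = FALSE)
  expect_equal(suppressMessages(cli_run("all", input = empty,
                                        output = tempfile())), 2L)
  # schema mismatch: a bundle whose survey table lost a required column
  broken <- file.path(tempdir(), "broken_bundle")
  cli_run("simulate", output = broken, seed = 304)
  sv <- utils::read.delim(file.path(broken, "surveys.tsv"))
  sv$standard_error <- NULL
  utils::write.table(sv, file.path(broken, "surveys.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_equal(suppressWarnings(suppressMessages(
    cli_run("estimate-exposure", input = broken, output = tempfile()))), 3L)
  expect_equal(suppressMessages(cli_run("fly")), 1L)
  unlink(c(empty, broken), recursive = TRUE)
})

test_that("a world calibrated to published death counts reprints the 61.2% change", {
  w <- generate_world(world_spec(seed = 305))
  cal <- calibrate_world_counts(w, c("1990" = 37465, "2013" = 60402),
                                metric = "deaths", seed = 9, n_draws = 25)
  res <- run_pipeline(cal, seed = 9, n_draws = 25)
  row <- res$trend[res$trend$metric == "deaths" &
                     res$trend$standardization == "unstandardized" &
                     res$trend$measure == "number", ]
  expect_equal(row$start, 37465, tolerance = 1e-9)
  expect_equal(row$end, 60402, tolerance = 1e-9)
  expect_equal(row$change_pct, 61.2)
  frow <- res$trend_formatted[res$trend_formatted$metric == "deaths" &
    res$trend_formatted$standardization == "unstandardized" &
    res$trend_formatted$measure == "number", ]
  expect_equal(frow$change, "61.2%")
})

test_that("identical periods give a uniformly zero-change trend table", {
  spec <- world_spec(pop_growth = 1, rate_drift = 1, survey_noise = 0,
                     seed = 306)
  w <- generate_two_period_world(spec, exposure_trend = 1.0)
  res <- run_pipeline(w, seed = 2, n_draws = 10)
  expect_true(all(abs(res$trend$change_pct) <= 0.1))
  expect_equal(nrow(res$flags), 0)
})

test_that("the trend table requires both periods", {
  w <- generate_world(world_spec(seed = 307))
  res <- run_pipeline(w, seed = 2, n_draws = 5)
  expect_error(build_trend_table(res$yearly[res$yearly$year == 1990, ]),
               "two periods")
  half <- res$yearly[!(res$yearly$metric == "deaths" &
                         res$yearly$year == 2013), ]
  expect_error(build_trend_table(half), "deaths")
})
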