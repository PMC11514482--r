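fix_dir <- withr::local_tempdir(.local_envir = teardown_env())
make_fixtures(fix_dir)
calls_telo <- read_calls(file.path(fix_dir, "sgTelo_calls.csv"))
calls_ns <- read_calls(file.path(fix_dir, "sgNS_calls.csv"))

test_that("cohort summaries reproduce the fixture frequency cells", {
  st <- summarize_cohort(calls_telo)
  sn <- summarize_cohort(calls_ns)
  expect_equal(st$overall$n_molecules, 1061L)
  expect_equal(sn$overall$n_molecules, 1100L)
  expect_equal(st$overall$its_plus_pct, 100 * 161 / 1061)
  expect_equal(st$overall$its_minus_pct, 100 * 42 / 1061)
  expect_equal(st$overall$tfe_pct, 100 * 86 / 1061)
  expect_equal(sn$overall$its_plus_pct, 100 * 59 / 1100)
  expect_equal(sn$overall$its_minus_pct, 100 * 4 / 1100)
  expect_equal(sn$overall$tfe_pct, 100 * 55 / 1100)
  # rendered at the table's precision
  expect_equal(smtaom:::fmt_pct(st$overall$its_plus_pct), "15.2")
  expect_equal(smtaom:::fmt_pct(st$overall$its_minus_pct), "4.0")
  expect_equal(smtaom:::fmt_pct(sn$overall$its_plus_pct), "5.4")
  expect_equal(smtaom:::fmt_pct(sn$overall$its_minus_pct), "0.36")
  expect_equal(smtaom:::fmt_pct(sn$overall$tfe_pct), "5.0")
  # cohort telomere means sit near their configured values
  expect_lt(abs(st$overall$end_tel_mean_kb - 11.3), 0.5)
  expect_lt(abs(sn$overall$end_tel_mean_kb - 11.7), 0.5)
  # per-arm event counts sum to the overall counts (conservation)
  for (f in c("n_end_tel", "n_tfe", "n_its_plus", "n_its_minus"))
    expect_equal(sum(st$per_arm[[f]]), st$overall[[f]])
  # an all-END_TEL cohort has zero event frequencies
  pure <- calls_telo[calls_telo$category == "END_TEL", ]
  sp <- summarize_cohort(pure)
  expect_equal(sp$overall$tfe_pct + sp$overall$its_plus_pct +
                 sp$overall$its_minus_pct, 0)
})

test_that("fold and percent changes match their closed forms", {
  expect_equal(round(fold_change(15.2, 5.4), 1), 2.8)
  expect_equal(round(fold_change(4.0, 0.36), 1), 11.1)
  expect_equal(fold_change(7, 7), 1)
  fz <- fold_change(47.6, 0)
  expect_true(is.infinite(fz))
  expect_true(attr(fz, "zero_baseline"))
  expect_equal(round(percent_change(13, 11.1)), 17)
  expect_equal(round(percent_change(11.5, 14.2)), -19)
  expect_equal(percent_change(5, 5), 0)
})

test_that("frequency comparisons agree across the three 2x2 tests", {
  for (tst in c("fisher_exact", "chi2", "two_prop_z")) {
    cmp <- compare_frequencies(161, 1061, 59, 1100, tst)
    expect_lt(cmp$p_value, 0.001)
    expect_equal(cmp$value_a, 100 * 161 / 1061)
    expect_equal(compare_frequencies(0, 100, 0, 100, tst)$p_value, 1)
  }
  expect_equal(compare_frequencies(5, 10, 5, 10, "fisher_exact")$p_value, 1)
})

test_that("length comparisons control type-I error and detect a 3 kb shift", {
  x <- c(10, 11, 12)
  same <- compare_lengths(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$fold_change, 1)
  # degenerate-variance shortcut
  expect_equal(compare_lengths(c(5, 5), c(5, 5))$p_value, 1)

  draw <- function(n, mean) {
    sdlog <- sqrt(log(1 + 0.35^2))
    stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  }
  withr::local_seed(101)
  reject_null <- replicate(200, {
    compare_lengths(draw(1000, 11.5), draw(1000, 11.5))$p_value < 0.05
  })
  expect_lte(mean(reject_null), 0.06)
  reject_alt <- replicate(200, {
    compare_lengths(draw(1050, 11.3), draw(1050, 14.2))$p_value < 0.05
  })
  expect_gt(mean(reject_alt), 0.8)
})

test_that("cohort comparison reports raw and BH-adjusted p-values per metric", {
  cc <- compare_cohorts(calls_telo, calls_ns)
  ov <- cc$overall
  expect_true(all(c("its_plus_pct", "its_minus_pct", "tfe_pct",
                    "end_tel_mean_kb") %in% ov$metric))
  expect_lt(ov$p_value[ov$metric == "its_plus_pct"], 0.001)
  expect_equal(ov$fold_change[ov$metric == "its_plus_pct"],
               (161 / 1061) / (59 / 1100))
  expect_true("p_adj_bh" %in% names(cc$per_arm))
  for (m in unique(cc$per_arm$metric)) {
    i <- cc$per_arm$metric == m
    expect_true(all(cc$per_arm$p_adj_bh[i] >= cc$per_arm$p_value[i] - 1e-12))
  }
})

test_that("the rendered report shows events-over-n cells and is byte-stable", {
  st <- summarize_cohort(calls_telo)
  sn <- summarize_cohort(calls_ns)
  cc <- compare_cohorts(calls_telo, calls_ns)
  p1 <- file.path(withr::local_tempdir(), "report.csv")
  paths <- render_report(list(st, sn), cc, p1)
  txt <- readLines(p1)
  expect_true(any(grepl("15.2 (161/1061)", txt, fixed = TRUE)))
  expect_true(any(grepl("0.36 (4/1100)", txt, fixed = TRUE)))
  expect_true(file.exists(paths[["per_arm"]]))
  expect_true(file.exists(paths[["json"]]))
  first <- readBin(p1, "raw", file.size(p1))
  render_report(list(st, sn), cc, p1)
  expect_identical(readBin(p1, "raw", file.size(p1)), first)
})
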