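test_that("event rates drive the simulated truth and molecules are conserved", {
  rs <- tiny_refset(4)
  cfg <- sim_config(event_rates = c(end_tel = 1, tfe = 0, its_plus = 0,
                                    its_minus = 0),
                    molecules_per_arm = 10, seed = 2)
  sim <- simulate_cohort(rs, cfg, "pure")
  expect_equal(length(sim$molecules), nrow(sim$truth))
  expect_true(all(sim$truth$true_category == "END_TEL"))
  expect_true(all(vapply(sim$molecules, function(m)
    nrow(m$red_segments) == 1L, logical(1))))

  # published-rate draw: realized counts inside the exact binomial 99% CI
  rates <- cohort_event_rates("sgTelo")
  sim2 <- simulate_cohort(rs, sim_config(event_rates = rates, seed = 4),
                          "sgTelo", n_molecules = 1061)
  tab <- table(factor(sim2$truth$true_category,
                      c("END_TEL", "TFE", "ITS_PLUS", "ITS_MINUS")))
  for (k in names(rates)) {
    ci <- stats::qbinom(c(0.005, 0.995), 1061, rates[[k]])
    expect_gte(tab[[toupper(k)]], ci[1])
    expect_lte(tab[[toupper(k)]], ci[2])
  }
  # conservation across all classes
  expect_equal(sum(tab), 1061L - sum(sim2$truth$true_category == "DEBRIS"))
})

test_that("simulation is deterministic given the seed", {
  rs <- tiny_refset(3)
  cfg <- sim_config(molecules_per_arm = 5, seed = 11)
  a <- simulate_cohort(rs, cfg, "x")
  b <- simulate_cohort(rs, cfg, "x")
  expect_identical(a, b)
  # and a different seed actually changes the draw
  c2 <- simulate_cohort(rs, sim_config(molecules_per_arm = 5, seed = 12), "x")
  expect_false(identical(a, c2))
})

test_that("with all noise channels off, molecule spacings equal the reference", {
  rs <- tiny_refset(3)
  cfg <- noiseless_config(event_rates = c(end_tel = 1, tfe = 0, its_plus = 0,
                                          its_minus = 0),
                          molecules_per_arm = 5, seed = 6)
  sim <- simulate_cohort(rs, cfg, "clean")
  for (i in seq_along(sim$molecules)) {
    m <- sim$molecules[[i]]
    arm <- rs$arms[[sim$truth$true_arm[i]]]
    ref_kb <- arm$label_positions / 1000
    # the molecule holds the distal window of the arm: its spacings must be a
    # suffix of the reference spacings
    spac <- diff(m$green_labels)
    ref_spac <- diff(ref_kb)
    expect_equal(spac,
                 tail(ref_spac, length(spac)), tolerance = 1e-9)
  }
})

test_that("simulated telomere lengths converge to the configured mean", {
  rs <- tiny_refset(3)
  cfg <- sim_config(event_rates = c(end_tel = 1, tfe = 0, its_plus = 0,
                                    its_minus = 0),
                    telomere_mean_kb = 11.5, telomere_cv = 0.35, seed = 8)
  sim <- simulate_cohort(rs, cfg, "big", n_molecules = 5000)
  tl <- sim$truth$true_telomere_kb
  se <- stats::sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - 11.5), 3 * se)
})

test_that("molecules round-trip through the BNX dialect", {
  rs <- tiny_refset(3)
  sim <- simulate_cohort(rs, sim_config(seed = 5), "rt", n_molecules = 100)
  path <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(sim$molecules, path)
  back <- read_bnx(path)
  expect_equal(length(back), 100L)
  for (i in c(1, 50, 100)) {
    expect_equal(back[[i]]$molecule_id, sim$molecules[[i]]$molecule_id)
    expect_equal(back[[i]]$green_labels, sim$molecules[[i]]$green_labels,
                 tolerance = 1e-3)
    expect_equal(back[[i]]$red_segments$start_kb,
                 sim$molecules[[i]]$red_segments$start_kb, tolerance = 1e-3)
  }
  # empty list -> header-only file
  p2 <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(list(), p2)
  expect_true(all(grepl("^#", readLines(p2))))
  expect_equal(read_bnx(p2), list())
})

test_that("malformed BNX input fails naming the offending line", {
  p <- withr::local_tempfile(fileext = ".bnx")
  writeLines(c("0\tm1\t100.0\tc", "1\t5.0\t10.0", "2\t90.0\tbad\t50"), p)
  expect_error(read_bnx(p), "line 3", class = "smta_format_error")
  p2 <- withr::local_tempfile(fileext = ".bnx")
  writeLines(c("0\tm1\t100.0\tc", "2\t90.0\t80.0\t50"), p2)
  expect_error(read_bnx(p2), "start must be below end",
               class = "smta_format_error")
  p3 <- withr::local_tempfile(fileext = ".bnx")
  writeLines("1\t5.0", p3)
  expect_error(read_bnx(p3), "line 1", class = "smta_format_error")
})
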