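test_that("well-formed reference files round-trip through the CMAP dialect", {
  path <- withr::local_tempfile(fileext = ".cmap")
  rs <- tiny_refset(n_arms = 2)
  write_reference(rs, path)
  back <- read_reference(path)
  expect_equal(length(back), 2L)
  expect_equal(names(back$arms), names(rs$arms))
  expect_equal(lapply(back$arms, `[[`, "label_positions"),
               lapply(rs$arms, `[[`, "label_positions"))
  expect_equal(vapply(back$arms, `[[`, numeric(1), "terminus_pos"),
               vapply(rs$arms, `[[`, numeric(1), "terminus_pos"))

  # a 35-arm set writes one record per label and round-trips identically
  big <- synthesize_reference(n_arms = 35, seed = 3)
  p2 <- withr::local_tempfile(fileext = ".cmap")
  write_reference(big, p2)
  lines <- readLines(p2)
  n_records <- sum(!grepl("^#", lines))
  expect_equal(n_records,
               sum(vapply(big$arms, function(a) length(a$label_positions),
                          integer(1))))
  back2 <- read_reference(p2)
  expect_equal(vapply(back2$arms, `[[`, numeric(1), "terminus_pos"),
               vapply(big$arms, `[[`, numeric(1), "terminus_pos"))
  expect_equal(lapply(back2$arms, `[[`, "label_positions"),
               lapply(big$arms, `[[`, "label_positions"))

  # empty set -> header-only file that reads back empty
  p3 <- withr::local_tempfile(fileext = ".cmap")
  write_reference(reference_set(list()), p3)
  expect_true(all(grepl("^#", readLines(p3))))
  expect_equal(length(read_reference(p3)), 0L)
})

test_that("malformed or inconsistent reference input fails with context", {
  bad <- withr::local_tempfile(fileext = ".cmap")
  writeLines(c("#h arm_id\tlabel_index\tposition_bp\tterminus_bp",
               "3q\t1\t50000\t400000",
               "3q\t2\t20000\t400000"), bad)
  expect_error(read_reference(bad, signature_min = 1), "3q",
               class = "smta_validation_error")

  bad2 <- withr::local_tempfile(fileext = ".cmap")
  writeLines(c("#h arm_id\tlabel_index\tposition_bp\tterminus_bp",
               "1q\t1\tnot_a_number\t400000"), bad2)
  expect_error(read_reference(bad2), "line 2", class = "smta_format_error")

  bad3 <- withr::local_tempfile(fileext = ".cmap")
  writeLines("1q\t1\t300000\t400000", bad3)
  expect_error(read_reference(bad3), "header", class = "smta_format_error")
  # the tsv dialect takes the same rows without header enforcement
  expect_equal(length(read_reference(bad3, dialect = "tsv",
                                     signature_min = 1)), 1L)

  expect_error(reference_arm("1p", c(10, 20, 20), 100),
               "strictly increasing", class = "smta_validation_error")
  expect_error(reference_set(list(reference_arm("1p", c(1, 2), 10),
                                  reference_arm("1p", c(1, 2), 10)),
                             signature_min = 1),
               "duplicate", class = "smta_validation_error")
  # too sparse a signature window names the offending arm
  sparse <- reference_arm("5q", c(1000, 2000, 300000), 400000)
  expect_error(reference_set(list(sparse), signature_min = 12), "5q",
               class = "smta_validation_error")
})

test_that("genomic orientation mirrors p-arm coordinates at load", {
  path <- withr::local_tempfile(fileext = ".cmap")
  writeLines(c("#h arm_id\tlabel_index\tposition_bp\tterminus_bp",
               sprintf("7p\t%d\t%d\t100000", 1:3, c(10000, 30000, 80000)),
               sprintf("7q\t%d\t%d\t100000", 1:3, c(10000, 30000, 80000))),
             path)
  rs <- read_reference(path, signature_min = 1, orientation = "genomic")
  # p arm mirrored: terminus - pos, re-sorted; q arm untouched
  expect_equal(rs$arms[["7p"]]$label_positions, c(20000, 70000, 90000))
  expect_equal(rs$arms[["7q"]]$label_positions, c(10000, 30000, 80000))
})

test_that("synthesized spacings are exponential and deterministic", {
  a <- synthesize_reference(n_arms = 4, seed = 9)
  b <- synthesize_reference(n_arms = 4, seed = 9)
  expect_identical(a, b)

  # one long arm: ~10,000 spacings; mean within 3 SE of 100/rate kb
  long <- synthesize_reference(n_arms = 1, labels_per_100kb = 15,
                               arm_length_kb = 68000, seed = 21)
  gaps <- diff(long$arms[[1]]$label_positions) / 1000
  expect_gt(length(gaps), 9000)
  mu <- 100 / 15
  se <- mu / sqrt(length(gaps))  # sd of an exponential equals its mean
  expect_lt(abs(mean(gaps) - mu), 3 * se)
  # Kolmogorov-Smirnov non-rejection at alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 1 / mu))
  expect_gt(ks$p.value, 0.01)
})

test_that("arm signatures are mutually distinguishable", {
  rs <- synthesize_reference(n_arms = 6, seed = 13)
  D <- check_distinguishability(rs)
  expect_equal(dim(D), c(6L, 6L))
  expect_equal(D, t(D))
  off <- D[upper.tri(D)]
  expect_true(all(off < 0.5 * min(diag(D))))

  # a duplicated arm is indistinguishable from its copy
  dup <- reference_set(list(
    reference_arm("1q", rs$arms[[1]]$label_positions,
                  rs$arms[[1]]$terminus_pos),
    reference_arm("2q", rs$arms[[1]]$label_positions,
                  rs$arms[[1]]$terminus_pos)))
  Dd <- check_distinguishability(dup)
  expect_equal(Dd[1, 2], Dd[1, 1])

  # single arm: 1x1 self-score matrix
  one <- reference_set(list(rs$arms[[1]]))
  expect_equal(dim(check_distinguishability(one)), c(1L, 1L))
})
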