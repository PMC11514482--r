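# Cohort statistics: per-arm and overall summary tables of chromosome-end
# frequencies and telomere means, cohort comparisons (fold changes, percent
# changes, 2x2 tests, Welch), and the rendered report.

# Rendering convention for percentages: one decimal at or above 1%, two
# significant figures below (so 0.3636 renders "0.36", matching how small
# frequencies are printed in per-cohort summary tables).
fmt_pct <- function(x) {
  ifelse(!is.finite(x), NA_character_,
         ifelse(x >= 0.995 | x == 0, sprintf("%.1f", x), sprintf("%.2g", x)))
}

#' Summarise end-feature calls for one cohort
#'
#' `UNCLASSIFIED` molecules are removed before any denominator is formed.
#' Frequencies are `100 * events / classified molecules`; the end-telomere
#' mean is taken over `END_TEL` telomere lengths only (telomere-free ends are
#' excluded by construction) and the fusion-with-ITS mean over `ITS_PLUS`
#' lengths only. Values are kept at full precision; rounding happens only in
#' [render_report()] and print methods.
#'
#' @param calls Data frame of end-feature calls (see [classify_cohort()]).
#' @param cohort Cohort tag; defaults to the single tag present in `calls`.
#' @param min_arm_n Arms with fewer classified molecules than this render
#'   their mean cells as NA in the report (the values are still computed).
#' @return An object of class `smta_cohort_summary` with `per_arm` and
#'   `overall` data frames.
#' @export
summarize_cohort <- function(calls, cohort = NULL, min_arm_n = 5) {
  keep <- calls[calls$category != "UNCLASSIFIED", , drop = FALSE]
  if (!nrow(keep))
    smta_stop("no classified molecules to summarise", "smta_summary_error")
  cohort <- cohort %||% paste(unique(keep$cohort), collapse = "+")
  one <- function(d, arm) {
    n <- nrow(d)
    et <- d$telomere_kb[d$category == "END_TEL"]
    ip <- d$telomere_kb[d$category == "ITS_PLUS"]
    data.frame(
      arm_id = arm, n_molecules = n,
      n_end_tel = sum(d$category == "END_TEL"),
      n_tfe = sum(d$category == "TFE"),
      n_its_plus = sum(d$category == "ITS_PLUS"),
      n_its_minus = sum(d$category == "ITS_MINUS"),
      end_tel_mean_kb = if (length(et)) mean(et, na.rm = TRUE) else NA_real_,
      end_tel_sd_kb = if (length(et) > 1) sd(et, na.rm = TRUE) else NA_real_,
      its_plus_mean_kb = if (length(ip)) mean(ip, na.rm = TRUE) else NA_real_,
      tfe_pct = 100 * sum(d$category == "TFE") / n,
      its_plus_pct = 100 * sum(d$category == "ITS_PLUS") / n,
      its_minus_pct = 100 * sum(d$category == "ITS_MINUS") / n,
      stringsAsFactors = FALSE)
  }
  arms <- sort(unique(keep$arm_id))
  per_arm <- do.call(rbind, lapply(arms, function(a)
    one(keep[keep$arm_id == a, , drop = FALSE], a)))
  overall <- one(keep, "overall")
  structure(list(cohort = cohort, per_arm = per_arm, overall = overall,
                 n_unclassified = sum(calls$category == "UNCLASSIFIED"),
                 min_arm_n = min_arm_n),
            class = "smta_cohort_summary")
}

#' @export
print.smta_cohort_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<cohort %s: %d classified molecules over %d arms (%d unclassified)>\n",
              x$cohort, o$n_molecules, nrow(x$per_arm), x$n_unclassified))
  cat(sprintf("  End Tel mean %.1f kb | ITS+ mean %.1f kb | ITS+ %s%% (%d/%d) | ITS- %s%% (%d/%d) | TFE %s%% (%d/%d)\n",
              o$end_tel_mean_kb, o$its_plus_mean_kb,
              fmt_pct(o$its_plus_pct), o$n_its_plus, o$n_molecules,
              fmt_pct(o$its_minus_pct), o$n_its_minus, o$n_molecules,
              fmt_pct(o$tfe_pct), o$n_tfe, o$n_molecules))
  invisible(x)
}

#' Fold change between two frequencies or means
#'
#' @param value_a,value_b Numerator and baseline values; `value_b = 0` yields
#'   `Inf` with a `zero_baseline` attribute (a frequency rising from 0%).
#' @return The ratio `value_a / value_b`.
#' @export
fold_change <- function(value_a, value_b) {
  if (value_b == 0)
    return(structure(Inf, zero_baseline = TRUE))
  value_a / value_b
}

#' Signed percent change between two values
#'
#' @param value_a,value_b New value and baseline; `value_b` must be positive.
#' @return `100 * (value_a - value_b) / value_b`.
#' @export
percent_change <- function(value_a, value_b) {
  if (value_b == 0)
    return(structure(Inf, zero_baseline = TRUE))
  100 * (value_a - value_b) / value_b
}

new_comparison <- function(metric, cohort_a, cohort_b, value_a, value_b,
                           p_value, test_name) {
  structure(list(metric = metric, cohort_a = cohort_a, cohort_b = cohort_b,
                 value_a = value_a, value_b = value_b,
                 fold_change = fold_change(value_a, value_b),
                 percent_change = percent_change(value_a, value_b),
                 p_value = p_value, test_name = test_name),
            class = "smta_comparison")
}

#' @export
print.smta_comparison <- function(x, ...) {
  cat(sprintf("<%s: %s %.4g vs %s %.4g | fold %.3g | %+.3g%% | p = %.4g (%s)>\n",
              x$metric, x$cohort_a, x$value_a, x$cohort_b, x$value_b,
              x$fold_change, x$percent_change, x$p_value, x$test_name))
  invisible(x)
}

two_prop_z <- function(count_a, n_a, count_b, n_b) {
  p1 <- count_a / n_a; p2 <- count_b / n_b
  pp <- (count_a + count_b) / (n_a + n_b)
  if (pp <= 0 || pp >= 1) return(1)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n_a + 1 / n_b))
  2 * pnorm(-abs(z))
}

#' Compare event frequencies between two cohorts
#'
#' Two-sided p-value of the 2x2 contingency table (events vs non-events in
#' each cohort) under the selected test. The chi-square and z tests are
#' uncorrected; degenerate tables (no events, or all events, in both
#' cohorts) return p = 1.
#'
#' @param count_a,n_a,count_b,n_b Event counts and totals.
#' @param test `"fisher_exact"`, `"chi2"`, or `"two_prop_z"`.
#' @param cohort_a,cohort_b Labels carried into the result.
#' @param metric Metric label carried into the result.
#' @return An `smta_comparison`; `value_a`/`value_b` are the percentages.
#' @export
compare_frequencies <- function(count_a, n_a, count_b, n_b,
                                test = c("fisher_exact", "chi2",
                                         "two_prop_z"),
                                cohort_a = "A", cohort_b = "B",
                                metric = "frequency") {
  test <- match.arg(test)
  stopifnot(count_a >= 0, count_b >= 0, count_a <= n_a, count_b <= n_b)
  tab <- matrix(c(count_a, n_a - count_a, count_b, n_b - count_b), nrow = 2,
                byrow = TRUE)
  degenerate <- (count_a + count_b == 0) || (count_a + count_b == n_a + n_b)
  p <- if (degenerate) 1
  else switch(test,
    fisher_exact = fisher.test(tab)$p.value,
    chi2 = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
    two_prop_z = two_prop_z(count_a, n_a, count_b, n_b))
  new_comparison(metric, cohort_a, cohort_b, 100 * count_a / n_a,
                 100 * count_b / n_b, p, test)
}

#' Compare telomere length distributions between two cohorts
#'
#' Two-sided Welch t-test on the length samples; if both samples are
#' degenerate (zero variance) the p-value shortcuts to 1 for equal means and
#' 0 otherwise.
#'
#' @param lengths_a,lengths_b Telomere lengths (kb), at least 2 each.
#' @param cohort_a,cohort_b,metric Labels carried into the result.
#' @return An `smta_comparison`; `value_a`/`value_b` are the means.
#' @export
compare_lengths <- function(lengths_a, lengths_b, cohort_a = "A",
                            cohort_b = "B", metric = "end_tel_mean_kb") {
  lengths_a <- lengths_a[is.finite(lengths_a)]
  lengths_b <- lengths_b[is.finite(lengths_b)]
  stopifnot(length(lengths_a) >= 2, length(lengths_b) >= 2)
  ma <- mean(lengths_a); mb <- mean(lengths_b)
  if (sd(lengths_a) == 0 && sd(lengths_b) == 0) {
    p <- if (isTRUE(all.equal(ma, mb))) 1 else 0
  } else {
    p <- t.test(lengths_a, lengths_b)$p.value
  }
  new_comparison(metric, cohort_a, cohort_b, ma, mb, p, "welch_t")
}

#' Compare two cohorts metric by metric
#'
#' Overall comparisons of the three fusion/TFE frequencies (selected 2x2
#' test) and the two telomere means (Welch), plus the same frequency
#' comparisons per arm with Benjamini-Hochberg adjusted p-values per metric
#' (reported alongside, never instead of, the raw p-values).
#'
#' @param calls_a,calls_b End-feature call tables of the two cohorts.
#' @param test 2x2 test for frequencies, see [compare_frequencies()].
#' @return List of class `smta_cohort_comparison` with `overall` and
#'   `per_arm` data frames.
#' @export
compare_cohorts <- function(calls_a, calls_b,
                            test = c("fisher_exact", "chi2", "two_prop_z")) {
  test <- match.arg(test)
  sa <- summarize_cohort(calls_a)
  sb <- summarize_cohort(calls_b)
  freq_row <- function(metric, field, da, db, arm = "overall") {
    cmp <- compare_frequencies(da[[field]], da$n_molecules,
                               db[[field]], db$n_molecules, test,
                               sa$cohort, sb$cohort, metric)
    data.frame(arm_id = arm, metric = metric,
               value_a = cmp$value_a, value_b = cmp$value_b,
               fold_change = cmp$fold_change,
               percent_change = cmp$percent_change,
               p_value = cmp$p_value, test_name = cmp$test_name,
               stringsAsFactors = FALSE)
  }
  ka <- calls_a[calls_a$category != "UNCLASSIFIED", ]
  kb <- calls_b[calls_b$category != "UNCLASSIFIED", ]
  len_row <- function(metric, cat) {
    la <- ka$telomere_kb[ka$category == cat]
    lb <- kb$telomere_kb[kb$category == cat]
    if (length(la) < 2 || length(lb) < 2) return(NULL)
    cmp <- compare_lengths(la, lb, sa$cohort, sb$cohort, metric)
    data.frame(arm_id = "overall", metric = metric, value_a = cmp$value_a,
               value_b = cmp$value_b, fold_change = cmp$fold_change,
               percent_change = cmp$percent_change, p_value = cmp$p_value,
               test_name = cmp$test_name, stringsAsFactors = FALSE)
  }
  freq_fields <- c(its_plus_pct = "n_its_plus", its_minus_pct = "n_its_minus",
                   tfe_pct = "n_tfe")
  overall <- rbind(
    do.call(rbind, lapply(names(freq_fields), function(m)
      freq_row(m, freq_fields[[m]], sa$overall, sb$overall))),
    len_row("end_tel_mean_kb", "END_TEL"),
    len_row("its_plus_mean_kb", "ITS_PLUS"))
  arms <- intersect(sa$per_arm$arm_id, sb$per_arm$arm_id)
  per_arm <- do.call(rbind, lapply(arms, function(a) {
    da <- sa$per_arm[sa$per_arm$arm_id == a, ]
    db <- sb$per_arm[sb$per_arm$arm_id == a, ]
    do.call(rbind, lapply(names(freq_fields), function(m)
      freq_row(m, freq_fields[[m]], da, db, a)))
  }))
  if (!is.null(per_arm) && nrow(per_arm)) {
    per_arm$p_adj_bh <- NA_real_
    for (m in unique(per_arm$metric)) {
      i <- per_arm$metric == m
      per_arm$p_adj_bh[i] <- p.adjust(per_arm$p_value[i], "BH")
    }
  }
  structure(list(cohort_a = sa$cohort, cohort_b = sb$cohort,
                 overall = overall, per_arm = per_arm, test = test),
            class = "smta_cohort_comparison")
}

report_cells <- function(s, min_arm_n) {
  o <- s$overall
  c(cohort = s$cohort,
    end_tel_mean_kb = sprintf("%.1f", o$end_tel_mean_kb),
    its_plus_mean_kb = sprintf("%.1f", o$its_plus_mean_kb),
    its_plus_pct = sprintf("%s (%d/%d)", fmt_pct(o$its_plus_pct),
                           o$n_its_plus, o$n_molecules),
    its_minus_pct = sprintf("%s (%d/%d)", fmt_pct(o$its_minus_pct),
                            o$n_its_minus, o$n_molecules),
    tfe_pct = sprintf("%s (%d/%d)", fmt_pct(o$tfe_pct), o$n_tfe,
                      o$n_molecules))
}

#' Render the cohort report
#'
#' Writes a summary-table CSV whose frequency cells read `"pct (events/n)"`,
#' a per-arm CSV (mean cells blanked below `min_arm_n` molecules), and a JSON
#' file with the full-precision values. Output is byte-stable given the same
#' inputs.
#'
#' @param summaries List of `smta_cohort_summary` (one or two cohorts).
#' @param comparisons Optional `smta_cohort_comparison`; adds a p-value row.
#' @param path Output CSV path; the per-arm CSV and JSON sit alongside with
#'   `_per_arm.csv` / `.json` suffixes.
#' @return Named vector of the written paths, invisibly.
#' @export
render_report <- function(summaries, comparisons = NULL, path) {
  if (inherits(summaries, "smta_cohort_summary")) summaries <- list(summaries)
  header <- c("cohort", "end_tel_mean_kb", "its_plus_mean_kb",
              "its_plus_pct", "its_minus_pct", "tfe_pct")
  rows <- vapply(summaries, function(s)
    paste(report_cells(s, s$min_arm_n), collapse = ","), character(1))
  lines <- c(paste(header, collapse = ","), rows)
  if (!is.null(comparisons)) {
    ov <- comparisons$overall
    pv <- function(m) {
      i <- match(m, ov$metric)
      if (is.na(i)) "" else sprintf("%.4g", ov$p_value[i])
    }
    lines <- c(lines, paste(c("p_value", pv("end_tel_mean_kb"),
                              pv("its_plus_mean_kb"), pv("its_plus_pct"),
                              pv("its_minus_pct"), pv("tfe_pct")),
                            collapse = ","))
  }
  writeLines(lines, path)
  per_arm_path <- sub("\\.csv$", "_per_arm.csv", path)
  if (per_arm_path == path) per_arm_path <- paste0(path, "_per_arm.csv")
  pa <- do.call(rbind, lapply(summaries, function(s) {
    d <- s$per_arm
    low <- d$n_molecules < s$min_arm_n
    d$end_tel_mean_kb[low] <- NA
    d$end_tel_sd_kb[low] <- NA
    d$its_plus_mean_kb[low] <- NA
    cbind(cohort = s$cohort, d)
  }))
  utils::write.csv(pa, per_arm_path, row.names = FALSE, na = "")
  json_path <- sub("\\.csv$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  payload <- list(
    cohorts = lapply(summaries, function(s)
      list(cohort = s$cohort, overall = s$overall,
           n_unclassified = s$n_unclassified)),
    comparisons = if (!is.null(comparisons)) comparisons$overall)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(report = path, per_arm = per_arm_path, json = json_path))
}
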