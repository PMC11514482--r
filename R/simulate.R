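# Single-molecule simulator: draws labelled molecules from chromosome ends
# with ground-truth end-feature annotations, emulating the two-colour optical
# measurement process (sizing noise, label dropout, false labels, resolution
# merging, fluorescence yield, random nanochannel orientation).

#' Event rates of the two study cohorts
#'
#' Chromosome-end event probabilities computed from the event counts of the
#' telomere-targeted (`"sgTelo"`) and non-targeting control (`"sgNS"`)
#' cohorts: 161/42/86 fusions-with-ITS / fusions-without-ITS / telomere-free
#' ends among 1061 molecules, and 59/4/55 among 1100, with end telomeres as
#' the remainder.
#'
#' @param cohort `"sgTelo"` or `"sgNS"`.
#' @return Named probability vector over
#'   `end_tel`, `tfe`, `its_plus`, `its_minus`.
#' @export
cohort_event_rates <- function(cohort = c("sgTelo", "sgNS")) {
  cohort <- match.arg(cohort)
  if (cohort == "sgTelo")
    c(end_tel = 772, tfe = 86, its_plus = 161, its_minus = 42) / 1061
  else
    c(end_tel = 982, tfe = 55, its_plus = 59, its_minus = 4) / 1100
}

#' Simulation configuration
#'
#' Defaults are the study conditions of the telomere-targeted cohort:
#' the published cohort event rates, log-normal telomere lengths around 11.5 kb,
#' about 30 molecules per arm, and measurement noise typical of nanochannel
#' optical maps.
#'
#' @param event_rates Named probabilities for `end_tel`, `tfe`, `its_plus`,
#'   `its_minus`; must lie in `[0, 1]` and sum to at most 1. Any remainder is
#'   the rate of unclassifiable debris molecules (interstitial fragments not
#'   touching a terminus).
#' @param telomere_mean_kb,telomere_cv Mean and coefficient of variation of
#'   the log-normal telomere length model.
#' @param sizing_error_cv Multiplicative per-interval fragment-sizing noise.
#' @param p_missing_label Label dropout probability.
#' @param false_labels_per_100kb Poisson rate of spurious labels.
#' @param resolution_kb Minimum resolvable label spacing: closer molecule
#'   labels collapse to their midpoint.
#' @param kb_per_pixel Optical stretch calibration (kb per camera pixel).
#' @param intensity_per_kb,intensity_cv Fluorescence yield of telomeric
#'   tracts (arbitrary units per kb) and its relative noise.
#' @param molecules_per_arm Molecules drawn per arm when `n_molecules` is not
#'   given to [simulate_cohort()].
#' @param min_molecule_kb,max_molecule_kb Backbone length range of the
#'   assignable (subtelomeric) part of each molecule.
#' @param partner_kb_range,partner_label_range Length (kb) and label-count
#'   range of the short, unassignable partner fragment joined in fusion
#'   events; kept below the assignability floor by construction.
#' @param tfe_erosion_max_kb Telomere-free ends are truncated uniformly up to
#'   this far proximal of the terminus.
#' @param flip_prob Probability a molecule is reversed end-for-end
#'   (nanochannel orientation is arbitrary).
#' @param seed Integer seed; simulation is deterministic given it.
#' @return An object of class `smta_sim_config`.
#' @export
sim_config <- function(event_rates = cohort_event_rates("sgTelo"),
                       telomere_mean_kb = 11.5, telomere_cv = 0.35,
                       sizing_error_cv = 0.03, p_missing_label = 0.10,
                       false_labels_per_100kb = 1, resolution_kb = 1.5,
                       kb_per_pixel = 0.5, intensity_per_kb = 100,
                       intensity_cv = 0.10, molecules_per_arm = 30,
                       min_molecule_kb = 150, max_molecule_kb = 300,
                       partner_kb_range = c(20, 80),
                       partner_label_range = c(2, 8),
                       tfe_erosion_max_kb = 5, flip_prob = 0.5, seed = 1) {
  need <- c("end_tel", "tfe", "its_plus", "its_minus")
  if (!all(need %in% names(event_rates)))
    smta_stop(sprintf("event_rates must name %s", paste(need, collapse = ", ")),
              "smta_validation_error")
  event_rates <- event_rates[need]
  if (any(event_rates < 0) || any(event_rates > 1) || sum(event_rates) > 1 + 1e-9)
    smta_stop("event_rates must lie in [0,1] and sum to at most 1",
              "smta_validation_error")
  stopifnot(telomere_mean_kb > 0, telomere_cv >= 0, sizing_error_cv >= 0,
            p_missing_label >= 0, p_missing_label < 1,
            false_labels_per_100kb >= 0, resolution_kb >= 0,
            kb_per_pixel > 0, intensity_per_kb > 0, intensity_cv >= 0,
            molecules_per_arm >= 1,
            min_molecule_kb > 0, max_molecule_kb >= min_molecule_kb,
            partner_kb_range[1] > 0, diff(partner_kb_range) >= 0,
            flip_prob >= 0, flip_prob <= 1)
  structure(as.list(environment())[c(
    "event_rates", "telomere_mean_kb", "telomere_cv", "sizing_error_cv",
    "p_missing_label", "false_labels_per_100kb", "resolution_kb",
    "kb_per_pixel", "intensity_per_kb", "intensity_cv", "molecules_per_arm",
    "min_molecule_kb", "max_molecule_kb", "partner_kb_range",
    "partner_label_range", "tfe_erosion_max_kb", "flip_prob", "seed")],
    class = "smta_sim_config")
}

#' @export
print.smta_sim_config <- function(x, ...) {
  r <- x$event_rates
  cat(sprintf(
    "<sim config: end_tel %.3f, tfe %.3f, its+ %.3f, its- %.3f (debris %.3f)\n",
    r["end_tel"], r["tfe"], r["its_plus"], r["its_minus"],
    max(0, 1 - sum(r))))
  cat(sprintf("  telomere ~ lognormal(mean %g kb, cv %g); seed %d>\n",
              x$telomere_mean_kb, x$telomere_cv, x$seed))
  invisible(x)
}

# Log-normal draw parameterised by mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Observed red-signal measurements for telomeric tracts of known length:
# extent in pixels (sizing noise over kb_per_pixel) and integrated intensity
# (yield per kb with multiplicative noise). Shared by the molecule simulator
# and the quantification tests.
#' Simulate the red-channel signal of telomeric tracts
#'
#' @param true_kb True tract lengths (kb).
#' @param config [sim_config()].
#' @return Data frame with `true_kb`, `extent_px`, `intensity`.
#' @export
simulate_red_signal <- function(true_kb, config = sim_config()) {
  n <- length(true_kb)
  extent_kb <- true_kb * pmax(rnorm(n, 1, config$sizing_error_cv), 0)
  intensity <- true_kb * config$intensity_per_kb *
    pmax(rnorm(n, 1, config$intensity_cv), 0)
  data.frame(true_kb = true_kb, extent_px = extent_kb / config$kb_per_pixel,
             intensity = intensity)
}

new_molecule <- function(molecule_id, length_kb, green_labels, red_segments,
                         cohort) {
  structure(list(molecule_id = molecule_id, length_kb = length_kb,
                 green_labels = green_labels, red_segments = red_segments,
                 cohort = cohort),
            class = "smta_molecule")
}

#' @export
print.smta_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s [%s]: %.1f kb, %d green labels, %d red segments>\n",
              x$molecule_id, x$cohort, x$length_kb, length(x$green_labels),
              nrow(x$red_segments)))
  invisible(x)
}

empty_reds <- function() {
  data.frame(start_kb = numeric(0), end_kb = numeric(0),
             intensity = numeric(0))
}

# Distal labels of `arm` inside a window of length L ending at the terminus,
# as molecule-local coordinates in (0, L).
distal_labels <- function(arm, L) {
  term <- arm$terminus_pos / 1000
  lab <- arm$label_positions / 1000
  lab[lab > term - L] - (term - L)
}

# Apply the measurement model to an ideal molecule: dropout, false labels,
# per-interval sizing noise, resolution merging, random flip.
apply_noise <- function(g, reds, total, config) {
  if (config$p_missing_label > 0 && length(g))
    g <- g[runif(length(g)) >= config$p_missing_label]
  nf <- rpois(1, config$false_labels_per_100kb * total / 100)
  if (nf > 0) g <- c(g, runif(nf, 0, total))
  g <- sort(unique(g))
  red_pts <- if (nrow(reds)) c(reds$start_kb, reds$end_kb) else numeric(0)
  if (config$sizing_error_cv > 0) {
    b <- sort(unique(c(0, g, red_pts, total)))
    d <- diff(b)
    f <- pmax(rnorm(length(d), 1, config$sizing_error_cv), 0.2)
    nb <- c(0, cumsum(d * f))
    remap <- function(x) nb[match(x, b)]
    g <- remap(g)
    if (nrow(reds)) {
      reds$start_kb <- remap(reds$start_kb)
      reds$end_kb <- remap(reds$end_kb)
    }
    total <- nb[length(nb)]
  }
  g <- collapse_labels(g, config$resolution_kb)
  if (runif(1) < config$flip_prob) {
    g <- sort(total - g)
    if (nrow(reds)) {
      new_start <- total - reds$end_kb
      reds$end_kb <- total - reds$start_kb
      reds$start_kb <- new_start
    }
  }
  list(g = g, reds = reds, total = total)
}

# Draw a short distal fragment (below the assignability floor) from a random
# partner arm; returns label distances from the partner terminus, the
# fragment length, and the partner arm id.
draw_partner <- function(refset, exclude_arm, config, max_tries = 100) {
  ids <- setdiff(arm_ids(refset), exclude_arm)
  for (k in seq_len(max_tries)) {
    pid <- if (length(ids) == 1L) ids else sample(ids, 1)
    pl <- runif(1, config$partner_kb_range[1], config$partner_kb_range[2])
    arm <- refset$arms[[pid]]
    term <- arm$terminus_pos / 1000
    d <- term - arm$label_positions / 1000
    d <- sort(d[d < pl])
    if (length(d) >= config$partner_label_range[1] &&
        length(d) <= config$partner_label_range[2])
      return(list(arm = pid, d = d, len = pl))
  }
  smta_stop("could not draw a partner fragment within the label-count range",
            "smta_generation_error")
}

#' Simulate a cohort of single molecules with ground truth
#'
#' Each molecule takes the distal label pattern of one reference arm and one
#' chromosome-end event: an end telomere (`END_TEL`, a terminal telomeric
#' tract painted red), a telomere-free end (`TFE`, truncated at/near the
#' terminus with no red), a fusion retaining an interstitial telomeric
#' sequence (`ITS_PLUS`, arm - red tract - short partner fragment), a fusion
#' without one (`ITS_MINUS`, arm - short partner fragment, no red), or
#' unclassifiable debris (`DEBRIS`, an interstitial fragment, at the residual
#' rate `1 - sum(event_rates)`). The measurement model (sizing noise,
#' dropout, false labels, resolution merging, fluorescence yield, random
#' orientation) is then applied.
#'
#' @param refset An `smta_ref_set`.
#' @param config [sim_config()]; the draw is deterministic given
#'   `config$seed`.
#' @param cohort Cohort tag stored on every molecule.
#' @param n_molecules Total molecules; defaults to
#'   `molecules_per_arm * n_arms`. Arms are filled by round-robin quota.
#' @return List with `molecules` (list of `smta_molecule`) and `truth`
#'   (data frame: `molecule_id`, `true_category`, `true_arm`,
#'   `true_partner_arm`, `true_telomere_kb`).
#' @export
simulate_cohort <- function(refset, config = sim_config(), cohort = "cohort",
                            n_molecules = NULL) {
  stopifnot(inherits(refset, "smta_ref_set"), length(refset$arms) >= 1)
  n <- n_molecules %||% (config$molecules_per_arm * length(refset$arms))
  min_term <- min(vapply(refset$arms, function(a) a$terminus_pos, numeric(1)))
  if (config$min_molecule_kb * 1000 > min_term)
    smta_stop("min_molecule_kb exceeds the shortest reference arm segment",
              "smta_generation_error")
  ids <- arm_ids(refset)
  classes <- c(names(config$event_rates), "DEBRIS")
  probs <- c(config$event_rates, max(0, 1 - sum(config$event_rates)))
  with_seed(config$seed, {
    arms_v <- rep(ids, length.out = n)
    cats_v <- toupper(sample(classes, n, replace = TRUE, prob = probs))
    mols <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      arm <- refset$arms[[arms_v[i]]]
      term <- arm$terminus_pos / 1000
      L <- min(runif(1, config$min_molecule_kb, config$max_molecule_kb), term)
      cat_i <- cats_v[i]
      partner <- NA_character_
      telo <- NA_real_
      reds <- empty_reds()
      if (cat_i == "END_TEL") {
        g <- distal_labels(arm, L)
        telo <- rlnorm_mean_cv(1, config$telomere_mean_kb, config$telomere_cv)
        reds <- data.frame(start_kb = L, end_kb = L + telo, intensity = NA)
        total <- L + telo
      } else if (cat_i == "TFE") {
        Lc <- L - runif(1, 0, config$tfe_erosion_max_kb)
        g <- distal_labels(arm, L)
        g <- g[g <= Lc]
        total <- Lc
      } else if (cat_i == "ITS_PLUS") {
        g <- distal_labels(arm, L)
        telo <- rlnorm_mean_cv(1, config$telomere_mean_kb, config$telomere_cv)
        p <- draw_partner(refset, arm$arm_id, config)
        partner <- p$arm
        junction <- L + telo
        g <- c(g, junction + p$d)
        reds <- data.frame(start_kb = L, end_kb = junction, intensity = NA)
        total <- junction + p$len
      } else if (cat_i == "ITS_MINUS") {
        g <- distal_labels(arm, L)
        p <- draw_partner(refset, arm$arm_id, config)
        partner <- p$arm
        g <- c(g, L + p$d)
        total <- L + p$len
      } else {  # DEBRIS: interstitial window ending well short of the terminus
        hi <- term - L - 30
        if (hi <= 0) hi <- term / 10
        a0 <- runif(1, 0, hi)
        lab <- arm$label_positions / 1000
        g <- lab[lab >= a0 & lab <= a0 + L] - a0
        total <- L
      }
      if (nrow(reds))
        reds$intensity <- telo * config$intensity_per_kb *
          pmax(rnorm(1, 1, config$intensity_cv), 0)
      obs <- apply_noise(g, reds, total, config)
      mid <- sprintf("%s_%05d", cohort, i)
      mols[[i]] <- new_molecule(mid, obs$total, obs$g, obs$reds, cohort)
      truth[[i]] <- data.frame(
        molecule_id = mid, true_category = cat_i, true_arm = arms_v[i],
        true_partner_arm = partner, true_telomere_kb = telo,
        stringsAsFactors = FALSE)
    }
    list(molecules = mols, truth = do.call(rbind, truth))
  })
}

#' Write molecules in the minimal BNX dialect
#'
#' Per-molecule block: a `0` line (`id`, `length_kb`, `cohort`), a `1` line
#' (green label positions, kb), and one `2` line per red segment
#' (`start_kb`, `end_kb`, `intensity`). Comment lines start `#`.
#'
#' @param mols List of molecules.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# smtaom molecules (minimal BNX dialect)", con)
  for (m in mols) {
    writeLines(sprintf("0\t%s\t%.4f\t%s", m$molecule_id, m$length_kb,
                       m$cohort), con)
    writeLines(paste(c("1", sprintf("%.4f", m$green_labels)),
                     collapse = "\t"), con)
    if (nrow(m$red_segments))
      writeLines(sprintf("2\t%.4f\t%.4f\t%.4f", m$red_segments$start_kb,
                         m$red_segments$end_kb, m$red_segments$intensity),
                 con)
  }
  invisible(path)
}

#' Read molecules from the minimal BNX dialect
#'
#' @param path Input path.
#' @return List of `smta_molecule`.
#' @export
read_bnx <- function(path) {
  if (!file.exists(path))
    smta_stop(sprintf("file not found: %s", path), "smta_format_error")
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  cur <- NULL
  flush_cur <- function(cur) {
    if (is.null(cur)) return(NULL)
    new_molecule(cur$id, cur$len, cur$g,
                 if (length(cur$reds))
                   do.call(rbind, cur$reds) else empty_reds(),
                 cur$cohort)
  }
  num <- function(x, k) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) smta_stop(sprintf("line %d: non-numeric field", k),
                            "smta_format_error")
    v
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl("^\\s*(#|$)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "0") {
      if (length(f) != 4L)
        smta_stop(sprintf("line %d: '0' line needs id, length_kb, cohort", k),
                  "smta_format_error")
      m <- flush_cur(cur)
      if (!is.null(m)) mols[[length(mols) + 1L]] <- m
      cur <- list(id = f[2], len = num(f[3], k), cohort = f[4],
                  g = numeric(0), reds = list())
    } else if (f[1] == "1") {
      if (is.null(cur))
        smta_stop(sprintf("line %d: '1' line before any '0' line", k),
                  "smta_format_error")
      cur$g <- if (length(f) > 1L) num(f[-1], k) else numeric(0)
    } else if (f[1] == "2") {
      if (is.null(cur))
        smta_stop(sprintf("line %d: '2' line before any '0' line", k),
                  "smta_format_error")
      if (length(f) != 4L)
        smta_stop(sprintf("line %d: '2' line needs start, end, intensity", k),
                  "smta_format_error")
      v <- num(f[-1], k)
      if (v[1] >= v[2])
        smta_stop(sprintf("line %d: red segment start must be below end", k),
                  "smta_format_error")
      cur$reds[[length(cur$reds) + 1L]] <-
        data.frame(start_kb = v[1], end_kb = v[2], intensity = v[3])
    } else {
      smta_stop(sprintf("line %d: unknown record type '%s'", k, f[1]),
                "smta_format_error")
    }
  }
  m <- flush_cur(cur)
  if (!is.null(m)) mols[[length(mols) + 1L]] <- m
  mols
}
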