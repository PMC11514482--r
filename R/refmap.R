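# Reference label maps: one per chromosome arm, oriented toward the telomere
# terminus. Coordinates are 0-based bp, arm-local, increasing toward the
# terminus for both p and q arms (one canonical orientation downstream).

#' Reference label map of one chromosome arm
#'
#' Holds the motif-label signature of the distal segment of a chromosome arm,
#' oriented so that increasing coordinate approaches the telomere terminus.
#'
#' @param arm_id Arm name, e.g. `"8q"`.
#' @param label_positions Strictly increasing label coordinates in bp, all
#'   below `terminus_pos`.
#' @param terminus_pos Coordinate (bp) of the chromosome end, i.e. the
#'   subtelomere/telomere boundary.
#' @param source Free-text provenance tag.
#' @return An object of class `smta_ref_arm`.
#' @export
reference_arm <- function(arm_id, label_positions, terminus_pos,
                          source = "user") {
  if (!is.character(arm_id) || length(arm_id) != 1L || !nzchar(arm_id))
    smta_stop("arm_id must be a single non-empty string",
              "smta_validation_error")
  label_positions <- as.numeric(label_positions)
  terminus_pos <- as.numeric(terminus_pos)
  if (any(!is.finite(label_positions)) || any(label_positions < 0))
    smta_stop(sprintf("arm '%s': label positions must be finite and >= 0",
                      arm_id), "smta_validation_error")
  if (is.unsorted(label_positions, strictly = TRUE))
    smta_stop(sprintf(
      "arm '%s': label positions must be strictly increasing", arm_id),
      "smta_validation_error")
  if (length(label_positions) && max(label_positions) >= terminus_pos)
    smta_stop(sprintf("arm '%s': all label positions must lie below the terminus",
                      arm_id), "smta_validation_error")
  structure(list(arm_id = arm_id, label_positions = label_positions,
                 terminus_pos = terminus_pos, source = source),
            class = "smta_ref_arm")
}

#' @export
print.smta_ref_arm <- function(x, ...) {
  cat(sprintf("<reference arm %s: %d labels, terminus %.1f kb, source %s>\n",
              x$arm_id, length(x$label_positions), x$terminus_pos / 1000,
              x$source))
  invisible(x)
}

#' Set of per-arm reference maps
#'
#' @param arms List of [reference_arm()] objects with unique arm ids.
#' @param signature_window_kb Length (kb) of the distal window whose label
#'   pattern identifies the arm.
#' @param signature_min Minimum number of labels required inside the distal
#'   signature window of every arm.
#' @return An object of class `smta_ref_set`.
#' @export
reference_set <- function(arms, signature_window_kb = 150,
                          signature_min = 12) {
  if (!length(arms)) {
    return(structure(list(arms = list(),
                          signature_window_kb = signature_window_kb,
                          signature_min = signature_min),
                     class = "smta_ref_set"))
  }
  stopifnot(all(vapply(arms, inherits, logical(1), "smta_ref_arm")))
  ids <- vapply(arms, `[[`, character(1), "arm_id")
  if (anyDuplicated(ids))
    smta_stop(sprintf("duplicate arm_id: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "smta_validation_error")
  for (a in arms) {
    lo <- a$terminus_pos - signature_window_kb * 1000
    n_sig <- sum(a$label_positions >= lo)
    if (n_sig < signature_min)
      smta_stop(sprintf(
        "arm '%s': only %d labels in the distal %g kb signature window (need >= %d)",
        a$arm_id, n_sig, signature_window_kb, signature_min),
        "smta_validation_error")
  }
  names(arms) <- ids
  structure(list(arms = arms, signature_window_kb = signature_window_kb,
                 signature_min = signature_min),
            class = "smta_ref_set")
}

#' @export
print.smta_ref_set <- function(x, ...) {
  cat(sprintf("<reference set: %d arms, signature window %g kb>\n",
              length(x$arms), x$signature_window_kb))
  invisible(x)
}

#' @export
length.smta_ref_set <- function(x) length(x$arms)

arm_ids <- function(refset) names(refset$arms)

# hg38-style arm names: 1p, 1q, 2p, ..., 22q, Xp, Xq, Yp, Yq
arm_name_pool <- function(n) {
  pool <- as.vector(t(outer(c(1:22, "X", "Y"), c("p", "q"), paste0)))
  if (n > length(pool))
    smta_stop(sprintf("at most %d arm names available", length(pool)),
              "smta_validation_error")
  pool[seq_len(n)]
}

#' Read a reference set from a minimal CMAP-dialect file
#'
#' The minimal dialect is tab-separated with comment lines starting `#` and
#' columns `arm_id`, `label_index`, `position_bp`, `terminus_bp`. The
#' `cmap_min` dialect requires a `#h` header line naming those columns; the
#' `tsv` dialect does not enforce a header.
#'
#' @param path File path.
#' @param dialect `"cmap_min"` or `"tsv"`.
#' @param signature_window_kb,signature_min Passed to [reference_set()].
#' @param orientation `"terminal"` (coordinates already increase toward the
#'   terminus; the canonical on-disk form) or `"genomic"` (p-arm coordinates
#'   run away from the terminus and are mirrored at load time).
#' @return An `smta_ref_set`.
#' @export
read_reference <- function(path, dialect = c("cmap_min", "tsv"),
                           signature_window_kb = 150, signature_min = 12,
                           orientation = c("terminal", "genomic")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    smta_stop(sprintf("file not found: %s", path), "smta_format_error")
  lines <- readLines(path, warn = FALSE)
  if (dialect == "cmap_min") {
    header <- grep("^#h\\b", lines, value = TRUE)
    if (!length(header) || !grepl("arm_id", header[1]))
      smta_stop("cmap_min dialect requires a '#h' header line naming arm_id",
                "smta_format_error")
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  recs <- list()
  for (k in keep) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      smta_stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                        k, length(f)), "smta_format_error")
    pos <- suppressWarnings(as.numeric(f[3]))
    term <- suppressWarnings(as.numeric(f[4]))
    if (is.na(pos) || is.na(term) || pos < 0 || term < 0)
      smta_stop(sprintf("line %d: position_bp/terminus_bp must be non-negative numbers",
                        k), "smta_format_error")
    recs[[length(recs) + 1L]] <-
      list(arm = f[1], idx = suppressWarnings(as.integer(f[2])),
           pos = pos, term = term)
  }
  if (!length(recs))
    return(reference_set(list(), signature_window_kb, signature_min))
  arm_v <- vapply(recs, `[[`, character(1), "arm")
  arms <- lapply(split(seq_along(recs), factor(arm_v, unique(arm_v))),
                 function(ii) {
    rr <- recs[ii]
    idx <- vapply(rr, `[[`, integer(1), "idx")
    pos <- vapply(rr, `[[`, numeric(1), "pos")[order(idx)]
    term <- unique(vapply(rr, `[[`, numeric(1), "term"))
    arm <- rr[[1]]$arm
    if (length(term) != 1L)
      smta_stop(sprintf("arm '%s': inconsistent terminus_bp values", arm),
                "smta_validation_error")
    if (orientation == "genomic" && grepl("p$", arm))
      pos <- rev(term - pos)
    if (anyDuplicated(pos))
      smta_stop(sprintf("arm '%s': duplicate label positions", arm),
                "smta_validation_error")
    if (is.unsorted(pos, strictly = TRUE))
      smta_stop(sprintf("arm '%s': label positions not sorted", arm),
                "smta_validation_error")
    reference_arm(arm, pos, term, source = basename(path))
  })
  reference_set(unname(arms), signature_window_kb, signature_min)
}

#' Write a reference set in the minimal CMAP dialect
#'
#' @param refset An `smta_ref_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(refset, path) {
  stopifnot(inherits(refset, "smta_ref_set"))
  lines <- c("# smtaom reference map (minimal CMAP dialect)",
             "#h arm_id\tlabel_index\tposition_bp\tterminus_bp")
  for (a in refset$arms) {
    n <- length(a$label_positions)
    if (n)
      lines <- c(lines, sprintf("%s\t%d\t%.1f\t%.1f", a$arm_id, seq_len(n),
                                a$label_positions, a$terminus_pos))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Synthesize a reference set with exponential label spacings
#'
#' Label occurrence of a sequence-motif labelling enzyme is emulated as a
#' Poisson process along each arm: spacings are i.i.d. exponential with mean
#' `100 / labels_per_100kb` kb. Arms are named in hg38 style (1p, 1q, ...).
#'
#' @param n_arms Number of arms (>= 1).
#' @param labels_per_100kb Expected labels per 100 kb (> 0).
#' @param signature_window_kb Distal identification window (kb).
#' @param arm_length_kb Length of the modelled distal segment of each arm (kb);
#'   the terminus sits at this coordinate.
#' @param signature_min Minimum labels required in the signature window; arms
#'   are redrawn (up to `max_retries` times) until satisfied.
#' @param seed Integer seed; the result is deterministic given it.
#' @param max_retries Redraws allowed per arm before a generation error.
#' @return An `smta_ref_set` with `source = "synthetic"` arms.
#' @export
synthesize_reference <- function(n_arms = 35, labels_per_100kb = 15,
                                 signature_window_kb = 150,
                                 arm_length_kb = 500, signature_min = 12,
                                 seed = 1, max_retries = 50) {
  stopifnot(n_arms >= 1, labels_per_100kb > 0, arm_length_kb > 0)
  mean_bp <- 100 / labels_per_100kb * 1000
  term <- arm_length_kb * 1000
  ids <- arm_name_pool(n_arms)
  with_seed(seed, {
    arms <- lapply(ids, function(id) {
      for (try in seq_len(max_retries)) {
        n_draw <- ceiling(term / mean_bp * 1.6) + 25L
        pos <- cumsum(rexp(n_draw, rate = 1 / mean_bp))
        while (pos[length(pos)] <= term)
          pos <- c(pos, pos[length(pos)] +
                     cumsum(rexp(n_draw, rate = 1 / mean_bp)))
        pos <- round(pos[pos < term], 1)
        n_sig <- sum(pos >= term - signature_window_kb * 1000)
        if (n_sig >= signature_min && !anyDuplicated(pos))
          return(reference_arm(id, pos, term, source = "synthetic"))
      }
      smta_stop(sprintf(
        "arm '%s': could not place %d labels in the signature window after %d tries (rate too low?)",
        id, signature_min, max_retries), "smta_generation_error")
    })
    reference_set(arms, signature_window_kb, signature_min)
  })
}

#' Pairwise signature distinguishability of a reference set
#'
#' Aligns the distal signature-window labels of each arm (as an ideal,
#' noise-free fragment) against every arm of the set, in both orientations and
#' with stretch fitted, and returns the matrix of best alignment scores. The
#' diagonal holds each arm's self-score; a well-separated set has every
#' off-diagonal entry well below the corresponding diagonal.
#'
#' @param refset An `smta_ref_set` with at least one arm.
#' @param params Alignment parameters, see [align_params()].
#' @return A symmetric numeric matrix with arm ids as dimnames.
#' @export
check_distinguishability <- function(refset, params = align_params()) {
  stopifnot(inherits(refset, "smta_ref_set"), length(refset$arms) >= 1)
  ids <- arm_ids(refset)
  n <- length(ids)
  frags <- lapply(refset$arms, function(a) {
    lo <- a$terminus_pos - refset$signature_window_kb * 1000
    # collapse below the resolution limit, as a measured fragment would be
    collapse_labels((a$label_positions[a$label_positions >= lo] - lo) / 1000,
                    params$ref_collapse_kb)
  })
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- best_orientation_score(frags[[i]], refset$arms[[j]], params)
  }
  pmax(S, t(S))
}

# Best stretch-fitted score of a fragment against one arm over both
# orientations (helper shared with assign_arms).
best_orientation_score <- function(frag, arm, params) {
  if (length(frag) < 2L) return(-Inf)
  fwd <- align_fragment(frag, arm, params)$score
  rev_frag <- sort(max(frag) + min(frag) - frag)
  bwd <- align_fragment(rev_frag, arm, params)$score
  max(fwd, bwd)
}
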