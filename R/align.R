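# Arm assignment by dynamic-programming alignment of label spacings.
#
# A molecule fragment either matches the distal label pattern of exactly one
# reference arm well enough (and better enough than the runner-up) to be
# assigned, or it is UNASSIGNED. All thresholds live in align_params().

#' Alignment parameters
#'
#' @param sizing_sd_kb_per_sqrt_kb Sizing-error scale: the squared-difference
#'   penalty between a reference interval and the de-stretched molecule
#'   interval is normalised by `2 * sd^2 * dref`, i.e. interval variance grows
#'   linearly with interval length (the standard optical-map error model).
#' @param miss_penalty Cost per reference label skipped between matched pairs.
#' @param false_penalty Cost per molecule label skipped between matched pairs.
#' @param match_reward Score gained per matched label pair.
#' @param min_matched_labels Assignability floor: minimum matched pairs.
#' @param min_score Assignability floor: minimum alignment score.
#' @param min_margin Assignability floor: required relative gap
#'   `(best - second_best) / best` between the best and second-best arm.
#' @param stretch_bounds Allowed global molecule-over-reference stretch
#'   interval; must contain 1.
#' @param ref_collapse_kb Reference labels closer than this are merged to
#'   their midpoint before alignment, mirroring the optical resolution limit
#'   applied to molecules.
#' @param max_step Band width of the DP: largest index step between
#'   consecutive matched pairs on either side (`max_step - 1` internal skips).
#' @param stretch_tol Convergence tolerance of the golden-section stretch fit.
#' @return An object of class `smta_align_params`.
#' @export
align_params <- function(sizing_sd_kb_per_sqrt_kb = 0.08,
                         miss_penalty = 3, false_penalty = 3,
                         match_reward = 3, min_matched_labels = 9,
                         min_score = 15, min_margin = 0.10,
                         stretch_bounds = c(0.9, 1.1),
                         ref_collapse_kb = 1.5, max_step = 6,
                         stretch_tol = 2e-3) {
  stopifnot(sizing_sd_kb_per_sqrt_kb > 0, miss_penalty >= 0,
            false_penalty >= 0, match_reward >= 0,
            length(stretch_bounds) == 2L,
            stretch_bounds[1] <= 1, stretch_bounds[2] >= 1,
            max_step >= 1)
  structure(list(sizing_sd_kb_per_sqrt_kb = sizing_sd_kb_per_sqrt_kb,
                 miss_penalty = miss_penalty, false_penalty = false_penalty,
                 match_reward = match_reward,
                 min_matched_labels = min_matched_labels,
                 min_score = min_score, min_margin = min_margin,
                 stretch_bounds = stretch_bounds,
                 ref_collapse_kb = ref_collapse_kb, max_step = max_step,
                 stretch_tol = stretch_tol),
            class = "smta_align_params")
}

# Deterministic golden-section maximization of f over [lo, hi].
golden_max <- function(f, lo, hi, tol) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 >= f2) list(x = x1, value = f1) else list(x = x2, value = f2)
}

# DP at fixed stretch on pre-collapsed kb label vectors.
dp_at <- function(ref_kb, frag_kb, s, params) {
  dp_align_cpp(ref_kb, frag_kb, s, params$match_reward, params$miss_penalty,
               params$false_penalty, params$sizing_sd_kb_per_sqrt_kb,
               as.integer(params$max_step))
}

# Score-only DP (no traceback): the hot path.
dp_score <- function(ref_kb, frag_kb, s, params) {
  dp_score_cpp(ref_kb, frag_kb, s, params$match_reward, params$miss_penalty,
               params$false_penalty, params$sizing_sd_kb_per_sqrt_kb,
               as.integer(params$max_step))
}

#' Align a molecule fragment against one reference arm
#'
#' Finds the monotone label matching maximising the spacing-based alignment
#' score, with the global stretch factor fitted over
#' `params$stretch_bounds` by golden-section search on the DP score.
#' Leading and trailing unmatched labels are free on both sides; reference and
#' molecule labels skipped between matched pairs pay `miss_penalty` and
#' `false_penalty` respectively.
#'
#' @param fragment_labels Strictly increasing molecule label positions (kb);
#'   at least 2.
#' @param ref A [reference_arm()] (at least 2 labels after resolution
#'   collapsing).
#' @param params [align_params()].
#' @param optimize_stretch If `FALSE`, score at stretch 1 only.
#' @return List with `score`, `matched` (two-column matrix of reference and
#'   molecule label indices), `stretch` and `n_matched`. Reference indices
#'   refer to the resolution-collapsed reference labels, returned as
#'   `ref_kb`.
#' @export
align_fragment <- function(fragment_labels, ref, params = align_params(),
                           optimize_stretch = TRUE) {
  stopifnot(inherits(ref, "smta_ref_arm"))
  frag <- as.numeric(fragment_labels)
  ref_kb <- collapse_labels(ref$label_positions / 1000, params$ref_collapse_kb)
  if (length(frag) < 2L || length(ref_kb) < 2L)
    smta_stop("alignment needs at least 2 labels on each side",
              "smta_alignment_error")
  if (is.unsorted(frag, strictly = TRUE))
    smta_stop("fragment labels must be strictly increasing",
              "smta_alignment_error")
  s_hat <- 1
  if (optimize_stretch) {
    opt <- golden_max(function(s) dp_score(ref_kb, frag, s, params),
                      params$stretch_bounds[1], params$stretch_bounds[2],
                      params$stretch_tol)
    # keep s = 1 if the search did not beat it (guards rare multimodality)
    if (opt$value > dp_score(ref_kb, frag, 1, params)) s_hat <- opt$x
  }
  r <- dp_at(ref_kb, frag, s_hat, params)
  list(score = r$score,
       matched = cbind(ref_idx = r$ref_idx, mol_idx = r$mol_idx),
       stretch = s_hat, n_matched = length(r$ref_idx), ref_kb = ref_kb)
}

# Split a molecule's green labels into fragments at its red segments.
# Labels inside a red segment belong to no fragment. Returns a list of
# list(start, end, labels) in molecule kb.
segment_fragments <- function(mol) {
  reds <- mol$red_segments
  cuts <- if (nrow(reds)) reds[order(reds$start_kb), , drop = FALSE] else reds
  bounds_lo <- c(0, if (nrow(cuts)) cuts$end_kb)
  bounds_hi <- c(if (nrow(cuts)) cuts$start_kb, mol$length_kb)
  out <- list()
  for (k in seq_along(bounds_lo)) {
    lo <- bounds_lo[k]; hi <- bounds_hi[k]
    if (hi <= lo) next
    lab <- mol$green_labels[mol$green_labels >= lo & mol$green_labels <= hi]
    out[[length(out) + 1L]] <- list(start = lo, end = hi, labels = lab)
  }
  out
}

empty_assignment <- function(mol, frag, frag_id, reason = NA_character_) {
  data.frame(molecule_id = mol$molecule_id, fragment_id = frag_id,
             fragment_start_kb = frag$start, fragment_end_kb = frag$end,
             n_labels = length(frag$labels), arm_id = "UNASSIGNED",
             orientation = NA_character_, score = NA_real_,
             n_matched = NA_integer_, stretch = NA_real_,
             candidate_arm = NA_character_, second_best_arm = NA_character_,
             margin = NA_real_, terminus_proj_kb = NA_real_,
             dir = NA_integer_, qc = reason, stringsAsFactors = FALSE)
}

#' Assign every green-label fragment of a molecule to a chromosome arm
#'
#' Each fragment (maximal run of green labels between red segments) is scored
#' against every arm in both orientations at stretch 1; the top candidates
#' are then refined with the stretch fitted, and the best arm is accepted only
#' if all three assignability floors (`min_matched_labels`, `min_score`,
#' `min_margin`) pass. Fragments with fewer than 2 labels, and fragments
#' failing any floor, are `UNASSIGNED` (with best-candidate metadata
#' retained); no input raises an error.
#'
#' Orientation `"toward_terminus"` means the arm terminus lies toward
#' increasing molecule coordinate; ties between orientations and arms are
#' broken toward `"toward_terminus"`, then lexicographically by arm id.
#'
#' @param mol A molecule (see [simulate_cohort()] / [read_bnx()]).
#' @param refset An `smta_ref_set`.
#' @param params [align_params()].
#' @param refine_top Number of leading arms refined with the stretch fit.
#' @return A data frame with one row per fragment: fragment interval, arm
#'   (or `"UNASSIGNED"`), orientation, score, matched-label count, stretch,
#'   runner-up arm and margin, and the projected position of the arm terminus
#'   on the molecule (`terminus_proj_kb`, with `dir` = +1/-1 giving the
#'   direction of the terminus along the molecule axis).
#' @export
assign_arms <- function(mol, refset, params = align_params(),
                        refine_top = 2L) {
  stopifnot(inherits(refset, "smta_ref_set"))
  ids <- arm_ids(refset)
  ref_kb_list <- lapply(refset$arms, function(a)
    collapse_labels(a$label_positions / 1000, params$ref_collapse_kb))
  term_kb <- vapply(refset$arms, function(a) a$terminus_pos / 1000, numeric(1))
  frags <- segment_fragments(mol)
  rows <- list()
  for (fi in seq_along(frags)) {
    fr <- frags[[fi]]
    if (length(fr$labels) < 2L) {
      rows[[fi]] <- empty_assignment(mol, fr, fi, "few_labels")
      next
    }
    frag_fwd <- fr$labels
    frag_rev <- sort(max(fr$labels) + min(fr$labels) - fr$labels)
    # quick pass at stretch 1, both orientations
    quick <- matrix(-Inf, length(ids), 2,
                    dimnames = list(ids, c("fwd", "rev")))
    for (a in seq_along(ids)) {
      rk <- ref_kb_list[[a]]
      if (length(rk) < 2L) next
      quick[a, 1] <- dp_score(rk, frag_fwd, 1, params)
      quick[a, 2] <- dp_score(rk, frag_rev, 1, params)
    }
    arm_best_quick <- pmax(quick[, 1], quick[, 2])
    top <- order(-arm_best_quick, ids)[seq_len(min(refine_top, length(ids)))]
    refined <- lapply(top, function(a) {
      rk <- ref_kb_list[[a]]
      if (length(rk) < 2L) return(NULL)
      fw <- align_fragment(frag_fwd, refset$arms[[a]], params)
      rv <- align_fragment(frag_rev, refset$arms[[a]], params)
      # tie-break toward toward_terminus (fwd)
      if (fw$score >= rv$score) c(fw, list(orient = "toward_terminus"))
      else c(rv, list(orient = "away"))
    })
    arm_score <- arm_best_quick
    arm_score[top] <- vapply(refined, function(r)
      if (is.null(r)) -Inf else r$score, numeric(1))
    ord <- order(-arm_score, ids)
    best_a <- ord[1]; second_a <- if (length(ids) > 1L) ord[2] else NA
    if (!best_a %in% top) {  # exact tie with an unrefined arm
      top <- c(top, best_a)
      fw <- align_fragment(frag_fwd, refset$arms[[best_a]], params)
      rv <- align_fragment(frag_rev, refset$arms[[best_a]], params)
      refined[[length(refined) + 1L]] <-
        if (fw$score >= rv$score) c(fw, list(orient = "toward_terminus"))
        else c(rv, list(orient = "away"))
    }
    best <- refined[[match(best_a, top)]]
    if (is.null(best) || !is.finite(best$score)) {
      rows[[fi]] <- empty_assignment(mol, fr, fi, "no_alignment")
      next
    }
    second_score <- if (is.na(second_a)) -Inf else arm_score[second_a]
    margin <- if (!is.finite(best$score) || best$score <= 0) 0
              else (best$score - max(second_score, 0)) / best$score
    # project the arm terminus onto the molecule axis
    mm <- best$matched
    s <- best$stretch
    r_last <- best$ref_kb[mm[nrow(mm), "ref_idx"]]
    gap <- s * (term_kb[best_a] - r_last)
    if (best$orient == "toward_terminus") {
      m_last <- frag_fwd[mm[nrow(mm), "mol_idx"]]
      proj <- m_last + gap; dirn <- 1L
    } else {
      C <- max(fr$labels) + min(fr$labels)
      m_last_rev <- frag_rev[mm[nrow(mm), "mol_idx"]]
      proj <- C - (m_last_rev + gap); dirn <- -1L
    }
    ok <- is.finite(best$score) &&
      best$n_matched >= params$min_matched_labels &&
      best$score >= params$min_score && margin >= params$min_margin
    rows[[fi]] <- data.frame(
      molecule_id = mol$molecule_id, fragment_id = fi,
      fragment_start_kb = fr$start, fragment_end_kb = fr$end,
      n_labels = length(fr$labels),
      arm_id = if (ok) ids[best_a] else "UNASSIGNED",
      orientation = best$orient, score = best$score,
      n_matched = best$n_matched, stretch = best$stretch,
      candidate_arm = ids[best_a],
      second_best_arm = if (is.na(second_a)) NA_character_ else ids[second_a],
      margin = margin, terminus_proj_kb = proj, dir = dirn,
      qc = if (ok) NA_character_ else "below_floor",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(empty_assignment(mol, list(start = 0, end = mol$length_kb,
                                      labels = numeric(0)), 1L, "no_fragment"))
  }
  do.call(rbind, rows)
}

#' Write arm assignments as TSV
#'
#' @param assignments Data frame from [assign_arms()] (rows of several
#'   molecules may be combined).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
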