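# Chromosome-end classification: every molecule receives exactly one of
# END_TEL / TFE / ITS_PLUS / ITS_MINUS / UNCLASSIFIED, decided from the best
# assigned fragment's projected arm terminus and the red-segment topology
# around it.

#' Classification parameters
#'
#' @param junction_window_kb A red segment "sits at" the chromosome end if
#'   its proximal edge lies within this distance of the projected arm
#'   terminus.
#' @param end_slack_kb Unlabelled molecule overhang tolerated beyond the red
#'   segment (for `END_TEL`) or beyond the projected terminus (for `TFE`).
#' @param tfe_overhang_kb Proximal tolerance for `TFE`: how far short of the
#'   projected terminus the molecule end may fall and still count as reaching
#'   the chromosome end. Molecules falling shorter are interstitial
#'   truncations and stay `UNCLASSIFIED`.
#' @param min_fragment_labels Minimum labels for a green fragment beyond the
#'   junction to count as a fusion partner.
#' @param calibration Optional [calibrate_telomere()] result; if supplied,
#'   telomere lengths are measured with the two-regime extent/intensity
#'   estimator, otherwise the observed red extent in kb is used directly.
#' @return An object of class `smta_classify_params`.
#' @export
classify_params <- function(junction_window_kb = 5, end_slack_kb = 20,
                            tfe_overhang_kb = 10, min_fragment_labels = 2,
                            calibration = NULL) {
  stopifnot(junction_window_kb >= 0, end_slack_kb >= 0, tfe_overhang_kb >= 0,
            min_fragment_labels >= 1)
  structure(list(junction_window_kb = junction_window_kb,
                 end_slack_kb = end_slack_kb,
                 tfe_overhang_kb = tfe_overhang_kb,
                 min_fragment_labels = min_fragment_labels,
                 calibration = calibration),
            class = "smta_classify_params")
}

call_row <- function(mol, category, arm = "UNASSIGNED",
                     partner = NA_character_, telomere = NA_real_,
                     flags = character(0)) {
  data.frame(molecule_id = mol$molecule_id, cohort = mol$cohort,
             arm_id = arm, category = category, partner_arm_id = partner,
             telomere_kb = telomere,
             qc_flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

measure_red <- function(red, params) {
  extent_kb <- red$end_kb - red$start_kb
  if (is.null(params$calibration)) return(extent_kb)
  measure_telomere(extent_kb / params$calibration$kb_per_pixel,
                   red$intensity, params$calibration)
}

# Try to assign a small set of labels (the putative partner fragment of an
# ITS- fusion) to an arm; returns the arm id or "UNASSIGNED".
assign_label_run <- function(labels, mol, refset, align_par) {
  if (length(labels) < 2L) return("UNASSIGNED")
  pseudo <- new_molecule(mol$molecule_id, mol$length_kb, sort(labels),
                         empty_reds(), mol$cohort)
  a <- assign_arms(pseudo, refset, align_par)
  a <- a[a$arm_id != "UNASSIGNED", , drop = FALSE]
  if (nrow(a)) a$arm_id[which.max(a$score)] else "UNASSIGNED"
}

#' Classify one molecule into a chromosome-end category
#'
#' Decision procedure, applied in order on the best assigned fragment and the
#' signed molecule axis pointing toward its projected arm terminus `T`:
#'
#' 1. No fragment assigned: `UNCLASSIFIED` (flag `no_arm`).
#' 2. A red segment starts within `junction_window_kb` of `T`:
#'    a green fragment with at least `min_fragment_labels` labels beyond the
#'    red segment makes the molecule `ITS_PLUS` (partner recorded, assignable
#'    or not); otherwise, a molecule ending within `end_slack_kb` of the red
#'    segment is `END_TEL`; otherwise `UNCLASSIFIED` (flag `truncated`).
#' 3. No red segment at `T`: at least `min_fragment_labels` labels beyond
#'    `T` make it `ITS_MINUS`; otherwise a molecule
#'    end within `[-tfe_overhang_kb, +end_slack_kb]` of `T` is `TFE`;
#'    otherwise `UNCLASSIFIED` (flag `truncated`).
#'
#' Degenerate inputs never raise errors; they route to `UNCLASSIFIED`.
#'
#' @param mol A molecule.
#' @param assignments Output of [assign_arms()] for `mol`.
#' @param refset An `smta_ref_set` (used to try assigning fusion partners).
#' @param params [classify_params()].
#' @param align_par [align_params()] used for partner assignment.
#' @return One-row data frame: `molecule_id`, `cohort`, `arm_id`,
#'   `category`, `partner_arm_id`, `telomere_kb`, `qc_flags`.
#' @export
classify_molecule <- function(mol, assignments, refset,
                              params = classify_params(),
                              align_par = align_params()) {
  ok <- assignments[assignments$arm_id != "UNASSIGNED", , drop = FALSE]
  if (!nrow(ok)) return(call_row(mol, "UNCLASSIFIED", flags = "no_arm"))
  best <- ok[which.max(ok$score), ]
  dir <- best$dir
  u <- function(x) dir * x            # signed axis toward the terminus
  Tu <- u(best$terminus_proj_kb)
  end_u <- u(if (dir > 0) mol$length_kb else 0)
  reds <- mol$red_segments
  flags <- character(0)
  if (nrow(reds)) {
    prox <- pmin(u(reds$start_kb), u(reds$end_kb))
    dist <- pmax(u(reds$start_kb), u(reds$end_kb))
    at_T <- which(abs(prox - Tu) <= params$junction_window_kb & dist > Tu)
  } else at_T <- integer(0)
  if (length(at_T)) {
    ri <- at_T[which.min(abs(pmin(u(reds$start_kb), u(reds$end_kb))[at_T] - Tu))]
    red <- reds[ri, ]
    red_dist <- max(u(red$start_kb), u(red$end_kb))
    beyond <- mol$green_labels[u(mol$green_labels) >
                                 red_dist + 1e-9]
    if (length(beyond) >= params$min_fragment_labels) {
      # partner fragment: already segmented at the red cut, so look it up
      part <- assignments[assignments$fragment_id != best$fragment_id &
                            assignments$n_labels >= params$min_fragment_labels, ,
                          drop = FALSE]
      pick <- if (dir > 0) part[part$fragment_start_kb >= red$start_kb - 1e-6, ,
                                drop = FALSE]
              else part[part$fragment_end_kb <= red$end_kb + 1e-6, ,
                        drop = FALSE]
      partner <- "UNASSIGNED"
      if (nrow(pick)) {
        assigned <- pick[pick$arm_id != "UNASSIGNED", , drop = FALSE]
        if (nrow(assigned)) {
          partner <- assigned$arm_id[which.max(assigned$score)]
          flags <- c(flags, "both_assignable")
        }
      }
      return(call_row(mol, "ITS_PLUS", best$arm_id, partner,
                      measure_red(red, params), flags))
    }
    if (end_u - red_dist <= params$end_slack_kb)
      return(call_row(mol, "END_TEL", best$arm_id,
                      telomere = measure_red(red, params), flags = flags))
    return(call_row(mol, "UNCLASSIFIED", best$arm_id, flags = "truncated"))
  }
  beyond <- mol$green_labels[u(mol$green_labels) > Tu + 1e-9]
  if (length(beyond) >= params$min_fragment_labels) {
    partner <- assign_label_run(beyond, mol, refset, align_par)
    if (partner != "UNASSIGNED") flags <- c(flags, "both_assignable")
    return(call_row(mol, "ITS_MINUS", best$arm_id,
                    if (nzchar(partner)) partner else "UNASSIGNED",
                    flags = flags))
  }
  if (end_u >= Tu - params$tfe_overhang_kb &&
      end_u <= Tu + params$end_slack_kb)
    return(call_row(mol, "TFE", best$arm_id, flags = flags))
  call_row(mol, "UNCLASSIFIED", best$arm_id, flags = "truncated")
}

#' Classify a cohort of molecules
#'
#' Maps [assign_arms()] + [classify_molecule()] over the molecules, preserving
#' input order, and reports category counts.
#'
#' @param mols List of molecules.
#' @param refset An `smta_ref_set`.
#' @param align_par [align_params()].
#' @param params [classify_params()].
#' @param quiet Suppress the category-count message.
#' @return Data frame of end-feature calls, one row per molecule.
#' @export
classify_cohort <- function(mols, refset, align_par = align_params(),
                            params = classify_params(), quiet = FALSE) {
  calls <- lapply(mols, function(m)
    classify_molecule(m, assign_arms(m, refset, align_par), refset, params,
                      align_par))
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(molecule_id = character(0), cohort = character(0),
               arm_id = character(0), category = character(0),
               partner_arm_id = character(0), telomere_kb = numeric(0),
               qc_flags = character(0), stringsAsFactors = FALSE)
  if (!quiet && nrow(calls)) {
    tab <- table(factor(calls$category, c(CATEGORIES, "UNCLASSIFIED")))
    message(paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
  }
  calls
}

#' Write / read end-feature calls as CSV
#'
#' @param calls Data frame of calls.
#' @param path File path.
#' @return `path` (write) or the calls data frame (read).
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path))
    smta_stop(sprintf("file not found: %s", path), "smta_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "cohort", "arm_id", "category", "partner_arm_id",
            "telomere_kb", "qc_flags")
  miss <- setdiff(need, names(df))
  if (length(miss))
    smta_stop(sprintf("calls file missing columns: %s",
                      paste(miss, collapse = ", ")), "smta_format_error")
  df
}
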