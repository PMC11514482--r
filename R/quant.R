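# Telomere length quantification: a two-regime estimator. Above the optical
# resolution floor the red-segment extent (pixels * kb-per-pixel) measures
# length directly; below it the segment is an unresolved dot and integrated
# fluorescence intensity divided by the fitted per-kb yield takes over,
# extending the measurable range down to ~0.1 kb.

#' Fit the extent and intensity calibrations
#'
#' Both conversions are least-squares fits through the origin (zero telomere
#' implies zero signal; an additive offset would admit negative lengths):
#' `true_kb ~ 0 + extent_px` for the optical stretch and
#' `intensity ~ 0 + true_kb` for the fluorescence yield.
#'
#' @param points Data frame with columns `extent_px`, `intensity`, `true_kb`
#'   of red segments with known tract length; at least 10 points spanning at
#'   least one decade of `true_kb`.
#' @param resolution_floor_kb Extent (kb) below which the intensity regime is
#'   used by [measure_telomere()].
#' @return An object of class `smta_calibration` with `kb_per_pixel`,
#'   `intensity_per_kb`, `resolution_floor_kb` and fit diagnostics (slope
#'   standard errors, point count).
#' @export
calibrate_telomere <- function(points, resolution_floor_kb = 1.5) {
  need <- c("extent_px", "intensity", "true_kb")
  if (!all(need %in% names(points)))
    smta_stop(sprintf("calibration points must have columns %s",
                      paste(need, collapse = ", ")), "smta_calibration_error")
  pts <- points[is.finite(points$true_kb) & points$true_kb > 0, , drop = FALSE]
  if (nrow(pts) < 10L)
    smta_stop("calibration needs at least 10 points with true_kb > 0",
              "smta_calibration_error")
  if (max(pts$true_kb) / min(pts$true_kb) < 10)
    smta_stop("calibration points must span at least one decade of true_kb",
              "smta_calibration_error")
  above <- pts[pts$true_kb >= resolution_floor_kb & pts$extent_px > 0, ,
               drop = FALSE]
  if (nrow(above) < 2L)
    smta_stop("need at least 2 points above the resolution floor to fit the extent slope",
              "smta_calibration_error")
  fit_px <- lm(true_kb ~ 0 + extent_px, data = above)
  fit_int <- lm(intensity ~ 0 + true_kb, data = pts)
  kb_per_pixel <- unname(coef(fit_px)[1])
  intensity_per_kb <- unname(coef(fit_int)[1])
  if (!is.finite(kb_per_pixel) || kb_per_pixel <= 0 ||
      !is.finite(intensity_per_kb) || intensity_per_kb <= 0)
    smta_stop("calibration slopes must be positive", "smta_calibration_error")
  structure(list(
    kb_per_pixel = kb_per_pixel, intensity_per_kb = intensity_per_kb,
    resolution_floor_kb = resolution_floor_kb,
    diagnostics = list(   # suppressed: "perfect fit" chatter on exact input
      kb_per_pixel_se =
        suppressWarnings(summary(fit_px)$coefficients[1, 2]),
      intensity_per_kb_se =
        suppressWarnings(summary(fit_int)$coefficients[1, 2]),
      n = nrow(pts))),
    class = "smta_calibration")
}

#' @export
print.smta_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration: %.4g kb/px (se %.2g), %.4g intensity/kb (se %.2g), floor %g kb, n=%d>\n",
    x$kb_per_pixel, x$diagnostics$kb_per_pixel_se, x$intensity_per_kb,
    x$diagnostics$intensity_per_kb_se, x$resolution_floor_kb,
    x$diagnostics$n))
  invisible(x)
}

#' Measure telomere length from a red segment
#'
#' Segments whose extent (in kb, after the pixel conversion) reaches the
#' resolution floor are measured by extent; shorter segments by intensity.
#' Results are never negative; a zero-extent, zero-intensity segment measures
#' 0 kb with a `zero_signal` flag.
#'
#' @param extent_px Segment extent(s) in pixels.
#' @param intensity Integrated intensity(ies).
#' @param calib [calibrate_telomere()] result.
#' @param detail If `TRUE`, return a data frame with the regime used and qc
#'   flag per segment instead of a bare numeric vector.
#' @return Numeric vector of lengths (kb), or a data frame when
#'   `detail = TRUE`.
#' @export
measure_telomere <- function(extent_px, intensity, calib, detail = FALSE) {
  stopifnot(inherits(calib, "smta_calibration"))
  extent_kb <- pmax(extent_px, 0) * calib$kb_per_pixel
  use_extent <- extent_kb >= calib$resolution_floor_kb
  kb <- ifelse(use_extent, extent_kb,
               pmax(intensity, 0) / calib$intensity_per_kb)
  zero <- !use_extent & pmax(intensity, 0) == 0
  kb[zero] <- 0
  if (!detail) return(kb)
  data.frame(kb = kb, mode = ifelse(use_extent, "extent", "intensity"),
             qc_flag = ifelse(zero, "zero_signal", ""),
             stringsAsFactors = FALSE)
}

#' Store / load a calibration as YAML
#'
#' @param calib An `smta_calibration`.
#' @param path File path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "smta_calibration"))
  yaml::write_yaml(unclass(calib), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("kb_per_pixel", "intensity_per_kb", "resolution_floor_kb")
  if (!all(need %in% names(x)))
    smta_stop(sprintf("calibration file missing fields: %s",
                      paste(setdiff(need, names(x)), collapse = ", ")),
              "smta_format_error")
  structure(x, class = "smta_calibration")
}
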