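#' Per-pixel oxygenation maps
#'
#' @param c_hbo2,c_hb hemoglobin concentration matrices, mol/L.
#' @param sto2 oxygen saturation matrix, percent.
#' @param valid logical validity mask.
#' @param clipped logical mask of pixels where a negative concentration
#'   was clipped to zero (QC flag; such pixels stay valid).
#' @param pixel_pitch mm/px.
#' @return object of class `oxygenation_maps`.
#' @export
oxygenation_maps <- function(c_hbo2, c_hb, sto2, valid = NULL,
                             clipped = NULL, pixel_pitch = NA_real_) {
  if (is.null(valid)) valid <- !is.na(sto2)
  if (is.null(clipped)) clipped <- matrix(FALSE, nrow(sto2), ncol(sto2))
  structure(list(c_hbo2 = c_hbo2, c_hb = c_hb, sto2 = sto2,
                 valid = valid, clipped = clipped,
                 pixel_pitch = pixel_pitch),
            class = "oxygenation_maps")
}

#' @export
print.oxygenation_maps <- function(x, ...) {
  v <- x$sto2[x$valid]
  cat(sprintf(
    "<oxygenation_maps> %d x %d px, %.0f%% valid, StO2 %.1f-%.1f%% (median %.1f%%)\n",
    nrow(x$sto2), ncol(x$sto2), 100 * mean(x$valid),
    min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Beer-Lambert unmixing of two-wavelength absorption into StO2
#'
#' Solves per pixel the exactly determined 2x2 linear system
#' \deqn{\mu_a(\lambda) = \ln 10\,(\epsilon_{HbO2}(\lambda) C_{HbO2} +
#'   \epsilon_{Hb}(\lambda) C_{Hb})/10, \quad \lambda \in \{665, 860\}\,nm}
#' for the oxy-/deoxyhemoglobin concentrations and reports
#' \eqn{StO_2 = 100\,C_{HbO2}/(C_{HbO2}+C_{Hb})}. With only two
#' chromophores at two wavelengths the solve is a closed-form matrix
#' inverse (no least squares). Negative concentrations (noise near the
#' floor) are clipped to zero and flagged `clipped` rather than masked, to
#' preserve the spatial continuity of StO2 maps; pixels whose total
#' hemoglobin falls below `total_hb_floor` are masked invalid.
#'
#' @param mu_a_665,mu_a_860 [optical_property_maps()] (or plain matrices,
#'   mm^-1) at 665 and 860 nm.
#' @param extinction extinction table from [hb_extinction()].
#' @param total_hb_floor minimum credible total hemoglobin, mol/L
#'   (default 1e-7).
#' @return [oxygenation_maps()].
#' @export
unmix_chromophores <- function(mu_a_665, mu_a_860,
                               extinction = hb_extinction(),
                               total_hb_floor = 1e-7) {
  grab <- function(m) {
    if (inherits(m, "optical_property_maps"))
      list(mu = m$mu_a, valid = m$valid, pitch = m$pixel_pitch)
    else list(mu = m, valid = !is.na(m), pitch = NA_real_)
  }
  a <- grab(mu_a_665); b <- grab(mu_a_860)
  if (!all(dim(a$mu) == dim(b$mu)))
    stop_stage("oxygenation", "wavelength maps differ in shape")
  e <- hb_extinction_matrix(extinction)
  det_e <- e[1, 1] * e[2, 2] - e[1, 2] * e[2, 1]
  if (abs(det_e) < 1e-12 * max(abs(e))^2)
    stop_stage("oxygenation", "extinction matrix is singular")
  # closed-form 2x2 inverse
  c_hbo2 <- (e[2, 2] * a$mu - e[1, 2] * b$mu) / det_e
  c_hb <- (-e[2, 1] * a$mu + e[1, 1] * b$mu) / det_e
  clipped <- (c_hbo2 < 0 | c_hb < 0)
  clipped[is.na(clipped)] <- FALSE
  c_hbo2 <- pmax(c_hbo2, 0); c_hb <- pmax(c_hb, 0)
  total <- c_hbo2 + c_hb
  valid <- a$valid & b$valid & !is.na(total) & total >= total_hb_floor
  sto2 <- 100 * c_hbo2 / total
  sto2[!valid] <- NA_real_
  pitch <- if (!is.na(a$pitch)) a$pitch else b$pitch
  oxygenation_maps(matrix(c_hbo2, nrow(a$mu)), matrix(c_hb, nrow(a$mu)),
                   matrix(sto2, nrow(a$mu)), valid = valid,
                   clipped = clipped & valid, pixel_pitch = pitch)
}

# ln(10)/10-scaled extinction matrix: rows = wavelengths (665, 860),
# columns = (HbO2, Hb); maps mol/L to mm^-1.
#' @noRd
hb_extinction_matrix <- function(extinction = hb_extinction()) {
  rows <- extinction[match(c(665, 860), extinction$wavelength_nm), ]
  if (anyNA(rows$wavelength_nm))
    stop_stage("oxygenation", "extinction table must cover 665 and 860 nm")
  log(10) / 10 * rbind(c(rows$eps_hbo2[1], rows$eps_hb[1]),
                       c(rows$eps_hbo2[2], rows$eps_hb[2]))
}

#' Per-ROI StO2 time course
#'
#' Summarizes StO2 maps over named regions of interest across timepoints:
#' mean and standard deviation over valid pixels, emitted as long-format
#' records. Clipped pixels (negative concentration clipped to zero) are
#' included by default: near-zero saturation their noise distribution is
#' one-sided, and excluding them would truncate the low tail and bias deep
#' ischemic ROI means upward; set `include_clipped = FALSE` to restrict to
#' strictly unclipped pixels. An ROI with no valid pixels at a timepoint
#' yields a flagged record (NA summary) rather than being dropped.
#'
#' @param maps named list of [oxygenation_maps()], one per timepoint
#'   (names = timepoint labels).
#' @param roi_masks named list of logical matrices.
#' @param include_clipped include clipped pixels in the summary
#'   (default TRUE).
#' @return data frame with columns `roi`, `timepoint`, `mean_sto2`,
#'   `sd_sto2`, `n_valid`, `empty`.
#' @export
sto2_timecourse <- function(maps, roi_masks, include_clipped = TRUE) {
  stopifnot(length(names(maps)) == length(maps),
            length(names(roi_masks)) == length(roi_masks))
  out <- list()
  for (tp in names(maps)) {
    m <- maps[[tp]]
    usable <- m$valid & (include_clipped | !m$clipped)
    for (roi in names(roi_masks)) {
      mask <- roi_masks[[roi]]
      if (!all(dim(mask) == dim(m$sto2)))
        stop_stage("oxygenation", "ROI '%s' shape differs from map", roi)
      px <- m$sto2[mask & usable]
      out[[length(out) + 1L]] <- data.frame(
        roi = roi, timepoint = tp,
        mean_sto2 = if (length(px)) mean(px) else NA_real_,
        sd_sto2 = if (length(px) > 1) stats::sd(px) else
          if (length(px) == 1) 0 else NA_real_,
        n_valid = length(px), empty = length(px) == 0L)
    }
  }
  do.call(rbind, out)
}
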