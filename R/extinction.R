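#' Hemoglobin molar extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' laser wavelengths of the imaging system (665 and 860 nm), in
#' cm^-1 / (mol/L). Values are interpolated from the Prahl/OMLC tabulated
#' compilation of hemoglobin absorption spectra. At 665 nm deoxyhemoglobin
#' dominates (red), at 860 nm oxyhemoglobin dominates (NIR), which keeps the
#' two-wavelength unmixing system well conditioned.
#'
#' @param wavelengths_nm wavelengths to return; all must be present in the
#'   table (default: the full table).
#' @return A data frame with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`
#'   (cm^-1 M^-1) carrying a `source` attribute.
#' @examples
#' hb_extinction()
#' @export
hb_extinction <- function(wavelengths_nm = NULL) {
  tab <- data.frame(
    wavelength_nm = c(665, 860),
    eps_hbo2 = c(320.0, 1070.0),
    eps_hb = c(3151.0, 710.0)
  )
  if (!is.null(wavelengths_nm)) {
    idx <- match(wavelengths_nm, tab$wavelength_nm)
    if (anyNA(idx))
      stop("wavelength(s) not in extinction table: ",
           paste(wavelengths_nm[is.na(idx)], collapse = ", "), call. = FALSE)
    tab <- tab[idx, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "units") <- "cm^-1 M^-1"
  attr(tab, "source") <-
    "interpolated from the Prahl (OMLC) tabulated hemoglobin spectra"
  tab
}

#' Absorption coefficient from hemoglobin concentrations
#'
#' Beer-Lambert forward relation: the tissue absorption coefficient at a
#' wavelength is the extinction-weighted sum of the chromophore
#' concentrations,
#' \deqn{\mu_a(\lambda) = \ln 10 \,(\epsilon_{HbO2}(\lambda) C_{HbO2} +
#'   \epsilon_{Hb}(\lambda) C_{Hb}) / 10}
#' with extinction coefficients in cm^-1 M^-1, concentrations in mol/L, and
#' the factor 10 converting cm^-1 to mm^-1.
#'
#' @param c_hbo2,c_hb oxy-/deoxyhemoglobin concentrations, mol/L (scalars,
#'   vectors or matrices; >= 0).
#' @param wavelength_nm wavelength present in the extinction table.
#' @param extinction extinction table as returned by [hb_extinction()].
#' @return Absorption coefficient map, mm^-1, same shape as the inputs.
#' @export
mu_a_from_chromophores <- function(c_hbo2, c_hb, wavelength_nm,
                                   extinction = hb_extinction()) {
  if (any(c_hbo2 < 0, na.rm = TRUE) || any(c_hb < 0, na.rm = TRUE))
    stop("concentrations must be >= 0", call. = FALSE)
  row <- extinction[extinction$wavelength_nm == wavelength_nm, ]
  if (nrow(row) != 1L)
    stop("wavelength ", wavelength_nm, " nm not in extinction table",
         call. = FALSE)
  log(10) * (row$eps_hbo2 * c_hbo2 + row$eps_hb * c_hb) / 10
}

#' Hemoglobin concentrations from saturation and total hemoglobin
#'
#' Convenience inverse of the saturation definition: given StO2 (%) and
#' total hemoglobin (mol/L), returns the oxy/deoxy concentration pair.
#'
#' @param sto2 oxygen saturation, percent (0-100).
#' @param total_hb total hemoglobin concentration, mol/L.
#' @return list with elements `c_hbo2`, `c_hb` (mol/L).
#' @export
chromophores_from_sto2 <- function(sto2, total_hb) {
  if (any(sto2 < 0 | sto2 > 100, na.rm = TRUE))
    stop("sto2 must lie in [0, 100]", call. = FALSE)
  list(c_hbo2 = total_hb * sto2 / 100, c_hb = total_hb * (1 - sto2 / 100))
}
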