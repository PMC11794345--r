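#' Calibration phantom reference
#'
#' Bundles the known optical properties of a homogeneous tissue-mimicking
#' phantom with its demodulated modulation maps, per wavelength. The
#' phantom must be imaged with the same illumination and geometry as the
#' sample; the calibration ratio then cancels the unknown instrument
#' response.
#'
#' @param known data frame with columns `wavelength_nm`, `mu_a`,
#'   `mu_s_prime` (mm^-1).
#' @param modulation named list of [modulation_maps()] keyed by wavelength
#'   (as character).
#' @param refractive_index phantom refractive index.
#' @return object of class `phantom_reference`.
#' @export
phantom_reference <- function(known, modulation, refractive_index = 1.4) {
  stopifnot(is.data.frame(known),
            all(c("wavelength_nm", "mu_a", "mu_s_prime") %in% names(known)))
  if (any(known$mu_a <= 0) || any(known$mu_s_prime <= 0))
    stop("phantom optical properties must be positive", call. = FALSE)
  if (any(known$mu_a < 1e-4 | known$mu_a > 1 |
            known$mu_s_prime < 0.1 | known$mu_s_prime > 10))
    stop("phantom properties outside the forward model validity range",
         call. = FALSE)
  for (wl in known$wavelength_nm) {
    mm <- modulation[[as.character(wl)]]
    if (is.null(mm)) stop("missing phantom maps for ", wl, " nm",
                          call. = FALSE)
    if (any(mm$m_dc[mm$valid] <= 0) || any(mm$m_ac[mm$valid] <= 0))
      stop("phantom modulation maps must be strictly positive",
           call. = FALSE)
  }
  structure(list(known = known, modulation = modulation,
                 refractive_index = refractive_index),
            class = "phantom_reference")
}

#' Render and demodulate a homogeneous calibration phantom
#'
#' Convenience constructor for simulations: renders a flat homogeneous
#' phantom with the given optical properties under the acquisition spec and
#' demodulates it with the requested method, returning a ready
#' [phantom_reference()].
#'
#' @param acq an [acquisition_spec()].
#' @param dims image size `c(height_px, width_px)`.
#' @param pixel_pitch mm/px.
#' @param known data frame of known properties (see [phantom_reference()]).
#' @param fx AC spatial frequency, mm^-1.
#' @param method `"sfdi"` or `"ssop"`.
#' @param refractive_index phantom refractive index.
#' @return a `phantom_reference`.
#' @export
simulate_phantom_reference <- function(acq, dims, pixel_pitch, known,
                                       fx = 0.2, method = c("sfdi", "ssop"),
                                       refractive_index = 1.4) {
  method <- match.arg(method)
  mu_a <- as.list(known$mu_a); names(mu_a) <- known$wavelength_nm
  mu_s <- as.list(known$mu_s_prime); names(mu_s) <- known$wavelength_nm
  scene <- scene_spec(dims[2], dims[1], pixel_pitch,
                      mu_s_prime = mu_s, mu_a = mu_a,
                      refractive_index = refractive_index)
  stack <- render_frames(scene, acq)
  modulation <- lapply(known$wavelength_nm, function(wl) {
    if (method == "sfdi") demodulate_sfdi_3phase(stack, wl, fx)
    else demodulate_ssop_fourier(stack, fx, wavelength_nm = wl)
  })
  names(modulation) <- known$wavelength_nm
  phantom_reference(known, modulation, refractive_index)
}

#' Calibrated diffuse reflectance maps
#'
#' @param r_dc,r_ac reflectance matrices at fx = 0 and fx.
#' @param fx AC frequency, mm^-1.
#' @param wavelength_nm wavelength.
#' @param valid logical validity mask.
#' @param pixel_pitch mm/px.
#' @return object of class `reflectance_maps`.
#' @export
reflectance_maps <- function(r_dc, r_ac, fx, wavelength_nm, valid = NULL,
                             pixel_pitch = NA_real_) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(r_dc), ncol(r_dc))
  structure(list(r_dc = r_dc, r_ac = r_ac, fx = fx,
                 wavelength_nm = wavelength_nm, valid = valid,
                 pixel_pitch = pixel_pitch),
            class = "reflectance_maps")
}

#' Phantom calibration of modulation maps to diffuse reflectance
#'
#' Converts sample modulation maps to calibrated diffuse reflectance by
#' ratioing against the phantom acquisition and rescaling with the forward
#' model's prediction for the phantom's known properties:
#' \deqn{R(f_x) = \frac{M_{sample}(f_x)}{M_{phantom}(f_x)}
#'   R_d^{model}(\mu_a^{ph}, \mu_s'^{ph}, f_x).}
#' Any multiplicative instrument gain shared by sample and phantom cancels
#' exactly. Pixels where the phantom signal falls below
#' `low_signal_frac` of its median are flagged invalid rather than raising
#' an error.
#'
#' @param sample [modulation_maps()] of the sample.
#' @param phantom a [phantom_reference()] (entry matching the sample's
#'   wavelength is used).
#' @param fx AC frequency; defaults to the sample's.
#' @param low_signal_frac low-signal threshold as a fraction of the phantom
#'   median (default 0.01).
#' @return [reflectance_maps()].
#' @export
calibrate_reflectance <- function(sample, phantom, fx = sample$fx,
                                  low_signal_frac = 0.01) {
  stopifnot(inherits(sample, "modulation_maps"),
            inherits(phantom, "phantom_reference"))
  wl <- sample$wavelength_nm
  ph_mm <- phantom$modulation[[as.character(wl)]]
  if (is.null(ph_mm))
    stop_stage("calibration", "phantom has no maps at %s nm", wl)
  if (!all(dim(sample$m_dc) == dim(ph_mm$m_dc)))
    stop_stage("calibration", "sample/phantom shape mismatch")
  if (!identical(sample$method, ph_mm$method))
    stop_stage("calibration", "sample and phantom must share method")
  if (abs(fx - ph_mm$fx) > 1e-12)
    stop_stage("calibration", "sample and phantom fx differ")
  known <- phantom$known[phantom$known$wavelength_nm == wl, ]
  rd0 <- diffuse_reflectance_forward(known$mu_a, known$mu_s_prime, 0,
                                     phantom$refractive_index)
  rdf <- diffuse_reflectance_forward(known$mu_a, known$mu_s_prime, fx,
                                     phantom$refractive_index)
  thr_dc <- low_signal_frac * stats::median(ph_mm$m_dc[ph_mm$valid])
  thr_ac <- low_signal_frac * stats::median(ph_mm$m_ac[ph_mm$valid])
  ok <- sample$valid & ph_mm$valid &
    ph_mm$m_dc > thr_dc & ph_mm$m_ac > thr_ac
  r_dc <- sample$m_dc / ph_mm$m_dc * rd0
  r_ac <- sample$m_ac / ph_mm$m_ac * rdf
  r_dc[!ok] <- NA_real_; r_ac[!ok] <- NA_real_
  reflectance_maps(r_dc, r_ac, fx, wl, valid = ok,
                   pixel_pitch = sample$pixel_pitch)
}
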