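#' Height map container
#'
#' @param height elevation matrix, mm.
#' @param triangulation_deg triangulation angle used in the conversion.
#' @param reference description of the h = 0 plane.
#' @return object of class `height_map`.
#' @export
height_map <- function(height, triangulation_deg,
                       reference = "flat reference plane") {
  structure(list(height = height, triangulation_deg = triangulation_deg,
                 reference = reference),
            class = "height_map")
}

#' Fringe phase to surface height
#'
#' Standard fringe-projection triangulation: the height-induced phase
#' shift relative to a flat reference is proportional to elevation,
#' \deqn{h = \frac{\phi - \phi_{ref}}{2\pi f_x \tan\theta_{tri}},}
#' the inverse of the renderer's phase convention.
#'
#' @param phase a [phase_map()] of the sample (unwrapped).
#' @param reference_phase a `phase_map` of the flat reference, or a plain
#'   matrix of reference phase values (e.g. [carrier_phase()]).
#' @param triangulation_deg triangulation angle, degrees.
#' @return [height_map()].
#' @export
phase_to_height <- function(phase, reference_phase, triangulation_deg = 10) {
  stopifnot(inherits(phase, "phase_map"))
  if (inherits(reference_phase, "phase_map")) {
    if (abs(phase$fx - reference_phase$fx) > 1e-12)
      stop_stage("profilometry", "sample and reference fx differ")
    ref <- reference_phase$unwrapped
  } else ref <- reference_phase
  if (!all(dim(ref) == dim(phase$unwrapped)))
    stop_stage("profilometry", "phase map shapes differ")
  h <- (phase$unwrapped - ref) /
    (2 * pi * phase$fx * tan(triangulation_deg * pi / 180))
  height_map(h, triangulation_deg)
}

#' Height-based illumination correction of modulation maps
#'
#' Divides both channels by the modeled illumination intensity factor of a
#' non-flat surface: the Lambertian tilt factor \eqn{\cos\theta} computed
#' from the (Gaussian-smoothed) height gradient, optionally combined with
#' an inverse-square working-distance factor. A flat height map leaves the
#' maps unchanged; slopes beyond `max_slope_deg` are masked invalid. The
#' correction model is the exact inverse of what the renderer simulates,
#' so forward and inverse form a consistent pair.
#'
#' Because the factor is wavelength- and frequency-independent, the
#' correction never changes the M_AC/M_DC ratio; it matters downstream
#' because calibration against a flat phantom does not cancel
#' sample-specific tilt.
#'
#' @param maps [modulation_maps()] or [reflectance_maps()].
#' @param height a [height_map()] (or matrix, mm).
#' @param smooth_sigma_px Gaussian smoothing of the height map before
#'   differentiation, pixels (default 2; stabilizes cos theta).
#' @param working_distance_mm optional nominal working distance; when
#'   given, an additional `((d - h)/d)^-2` factor models the
#'   distance-dependent irradiance (default NULL = off, matching the
#'   renderer default).
#' @param max_slope_deg slopes steeper than this are masked (default 75).
#' @param pixel_pitch mm/px; defaults to the maps' pitch.
#' @return corrected maps of the same class.
#' @export
profile_correct <- function(maps, height, smooth_sigma_px = 2,
                            working_distance_mm = NULL, max_slope_deg = 75,
                            pixel_pitch = maps$pixel_pitch) {
  h <- if (inherits(height, "height_map")) height$height else height
  ch <- channels_of(maps)
  if (!all(dim(h) == dim(maps[[ch[1]]])))
    stop_stage("profilometry", "height/map shapes differ")
  if (is.na(pixel_pitch)) stop_stage("profilometry", "pixel pitch unknown")
  hs <- gauss_smooth(h, smooth_sigma_px)
  g <- gradient_mm(hs, pixel_pitch)
  slope <- sqrt(g$gx^2 + g$gy^2)
  cos_theta <- 1 / sqrt(1 + slope^2)
  factor <- cos_theta
  if (!is.null(working_distance_mm))
    factor <- factor * (working_distance_mm /
                          (working_distance_mm - hs))^2
  out <- maps
  for (f in ch) out[[f]] <- maps[[f]] / factor
  too_steep <- atan(slope) > max_slope_deg * pi / 180
  out$valid <- maps$valid & !too_steep
  out
}

#' @noRd
channels_of <- function(maps) {
  if (inherits(maps, "modulation_maps")) c("m_dc", "m_ac")
  else if (inherits(maps, "reflectance_maps")) c("r_dc", "r_ac")
  else stop("maps must be modulation_maps or reflectance_maps",
            call. = FALSE)
}
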