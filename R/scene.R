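#' Ground-truth scene specification
#'
#' Container for the per-pixel ground truth that the renderer images:
#' surface height, hemoglobin concentrations (or direct absorption
#' overrides for phantoms), reduced scattering per wavelength, refractive
#' index, and named region-of-interest masks for the liver lobes.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_pitch metric pixel size, mm/px.
#' @param height_map surface elevation above the reference plane, mm
#'   (matrix `height_px` x `width_px`, or a scalar; default 0 = flat).
#' @param c_hbo2,c_hb oxy-/deoxyhemoglobin concentration maps, mol/L
#'   (matrix or scalar, >= 0).
#' @param mu_s_prime named list or vector of reduced scattering per
#'   wavelength (names = wavelength in nm), mm^-1; scalar per wavelength or
#'   full maps.
#' @param refractive_index tissue refractive index (default 1.4).
#' @param lobe_masks named list of disjoint logical masks (e.g. LL, LM, RM).
#' @param mu_a optional named list of direct absorption maps per wavelength
#'   (mm^-1); when present it overrides the chromophore-derived absorption
#'   (used for calibration phantoms, which are not hemoglobin-based).
#' @param sto2 optional per-pixel StO2 map (%) recorded as ground truth for
#'   error analysis; filled automatically by [make_ischemia_scene()].
#' @param layout optional lobe-layout metadata (see [liver_scene()]).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, pixel_pitch,
                       height_map = 0, c_hbo2 = 0, c_hb = 0,
                       mu_s_prime = c(`665` = 1.6, `860` = 1.2),
                       refractive_index = 1.4, lobe_masks = list(),
                       mu_a = NULL, sto2 = NULL, layout = NULL) {
  dims <- c(height_px, width_px)
  as_map <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == dims))
        stop(what, " map must be ", dims[1], " x ", dims[2], call. = FALSE)
      x
    } else matrix(x, dims[1], dims[2])
  }
  c_hbo2 <- as_map(c_hbo2, "c_hbo2"); c_hb <- as_map(c_hb, "c_hb")
  if (any(c_hbo2 < 0) || any(c_hb < 0))
    stop("chromophore concentrations must be >= 0", call. = FALSE)
  height_map <- as_map(height_map, "height")
  mu_s_prime <- as.list(mu_s_prime)
  if (is.null(names(mu_s_prime)) || any(names(mu_s_prime) == ""))
    stop("mu_s_prime must be named by wavelength (nm)", call. = FALSE)
  mu_s_prime <- lapply(mu_s_prime, as_map, what = "mu_s_prime")
  if (!is.null(mu_a)) mu_a <- lapply(as.list(mu_a), as_map, what = "mu_a")
  if (length(lobe_masks)) {
    lobe_masks <- lapply(lobe_masks, function(m) {
      storage.mode(m) <- "logical"
      as_map(m, "lobe mask")
    })
    tot <- Reduce(`+`, lobe_masks)
    if (any(tot > 1)) stop("lobe masks must be disjoint", call. = FALSE)
  }
  if (!is.null(sto2)) sto2 <- as_map(sto2, "sto2")
  structure(list(
    width_px = width_px, height_px = height_px, pixel_pitch = pixel_pitch,
    height_map = height_map, c_hbo2 = c_hbo2, c_hb = c_hb,
    mu_s_prime = mu_s_prime, refractive_index = refractive_index,
    lobe_masks = lobe_masks, mu_a = mu_a, sto2 = sto2, layout = layout
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %.4f mm/px (FOV %.0f x %.0f mm)\n",
              x$height_px, x$width_px, x$pixel_pitch,
              x$height_px * x$pixel_pitch, x$width_px * x$pixel_pitch))
  cat("  wavelengths:", paste(names(x$mu_s_prime), collapse = ", "), "nm;",
      "lobes:", if (length(x$lobe_masks)) paste(names(x$lobe_masks), collapse = ", ") else "none", "\n")
  invisible(x)
}

# Absorption map of a scene at one wavelength: direct override when present,
# otherwise Beer-Lambert from the chromophore maps.
#' @noRd
scene_mu_a <- function(scene, wavelength_nm, extinction = hb_extinction()) {
  wl <- as.character(wavelength_nm)
  if (!is.null(scene$mu_a)) {
    if (is.null(scene$mu_a[[wl]]))
      stop("scene has no mu_a override for ", wl, " nm", call. = FALSE)
    return(scene$mu_a[[wl]])
  }
  mu_a_from_chromophores(scene$c_hbo2, scene$c_hb, wavelength_nm, extinction)
}

#' @noRd
scene_mu_s <- function(scene, wavelength_nm) {
  wl <- as.character(wavelength_nm)
  if (is.null(scene$mu_s_prime[[wl]]))
    stop("scene has no mu_s_prime for ", wl, " nm", call. = FALSE)
  scene$mu_s_prime[[wl]]
}

#' Structured-illumination acquisition specification
#'
#' Mirrors the acquisition protocol of the two-wavelength SFDI/SSOP
#' instrument: a planar (fx = 0) and a high-frequency (fx = 0.2 mm^-1)
#' sinusoidal pattern, three phase shifts per frequency, and two laser
#' wavelengths (665 and 860 nm).
#'
#' @param wavelengths_nm laser wavelengths, nm.
#' @param spatial_frequencies_mm pattern spatial frequencies, mm^-1 (>= 0).
#' @param phases_rad phase shifts, strictly increasing in `[0, 2*pi)`.
#' @param illumination_gain illumination amplitude (arbitrary units; full
#'   scale for the noise model).
#' @param noise noise model from [noise_model()].
#' @param triangulation_deg projector-camera triangulation angle, degrees;
#'   sets the height-to-fringe-phase sensitivity of the profilometry
#'   geometry.
#' @param seed integer; fixes all acquisition randomness.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(wavelengths_nm = c(665, 860),
                             spatial_frequencies_mm = c(0, 0.2),
                             phases_rad = c(0, 2 * pi / 3, 4 * pi / 3),
                             illumination_gain = 1,
                             noise = noise_model("gaussian", sd_frac = 0.005),
                             triangulation_deg = 10,
                             seed = 1L) {
  if (any(spatial_frequencies_mm < 0)) stop("fx must be >= 0", call. = FALSE)
  if (any(diff(phases_rad) <= 0) || any(phases_rad < 0) ||
      any(phases_rad >= 2 * pi))
    stop("phases must be strictly increasing in [0, 2*pi)", call. = FALSE)
  structure(list(
    wavelengths_nm = wavelengths_nm,
    spatial_frequencies_mm = spatial_frequencies_mm,
    phases_rad = phases_rad, illumination_gain = illumination_gain,
    noise = noise, triangulation_deg = triangulation_deg,
    seed = as.integer(seed)
  ), class = "acquisition_spec")
}

#' Acquisition noise model
#'
#' @param type `"none"`, `"gaussian"` (additive read noise) or `"poisson"`
#'   (shot noise).
#' @param sd_frac Gaussian noise standard deviation as a fraction of full
#'   scale (the illumination gain); default 0.005 (0.5%).
#' @param scale Poisson scale: expected counts per intensity unit.
#' @return list describing the noise model.
#' @export
noise_model <- function(type = c("gaussian", "none", "poisson"),
                        sd_frac = 0.005, scale = 1e4) {
  type <- match.arg(type)
  list(type = type, sd_frac = sd_frac, scale = scale)
}

# Smoothstep from 0 to 1 over t in [0,1]; exactly 0/1 outside the band so
# that lobe means away from the transition are unaffected.
#' @noRd
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  (1 - cos(pi * t)) / 2
}

# Build a per-pixel StO2 field from per-lobe targets, with smooth
# transition bands at the LL|LM and LM|RM (demarcation) boundaries.
#' @noRd
build_sto2_field <- function(layout, dims, pixel_pitch, values,
                             demarcation_width_mm = NULL) {
  w_ll_lm <- layout$blend_ll_lm_mm
  w_lm_rm <- demarcation_width_mm %||% layout$blend_lm_rm_mm
  x_mm <- (seq_len(dims[2]) - 1) * pixel_pitch
  b1 <- layout$b1_frac * dims[2] * pixel_pitch
  b2 <- layout$b2_frac * dims[2] * pixel_pitch
  s <- values[["LL"]] +
    (values[["LM"]] - values[["LL"]]) * smoothstep((x_mm - b1) / w_ll_lm + 0.5) +
    (values[["RM"]] - values[["LM"]]) * smoothstep((x_mm - b2) / w_lm_rm + 0.5)
  matrix(rep(s, each = dims[1]), dims[1], dims[2])
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic liver scene with lobe geometry
#'
#' Builds the base scene used by the virtual hemi-hepatic ischemia
#' experiment: three vertical lobe territories (left lateral LL, left
#' medial LM, right medial RM, left to right), per-lobe StO2 targets, a
#' configurable demarcation transition band at the left/right boundary, and
#' lobe ROI masks eroded away from the transition bands so that mask means
#' equal the lobe targets exactly.
#'
#' The default geometry matches the instrument: a 15 x 15 cm field of view;
#' at `resolution = "quarter"` the image is 256 x 320 px, at `"full"`
#' 1024 x 1280 px.
#'
#' @param resolution `"quarter"`, `"full"` or `c(height_px, width_px)`.
#' @param fov_width_mm horizontal field of view, mm (default 150).
#' @param sto2 named per-lobe StO2 targets, percent.
#' @param total_hb total hemoglobin concentration, mol/L. The default
#'   (50e-6 M) keeps the hemoglobin-derived absorption inside the inversion
#'   table range, with comfortable margin against acquisition noise, at
#'   both wavelengths over the full StO2 span of the study (0-60%).
#' @param mu_s_prime named reduced scattering per wavelength, mm^-1.
#' @param height_map surface height, mm (default flat).
#' @param blend_ll_lm_mm,blend_lm_rm_mm widths of the smooth StO2
#'   transitions at the LL|LM and LM|RM boundaries, mm. The LM|RM band is
#'   the ischemic demarcation; it is narrow for total inflow occlusion and
#'   wide for arterial-only occlusion.
#' @param refractive_index tissue refractive index.
#' @return A `scene_spec` with lobe masks, StO2 ground truth and layout
#'   metadata.
#' @export
liver_scene <- function(resolution = "quarter", fov_width_mm = 150,
                        sto2 = c(LL = 46.0, LM = 42.7, RM = 48.0),
                        total_hb = 50e-6,
                        mu_s_prime = c(`665` = 1.6, `860` = 1.2),
                        height_map = 0,
                        blend_ll_lm_mm = 4, blend_lm_rm_mm = 6,
                        refractive_index = 1.4) {
  dims <- if (is.character(resolution)) {
    switch(match.arg(resolution, c("quarter", "full")),
           quarter = c(256L, 320L), full = c(1024L, 1280L))
  } else as.integer(resolution)
  pixel_pitch <- fov_width_mm / dims[2]
  layout <- list(b1_frac = 1 / 3, b2_frac = 2 / 3,
                 blend_ll_lm_mm = blend_ll_lm_mm,
                 blend_lm_rm_mm = blend_lm_rm_mm,
                 mask_margin_mm = 2)
  masks <- lobe_masks_from_layout(layout, dims, pixel_pitch)
  sto2_map <- build_sto2_field(layout, dims, pixel_pitch, sto2)
  ch <- chromophores_from_sto2(sto2_map, total_hb)
  sc <- scene_spec(dims[2], dims[1], pixel_pitch,
                   height_map = height_map,
                   c_hbo2 = ch$c_hbo2, c_hb = ch$c_hb,
                   mu_s_prime = mu_s_prime,
                   refractive_index = refractive_index,
                   lobe_masks = masks, sto2 = sto2_map, layout = layout)
  sc$total_hb <- total_hb
  sc
}

# Lobe ROI masks: vertical bands eroded by half the widest transition band
# plus a safety margin, so transition pixels never enter a mask.
#' @noRd
lobe_masks_from_layout <- function(layout, dims, pixel_pitch) {
  x_mm <- (seq_len(dims[2]) - 1) * pixel_pitch
  b1 <- layout$b1_frac * dims[2] * pixel_pitch
  b2 <- layout$b2_frac * dims[2] * pixel_pitch
  # erode enough for the widest band the study uses (HAO demarcation)
  m1 <- layout$blend_ll_lm_mm / 2 + layout$mask_margin_mm
  m2 <- max(layout$blend_lm_rm_mm, 20) / 2 + layout$mask_margin_mm
  in_band <- function(lo, hi) {
    col <- x_mm > lo & x_mm < hi
    matrix(rep(col, each = dims[1]), dims[1], dims[2])
  }
  list(LL = in_band(-Inf, b1 - m1),
       LM = in_band(b1 + m1, b2 - m2),
       RM = in_band(b2 + m2, Inf))
}

#' Default lobe-level StO2 effect profile of the ischemia model
#'
#' Per-group, per-timepoint lobe StO2 targets used by
#' [make_ischemia_scene()]: deep desaturation of the left lobes under total
#' vascular inflow occlusion (TVIO), moderate desaturation under hepatic
#' artery occlusion (HAO), right-medial lobe essentially unchanged, and a
#' prompt return to baseline on reperfusion (T2 = T0). Values are the
#' SSOP-StO2 group means of the swine hemi-hepatic ischemia experiment the
#' simulator emulates.
#'
#' @return data frame with columns `group`, `timepoint`, `LL`, `LM`, `RM`
#'   (percent StO2).
#' @export
ischemia_effect_profile <- function() {
  ref <- ischemia_reference()
  ref <- ref[, c("group", "lobe", "timepoint", "sto2_mean")]
  out <- expand.grid(group = c("TVIO", "HAO"),
                     timepoint = c("T0", "T1", "T2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (lb in c("LL", "LM", "RM"))
    out[[lb]] <- mapply(function(g, tp)
      ref$sto2_mean[ref$group == g & ref$lobe == lb & ref$timepoint == tp],
      out$group, out$timepoint)
  out
}

#' Apply an ischemia condition to a base liver scene
#'
#' Returns a copy of `base_scene` whose StO2 field matches the lobe-level
#' targets of the requested occlusion group and timepoint, with a smooth
#' demarcation transition between the clamped left territory (LL + LM) and
#' the perfused right territory (RM). Under TVIO the demarcation band is
#' narrow (a sharp line); under HAO it is wide (a faint, graded boundary).
#' Lobe means over the scene's ROI masks equal the targets exactly because
#' the masks exclude the transition bands.
#'
#' @param group `"TVIO"` (total vascular inflow occlusion) or `"HAO"`
#'   (hepatic artery occlusion).
#' @param timepoint `"T0"` (baseline), `"T1"` (ischemia, 30 min after
#'   clamping) or `"T2"` (reperfusion, 30 min after declamping).
#' @param base_scene a scene from [liver_scene()] (must carry lobe masks and
#'   layout metadata).
#' @param effect_profile lobe StO2 targets; default
#'   [ischemia_effect_profile()].
#' @param demarcation_width_mm width of the LM|RM transition band; default
#'   6 mm for TVIO, 20 mm for HAO.
#' @return A `scene_spec` with updated chromophores and StO2 ground truth.
#' @export
make_ischemia_scene <- function(group = c("TVIO", "HAO"),
                                timepoint = c("T0", "T1", "T2"),
                                base_scene,
                                effect_profile = ischemia_effect_profile(),
                                demarcation_width_mm = NULL) {
  group <- match.arg(group); timepoint <- match.arg(timepoint)
  if (!length(base_scene$lobe_masks) || is.null(base_scene$layout))
    stop("base_scene must carry lobe masks and layout metadata ",
         "(use liver_scene())", call. = FALSE)
  row <- effect_profile[effect_profile$group == group &
                          effect_profile$timepoint == timepoint, ]
  if (nrow(row) != 1L)
    stop("effect profile has no row for ", group, "/", timepoint,
         call. = FALSE)
  width <- demarcation_width_mm %||% if (group == "TVIO") 6 else 20
  dims <- c(base_scene$height_px, base_scene$width_px)
  targets <- c(LL = row$LL, LM = row$LM, RM = row$RM)
  sto2_map <- build_sto2_field(base_scene$layout, dims,
                               base_scene$pixel_pitch, targets,
                               demarcation_width_mm = width)
  thb <- base_scene$total_hb %||% 50e-6
  ch <- chromophores_from_sto2(sto2_map, thb)
  sc <- base_scene
  sc$c_hbo2 <- ch$c_hbo2; sc$c_hb <- ch$c_hb; sc$sto2 <- sto2_map
  sc
}
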