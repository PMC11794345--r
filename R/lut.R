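#' Build a diffuse-reflectance look-up table
#'
#' Tabulates the forward model over an absorption/scattering grid at fx = 0
#' and at the AC frequency, verifies the strict monotonicity that
#' guarantees invertibility (reflectance decreasing in absorption,
#' increasing in scattering), and precomputes a dense inverse raster on a
#' regular (R_DC, R_AC) grid for fast per-pixel lookup. Absorption is
#' log-spaced (relative accuracy in absorption drives StO2 accuracy),
#' scattering linear. Default ranges cover the tissue-like span of the
#' training phantoms: 0.005-0.05 mm^-1 absorption, 0.5-3 mm^-1 reduced
#' scattering.
#'
#' The inverse raster is built from the tabulated surfaces alone (spline
#' refinement followed by monotone 1-D interpolation), so externally
#' supplied tables with the same schema (e.g. Monte Carlo generated) can be
#' inverted identically.
#'
#' @param fx AC spatial frequency, mm^-1 (> 0).
#' @param mu_a_grid absorption grid, mm^-1 (>= 16 points, increasing).
#' @param mu_s_grid reduced scattering grid, mm^-1.
#' @param n refractive index.
#' @param inverse_raster_n resolution of the precomputed inverse raster.
#' @param forward_model_id provenance string for the forward model.
#' @return object of class `lookup_table`.
#' @export
build_lut <- function(fx = 0.2,
                      mu_a_grid = lseq(0.005, 0.05, 64),
                      mu_s_grid = seq(0.5, 3, length.out = 64),
                      n = 1.4, inverse_raster_n = 512,
                      forward_model_id = "sfd_diffusion_v1") {
  if (fx <= 0) stop("fx must be > 0 for an AC table", call. = FALSE)
  if (length(mu_a_grid) < 16 || length(mu_s_grid) < 16)
    stop("grids need at least 16 points", call. = FALSE)
  r_dc <- outer(mu_a_grid, mu_s_grid,
                function(a, s) diffuse_reflectance_forward(a, s, 0, n))
  r_ac <- outer(mu_a_grid, mu_s_grid,
                function(a, s) diffuse_reflectance_forward(a, s, fx, n))
  mono_dec_rows <- all(apply(r_dc, 2, function(x) all(diff(x) < 0)))
  mono_inc_cols <- all(apply(r_dc, 1, function(x) all(diff(x) > 0)))
  if (!mono_dec_rows || !mono_inc_cols)
    stop("R_DC surface is not strictly monotone over the grid; ",
         "narrow the property ranges", call. = FALSE)
  if (!all(r_ac < r_dc))
    stop("R_AC >= R_DC somewhere on the grid; invalid forward surface",
         call. = FALSE)
  lut <- structure(list(
    mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid,
    r_dc_surface = r_dc, r_ac_surface = r_ac,
    fx = fx, refractive_index = n,
    forward_model_id = forward_model_id
  ), class = "lookup_table")
  lut$inverse <- build_inverse_raster(lut, inverse_raster_n)
  lut
}

# Dense inverse raster: regular (R_DC, R_AC) grid -> (log mu_a, mu_s').
# Built in three 1-D interpolation passes exploiting monotonicity:
#  1. spline-refine the tabulated surfaces onto a fine (log mu_a, mu_s) grid;
#  2. for each fine mu_s column, interpolate mu_a and R_AC onto the regular
#     R_DC raster (R_DC is monotone in mu_a);
#  3. for each R_DC raster row, interpolate mu_s and mu_a onto the regular
#     R_AC raster (R_AC is monotone in mu_s at fixed R_DC).
#' @noRd
build_inverse_raster <- function(lut, n_raster = 512, n_fine = 256) {
  lmua <- log(lut$mu_a_grid)
  lmua_f <- seq(min(lmua), max(lmua), length.out = n_fine)
  mus_f <- seq(min(lut$mu_s_grid), max(lut$mu_s_grid), length.out = n_fine)
  refine <- function(z) {
    half <- t(apply(z, 1, function(row)
      stats::spline(lut$mu_s_grid, row, xout = mus_f)$y))
    apply(half, 2, function(col)
      stats::spline(lmua, col, xout = lmua_f)$y)
  }
  rdc_f <- refine(lut$r_dc_surface)   # n_fine x n_fine (rows: log mu_a)
  rac_f <- refine(lut$r_ac_surface)
  rdc_grid <- seq(min(rdc_f), max(rdc_f), length.out = n_raster)
  rac_grid <- seq(min(rac_f), max(rac_f), length.out = n_raster)
  lmua_on <- matrix(NA_real_, n_raster, n_fine)
  rac_on <- matrix(NA_real_, n_raster, n_fine)
  for (j in seq_len(n_fine)) {
    x <- rev(rdc_f[, j])    # increasing in reversed mu_a order
    lmua_on[, j] <- stats::approx(x, rev(lmua_f), xout = rdc_grid,
                                  rule = 1)$y
    rac_on[, j] <- stats::approx(x, rev(rac_f[, j]), xout = rdc_grid,
                                 rule = 1)$y
  }
  log_mu_a <- matrix(NA_real_, n_raster, n_raster)
  mu_s <- matrix(NA_real_, n_raster, n_raster)
  for (i in seq_len(n_raster)) {
    y <- rac_on[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 2L) next
    log_mu_a[i, ] <- stats::approx(y[ok], lmua_on[i, ok], xout = rac_grid,
                                   rule = 1)$y
    mu_s[i, ] <- stats::approx(y[ok], mus_f[ok], xout = rac_grid,
                               rule = 1)$y
  }
  list(rdc_grid = rdc_grid, rac_grid = rac_grid,
       log_mu_a = log_mu_a, mu_s = mu_s)
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf(
    "<lookup_table> fx = %g mm^-1, n = %g, model %s\n  mu_a %g-%g mm^-1 (%d log-spaced), mu_s' %g-%g mm^-1 (%d linear)\n",
    x$fx, x$refractive_index, x$forward_model_id,
    min(x$mu_a_grid), max(x$mu_a_grid), length(x$mu_a_grid),
    min(x$mu_s_grid), max(x$mu_s_grid), length(x$mu_s_grid)))
  invisible(x)
}

#' Per-pixel optical property maps
#'
#' @param mu_a,mu_s_prime property matrices, mm^-1 (NA where invalid).
#' @param wavelength_nm wavelength.
#' @param valid logical validity mask.
#' @param pixel_pitch mm/px.
#' @return object of class `optical_property_maps`.
#' @export
optical_property_maps <- function(mu_a, mu_s_prime, wavelength_nm,
                                  valid = NULL, pixel_pitch = NA_real_) {
  if (is.null(valid)) valid <- !is.na(mu_a) & !is.na(mu_s_prime)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime,
                 wavelength_nm = wavelength_nm, valid = valid,
                 pixel_pitch = pixel_pitch),
            class = "optical_property_maps")
}

#' Invert calibrated reflectance to optical properties
#'
#' Looks each pixel's (R_DC, R_AC) pair up in the table's precomputed
#' inverse raster by bilinear interpolation, returning per-pixel absorption
#' and reduced scattering. Pixels falling outside the table's reflectance
#' hull (unphysical or out-of-range measurements) are masked invalid, never
#' clamped: clamping would silently corrupt StO2 downstream. The inversion
#' is deterministic and independent of pixel order.
#'
#' @param maps [reflectance_maps()]; its `fx` must match the table's.
#' @param lut a [build_lut()] table.
#' @return [optical_property_maps()].
#' @export
invert_reflectance <- function(maps, lut) {
  stopifnot(inherits(maps, "reflectance_maps"),
            inherits(lut, "lookup_table"))
  if (abs(maps$fx - lut$fx) > 1e-12)
    stop_stage("inversion", "reflectance fx (%g) != LUT fx (%g)",
               maps$fx, lut$fx)
  inv <- lut$inverse %||% build_inverse_raster(lut)
  q_dc <- as.vector(maps$r_dc); q_ac <- as.vector(maps$r_ac)
  lmua <- bilinear_lookup(inv$rdc_grid, inv$rac_grid, inv$log_mu_a,
                          q_dc, q_ac)
  mus <- bilinear_lookup(inv$rdc_grid, inv$rac_grid, inv$mu_s,
                         q_dc, q_ac)
  d <- dim(maps$r_dc)
  mu_a <- matrix(exp(lmua), d[1], d[2])
  mu_s_prime <- matrix(mus, d[1], d[2])
  valid <- maps$valid & !is.na(mu_a) & !is.na(mu_s_prime)
  mu_a[!valid] <- NA_real_; mu_s_prime[!valid] <- NA_real_
  optical_property_maps(mu_a, mu_s_prime, maps$wavelength_nm,
                        valid = valid, pixel_pitch = maps$pixel_pitch)
}
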