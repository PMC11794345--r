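#' Modulation amplitude maps
#'
#' @param m_dc,m_ac planar (fx = 0) and high-frequency modulation
#'   amplitude matrices.
#' @param fx spatial frequency of the AC channel, mm^-1.
#' @param wavelength_nm acquisition wavelength.
#' @param method `"sfdi_3phase"` or `"ssop_fourier"`.
#' @param pixel_pitch mm/px.
#' @param valid logical validity mask (default all TRUE).
#' @return object of class `modulation_maps`.
#' @export
modulation_maps <- function(m_dc, m_ac, fx, wavelength_nm, method,
                            pixel_pitch = NA_real_, valid = NULL) {
  stopifnot(all(dim(m_dc) == dim(m_ac)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m_dc), ncol(m_dc))
  structure(list(m_dc = m_dc, m_ac = m_ac, fx = fx,
                 wavelength_nm = wavelength_nm, method = method,
                 pixel_pitch = pixel_pitch, valid = valid),
            class = "modulation_maps")
}

#' @export
print.modulation_maps <- function(x, ...) {
  cat(sprintf(
    "<modulation_maps> %s, %g nm, fx = %g mm^-1, %d x %d px (%.0f%% valid)\n",
    x$method, x$wavelength_nm, x$fx, nrow(x$m_dc), ncol(x$m_dc),
    100 * mean(x$valid)))
  invisible(x)
}

#' Three-phase SFDI demodulation
#'
#' Exact demodulation of a three-phase-shifted sinusoidal sequence. For
#' frames \eqn{I_k = A + B\cos(\theta + \phi_k)} at phase offsets 0,
#' \eqn{2\pi/3}, \eqn{4\pi/3} the amplitude identity
#' \deqn{M_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 +
#'   (I_3-I_1)^2} = B}
#' is exact (to machine precision) for a pure sinusoid. The DC channel
#' \eqn{M_{DC}} is the three-frame mean of the planar (fx = 0) stack,
#' mirroring the instrument's separate planar acquisition.
#'
#' @param stack a `frame_stack` containing both the fx = 0 and the
#'   requested fx block at `wavelength_nm`.
#' @param wavelength_nm wavelength to demodulate.
#' @param fx spatial frequency of the AC channel, mm^-1.
#' @return [modulation_maps()] with `method = "sfdi_3phase"`.
#' @export
demodulate_sfdi_3phase <- function(stack, wavelength_nm, fx) {
  ac <- stack_frames(stack, wavelength_nm, fx)
  if (length(ac$frames) != 3L)
    stop_stage("demodulation", "need exactly 3 frames at fx = %g (got %d)",
               fx, length(ac$frames))
  expect_ph <- c(0, 2 * pi / 3, 4 * pi / 3)
  if (max(abs(sort(ac$phases) - expect_ph)) > 1e-9)
    stop_stage("demodulation", "phases must be 0, 2*pi/3, 4*pi/3")
  o <- order(ac$phases)
  i1 <- ac$frames[[o[1]]]; i2 <- ac$frames[[o[2]]]; i3 <- ac$frames[[o[3]]]
  m_ac <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  dc <- stack_frames(stack, wavelength_nm, 0)
  m_dc <- Reduce(`+`, dc$frames) / length(dc$frames)
  modulation_maps(m_dc, m_ac, fx, wavelength_nm, "sfdi_3phase",
                  pixel_pitch = stack$pixel_pitch)
}

#' SSOP spectral filter specification
#'
#' Raised-cosine filters for single-frame Fourier demodulation: an annular
#' band-pass of configurable half-width centered on the fringe carrier
#' (+fx), and a radial low-pass around zero frequency. Each filter is flat
#' out to `taper_start_frac` of its cutoff and rolls off as cos^2 beyond.
#'
#' @param bandpass_halfwidth_mm half-width of the band-pass around the
#'   carrier, mm^-1; default `fx / 2` (resolved at demodulation time).
#' @param lowpass_cutoff_mm low-pass cutoff, mm^-1; default `fx / 2`.
#' @param taper_start_frac fraction of the cutoff at which the cosine
#'   taper begins (default 0.5).
#' @return list of class `ssop_filter_spec`.
#' @export
ssop_filter_spec <- function(bandpass_halfwidth_mm = NULL,
                             lowpass_cutoff_mm = NULL,
                             taper_start_frac = 0.5) {
  structure(list(bandpass_halfwidth_mm = bandpass_halfwidth_mm,
                 lowpass_cutoff_mm = lowpass_cutoff_mm,
                 taper_start_frac = taper_start_frac),
            class = "ssop_filter_spec")
}

#' @noRd
raised_cosine <- function(rho, cutoff, taper_start_frac) {
  a <- taper_start_frac * cutoff
  h <- matrix(0, nrow(rho), ncol(rho))
  h[rho <= a] <- 1
  band <- rho > a & rho < cutoff
  h[band] <- cos(pi / 2 * (rho[band] - a) / (cutoff - a))^2
  h
}

#' Single-frame SSOP Fourier demodulation
#'
#' Estimates both modulation channels from a single high-spatial-frequency
#' frame by spectral filtering: the low-pass region around zero frequency
#' yields the DC channel, and a one-sided band-pass around the fringe
#' carrier yields the analytic-signal magnitude, i.e. the AC amplitude.
#' Outputs are scaled to the same convention as [demodulate_sfdi_3phase()]
#' (DC = planar-stack mean, AC = fringe amplitude), so SSOP and SFDI maps
#' are interchangeable downstream. The frame is symmetrically padded before
#' the FFT and pixels within one filter width of the border are flagged
#' invalid.
#'
#' @param frame intensity matrix (fringes running along image x), or a
#'   `frame_stack` from which the first phase frame at
#'   (`wavelength_nm`, `fx`) is taken.
#' @param fx carrier spatial frequency, mm^-1; must be below Nyquist
#'   (at least ~6 px per period recommended).
#' @param pixel_pitch mm/px (taken from the stack when a stack is given).
#' @param filter_spec an [ssop_filter_spec()].
#' @param wavelength_nm recorded in the output (and used to pick the frame
#'   from a stack).
#' @return [modulation_maps()] with `method = "ssop_fourier"`.
#' @export
demodulate_ssop_fourier <- function(frame, fx, pixel_pitch = NULL,
                                    filter_spec = ssop_filter_spec(),
                                    wavelength_nm = NA_real_) {
  if (inherits(frame, "frame_stack")) {
    pixel_pitch <- frame$pixel_pitch
    frame <- stack_frames(frame, wavelength_nm, fx)$frames[[1]]
  }
  if (is.null(pixel_pitch)) stop("pixel_pitch required", call. = FALSE)
  nyquist <- 1 / (2 * pixel_pitch)
  if (fx >= nyquist)
    stop_stage("demodulation", "fx = %g at/above Nyquist (%g mm^-1)",
               fx, nyquist)
  hw <- filter_spec$bandpass_halfwidth_mm %||% (fx / 2)
  lp <- filter_spec$lowpass_cutoff_mm %||% (fx / 2)
  # filter width = spatial main-lobe extent of the cos^2-tapered band-pass
  # (about 2 / half-width); pixels within one width of a border are
  # flagged invalid, and the mirror padding keeps the seam that far away
  filt_w_px <- ceiling(2 / (hw * pixel_pitch))
  nr <- nrow(frame); nc <- ncol(frame)
  p <- min(filt_w_px, nr - 1L, nc - 1L)
  # symmetric (mirror) padding
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  fp <- frame[ri, ci]
  np_r <- nrow(fp); np_c <- ncol(fp)
  fu <- function(nf, pitch) {
    k <- 0:(nf - 1)
    ifelse(k <= nf / 2, k, k - nf) / (nf * pitch)
  }
  u <- matrix(rep(fu(np_c, pixel_pitch), each = np_r), np_r, np_c)
  v <- matrix(rep(fu(np_r, pixel_pitch), np_c), np_r, np_c)
  FT <- stats::fft(fp)
  lo <- raised_cosine(sqrt(u^2 + v^2), lp, filter_spec$taper_start_frac)
  bp <- raised_cosine(sqrt((u - fx)^2 + v^2), hw,
                      filter_spec$taper_start_frac)
  m_dc <- 2 * Re(stats::fft(FT * lo, inverse = TRUE)) / (np_r * np_c)
  m_ac <- 2 * Mod(stats::fft(FT * bp, inverse = TRUE)) / (np_r * np_c)
  crop <- function(m) m[p + (1:nr), p + (1:nc)]
  valid <- matrix(FALSE, nr, nc)
  interior_r <- (filt_w_px + 1):(nr - filt_w_px)
  interior_c <- (filt_w_px + 1):(nc - filt_w_px)
  if (length(interior_r) > 0 && length(interior_c) > 0)
    valid[interior_r, interior_c] <- TRUE
  mm <- modulation_maps(crop(m_dc), crop(m_ac), fx, wavelength_nm,
                        "ssop_fourier", pixel_pitch = pixel_pitch,
                        valid = valid)
  mm$filter_width_px <- filt_w_px
  mm
}

#' Fringe phase map
#'
#' @param wrapped wrapped phase matrix, radians in (-pi, pi].
#' @param unwrapped continuous phase matrix, radians.
#' @param fx carrier frequency, mm^-1.
#' @param pixel_pitch mm/px.
#' @param valid logical mask (FALSE where modulation amplitude vanished).
#' @return object of class `phase_map`.
#' @export
phase_map <- function(wrapped, unwrapped, fx, pixel_pitch = NA_real_,
                      valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(wrapped), ncol(wrapped))
  structure(list(wrapped = wrapped, unwrapped = unwrapped, fx = fx,
                 pixel_pitch = pixel_pitch, valid = valid),
            class = "phase_map")
}

#' @noRd
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Two-dimensional phase unwrapping
#'
#' Itoh line-scan unwrapping suited to carrier-dominant fringe maps: each
#' row is unwrapped by integrating wrapped phase differences along x (the
#' fringe direction), and rows are then stitched by unwrapping the first
#' column vertically. Valid whenever neighboring-pixel phase differences of
#' the true phase stay below pi, which holds by construction for the
#' instrument's carrier (well below Nyquist) over smooth surfaces.
#'
#' @param wrapped wrapped phase matrix, radians.
#' @return unwrapped phase matrix.
#' @export
unwrap_phase <- function(wrapped) {
  nr <- nrow(wrapped); nc <- ncol(wrapped)
  dx <- wrap_to_pi(wrapped[, -1, drop = FALSE] -
                     wrapped[, -nc, drop = FALSE])
  unw <- cbind(wrapped[, 1], t(apply(dx, 1, cumsum)) + wrapped[, 1])
  col0 <- wrapped[, 1]
  dy <- wrap_to_pi(diff(col0))
  col0_unw <- cumsum(c(col0[1], dy))
  unw + (col0_unw - col0)
}

#' Three-step fringe phase extraction
#'
#' Recovers the wrapped fringe phase from the three phase-shifted frames,
#' \eqn{\phi = \mathrm{atan2}(\sqrt 3 (I_3 - I_2),\ 2I_1 - I_2 - I_3)},
#' then unwraps it with [unwrap_phase()]. The recovered phase is the full
#' fringe argument (carrier ramp plus height-induced shift); subtracting a
#' flat-reference phase isolates the height term (see [phase_to_height()]).
#' Pixels whose modulation amplitude is negligible are flagged invalid.
#'
#' @inheritParams demodulate_sfdi_3phase
#' @return [phase_map()].
#' @export
extract_phase_3step <- function(stack, wavelength_nm, fx) {
  ac <- stack_frames(stack, wavelength_nm, fx)
  if (length(ac$frames) != 3L)
    stop_stage("demodulation", "need exactly 3 frames at fx = %g", fx)
  o <- order(ac$phases)
  i1 <- ac$frames[[o[1]]]; i2 <- ac$frames[[o[2]]]; i3 <- ac$frames[[o[3]]]
  wrapped <- atan2(sqrt(3) * (i3 - i2), 2 * i1 - i2 - i3)
  amp <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  valid <- amp > 1e-9 * max(amp)
  phase_map(wrapped, unwrap_phase(wrapped), fx,
            pixel_pitch = stack$pixel_pitch, valid = valid)
}

#' Ideal carrier phase ramp of a flat reference plane
#'
#' @param nrow_px,ncol_px image size.
#' @param pixel_pitch mm/px.
#' @param fx carrier frequency, mm^-1.
#' @return matrix of `2*pi*fx*X_mm`.
#' @export
carrier_phase <- function(nrow_px, ncol_px, pixel_pitch, fx) {
  x_mm <- (seq_len(ncol_px) - 1) * pixel_pitch
  matrix(rep(2 * pi * fx * x_mm, each = nrow_px), nrow_px, ncol_px)
}
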