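#' Render structured-light frame stacks from a ground-truth scene
#'
#' Forward-images a scene under the acquisition protocol: for every
#' wavelength and spatial frequency the detected intensity is
#' \deqn{I(x,y) = G(x,y)\,[R_d(\mu_a,\mu_s',0) +
#'   R_d(\mu_a,\mu_s',f_x)\cos(2\pi f_x X + \phi + \Delta\phi_h)]/2}
#' where \eqn{G} is the illumination gain including the Lambertian
#' surface-tilt factor \eqn{\cos\theta} computed from the height map,
#' \eqn{X} is the metric horizontal coordinate and
#' \eqn{\Delta\phi_h = 2\pi f_x h \tan\theta_{tri}} is the height-induced
#' fringe phase shift of the triangulation geometry. Planar illumination
#' (fx = 0) projects a uniform pattern, so its three frames are identical:
#' \eqn{I = G R_d(0)}.
#'
#' Noise is applied per frame according to the acquisition noise model,
#' seeded deterministically from the acquisition seed (one substream per
#' wavelength/frequency block); intensities are truncated at zero.
#'
#' @param scene a [scene_spec()].
#' @param acq an [acquisition_spec()].
#' @return An object of class `frame_stack`: list of intensity matrices
#'   plus an index data frame (`wavelength`, `fx`, `phase`), pixel pitch
#'   and an echo of the acquisition spec.
#' @export
render_frames <- function(scene, acq) {
  stopifnot(inherits(scene, "scene_spec"), inherits(acq, "acquisition_spec"))
  dims <- c(scene$height_px, scene$width_px)
  x_mm <- matrix(rep((seq_len(dims[2]) - 1) * scene$pixel_pitch,
                     each = dims[1]), dims[1], dims[2])
  g <- gradient_mm(scene$height_map, scene$pixel_pitch)
  cos_theta <- 1 / sqrt(1 + g$gx^2 + g$gy^2)
  gain_field <- acq$illumination_gain * cos_theta
  tan_tri <- tan(acq$triangulation_deg * pi / 180)
  frames <- list(); idx <- list(); k <- 0L
  for (wl in acq$wavelengths_nm) {
    mu_a <- scene_mu_a(scene, wl)
    mu_s <- scene_mu_s(scene, wl)
    rd0 <- diffuse_reflectance_forward(mu_a, mu_s, 0, scene$refractive_index)
    for (fx in acq$spatial_frequencies_mm) {
      sub <- derive_seed(acq$seed, sprintf("render_%s_%s", wl, fx))
      block <- if (fx == 0) {
        flat <- gain_field * rd0
        rep(list(flat), length(acq$phases_rad))
      } else {
        rdfx <- diffuse_reflectance_forward(mu_a, mu_s, fx,
                                            scene$refractive_index)
        dphi <- 2 * pi * fx * scene$height_map * tan_tri
        lapply(acq$phases_rad, function(phi) {
          gain_field * (rd0 + rdfx * cos(2 * pi * fx * x_mm + phi + dphi)) / 2
        })
      }
      block <- apply_noise(block, acq$noise, acq$illumination_gain, sub)
      for (j in seq_along(block)) {
        k <- k + 1L
        frames[[k]] <- block[[j]]
        idx[[k]] <- data.frame(wavelength = wl, fx = fx,
                               phase = acq$phases_rad[j])
      }
    }
  }
  structure(list(frames = frames, index = do.call(rbind, idx),
                 pixel_pitch = scene$pixel_pitch, acquisition = acq),
            class = "frame_stack")
}

#' @noRd
apply_noise <- function(block, noise, gain, seed) {
  if (noise$type == "none") return(block)
  with_seed(seed, lapply(block, function(im) {
    out <- switch(noise$type,
      gaussian = im + stats::rnorm(length(im), 0, noise$sd_frac * gain),
      poisson = stats::rpois(length(im), pmax(im, 0) * noise$scale) /
        noise$scale)
    matrix(pmax(out, 0), nrow(im), ncol(im))
  }))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%.4f mm/px)\n",
              length(x$frames), d[1], d[2], x$pixel_pitch))
  print(stats::aggregate(phase ~ wavelength + fx, x$index, length))
  invisible(x)
}

#' Extract the frames of one (wavelength, spatial frequency) block
#'
#' @param stack a `frame_stack`.
#' @param wavelength_nm,fx block selectors.
#' @return list with `frames` (list of matrices) and `phases` (radians).
#' @export
stack_frames <- function(stack, wavelength_nm, fx) {
  sel <- which(stack$index$wavelength == wavelength_nm &
                 abs(stack$index$fx - fx) < 1e-12)
  if (!length(sel))
    stop("no frames at ", wavelength_nm, " nm, fx = ", fx, call. = FALSE)
  list(frames = stack$frames[sel], phases = stack$index$phase[sel])
}
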