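# File plumbing: frame stacks as multi-page TIFF + JSON sidecar, maps as
# TIFF, study tables as CSV, StO2 renderings as PNG.

#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 16-bit TIFF pages normalized by a common
#' scale factor recorded in the sidecar, which also carries the page index
#' (wavelength, spatial frequency, phase per page), the pixel pitch and an
#' echo of the acquisition spec.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  scale <- max(1e-12, max(vapply(stack$frames, max, 0)))
  pages <- lapply(stack$frames, function(f) pmin(f / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  acq <- stack$acquisition
  sidecar <- list(
    pixel_pitch_mm = stack$pixel_pitch, intensity_scale = scale,
    pages = stack$index,
    acquisition = list(
      wavelengths_nm = acq$wavelengths_nm,
      spatial_frequencies_mm = acq$spatial_frequencies_mm,
      phases_rad = acq$phases_rad,
      illumination_gain = acq$illumination_gain,
      noise = acq$noise, triangulation_deg = acq$triangulation_deg,
      seed = acq$seed))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(side$pages) || nrow(side$pages) != length(pages))
    stop_stage("io", "sidecar page index does not match TIFF page count")
  frames <- lapply(pages, function(p) p * side$intensity_scale)
  a <- side$acquisition
  acq <- acquisition_spec(
    wavelengths_nm = a$wavelengths_nm,
    spatial_frequencies_mm = a$spatial_frequencies_mm,
    phases_rad = a$phases_rad, illumination_gain = a$illumination_gain,
    noise = do.call(noise_model, a$noise[names(a$noise) %in%
                                           c("type", "sd_frac", "scale")]),
    triangulation_deg = a$triangulation_deg, seed = a$seed)
  structure(list(frames = frames, index = as.data.frame(side$pages),
                 pixel_pitch = side$pixel_pitch_mm, acquisition = acq),
            class = "frame_stack")
}

#' Write a single-channel map as 16-bit TIFF
#'
#' @param map numeric matrix; NAs are written as 0.
#' @param path output path.
#' @param max_value full-scale value (e.g. 100 for StO2 in %).
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, max_value = max(map, na.rm = TRUE)) {
  m <- map / max_value
  m[is.na(m)] <- 0
  tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Render a StO2 map to a colormapped PNG
#'
#' Fixed colormap bounds of 0-100% so frames of a time series are
#' comparable; invalid pixels are black.
#'
#' @param oxy an [oxygenation_maps()] or StO2 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_sto2_png <- function(oxy, path) {
  if (inherits(oxy, "oxygenation_maps")) {
    s <- oxy$sto2; valid <- oxy$valid
  } else { s <- oxy; valid <- !is.na(oxy) }
  pal <- grDevices::colorRamp(grDevices::hcl.colors(64, "Spectral",
                                                    rev = TRUE))
  t01 <- pmin(pmax(s / 100, 0), 1)
  t01[!valid] <- 0
  rgbv <- pal(as.vector(t01)) / 255
  arr <- array(0, c(nrow(s), ncol(s), 3))
  for (k in 1:3) {
    ch <- matrix(rgbv[, k], nrow(s), ncol(s))
    ch[!valid] <- 0
    arr[, , k] <- ch
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Write / read a study table as CSV
#'
#' @param table study table data frame.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("study_table", "data.frame")
  out
}
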