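# Shared fixtures: all synthetic, built in code at test time.

# pixel pitch of the quarter-resolution instrument geometry (150 mm / 320 px)
QPITCH <- 150 / 320

noiseless_acq <- function(...) {
  acquisition_spec(noise = noise_model("none"), ...)
}

# small flat homogeneous tissue scene (height x width = 64 x 80 px)
small_tissue_scene <- function(sto2 = 70, total_hb = 50e-6,
                               height_map = 0, pitch = QPITCH) {
  ch <- chromophores_from_sto2(sto2, total_hb)
  scene_spec(80, 64, pitch, height_map = height_map,
             c_hbo2 = ch$c_hbo2, c_hb = ch$c_hb)
}

default_phantom_props <- function() {
  data.frame(wavelength_nm = c(665, 860),
             mu_a = c(0.012, 0.012), mu_s_prime = c(1.5, 1.2))
}

small_phantom <- function(acq, dims = c(64, 80), pitch = QPITCH,
                          method = "sfdi") {
  simulate_phantom_reference(acq, dims, pitch, default_phantom_props(),
                             method = method)
}

# shared LUT (built once per test session; ~1 s)
shared_lut <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lut()
    cache
  }
})

gaussian_bump_height <- function(nr, nc, peak_mm = 20, sigma_px = 12) {
  peak_mm * outer(exp(-((seq_len(nr) - nr / 2)^2) / (2 * sigma_px^2)),
                  exp(-((seq_len(nc) - nc / 2)^2) / (2 * sigma_px^2)))
}
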