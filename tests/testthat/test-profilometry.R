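# Phase-to-height conversion and height-based illumination correction.

test_that("identical phases give zero height; tan-linearity holds", {
  ref <- carrier_phase(32, 40, QPITCH, 0.2)
  pm <- phase_map(ref, ref, 0.2, QPITCH)
  h <- phase_to_height(pm, ref, 10)
  expect_equal(max(abs(h$height)), 0)
  # doubling a small triangulation angle about halves the height
  pm2 <- phase_map(ref, ref + 0.3, 0.2, QPITCH)
  h5 <- phase_to_height(pm2, ref, 5)$height[1, 1]
  h10 <- phase_to_height(pm2, ref, 10)$height[1, 1]
  expect_equal(h5 / h10, tan(10 * pi / 180) / tan(5 * pi / 180),
               tolerance = 1e-12)
  expect_equal(h5 / h10, 2, tolerance = 0.01)
})

test_that("a rendered Gaussian bump is recovered within 2% at the peak", {
  h_true <- gaussian_bump_height(64, 80, peak_mm = 20)
  sc <- small_tissue_scene(height_map = h_true)
  stack <- render_frames(sc, noiseless_acq())
  pm <- extract_phase_3step(stack, 665, 0.2)
  ref <- carrier_phase(64, 80, QPITCH, 0.2)
  h <- phase_to_height(pm, ref, 10)
  expect_lt(abs(max(h$height) - 20) / 20, 0.02)
  expect_lt(max(abs(h$height - h_true)), 0.2)
})

test_that("flat height leaves maps unchanged; ratio is always invariant", {
  mm <- modulation_maps(matrix(2, 16, 20), matrix(0.8, 16, 20), 0.2, 665,
                        "sfdi_3phase", pixel_pitch = QPITCH)
  out <- profile_correct(mm, matrix(0, 16, 20))
  expect_identical(out$m_dc, mm$m_dc)
  expect_identical(out$m_ac, mm$m_ac)
  h <- gaussian_bump_height(16, 20, peak_mm = 10, sigma_px = 5)
  out2 <- profile_correct(mm, h)
  expect_equal(out2$m_ac / out2$m_dc, mm$m_ac / mm$m_dc, tolerance = 1e-12)
  expect_true(any(out2$m_dc > mm$m_dc))  # tilt correction boosts slopes
})

test_that("correction undoes the rendered Lambertian factor on a tilt", {
  # tilted plane: constant slope 0.35 along x (~19 degrees)
  slope <- 0.35
  h <- matrix(rep((seq_len(80) - 1) * QPITCH * slope, each = 64), 64, 80)
  sc_flat <- small_tissue_scene()
  sc_tilt <- small_tissue_scene(height_map = h)
  acq <- noiseless_acq()
  m_flat <- demodulate_sfdi_3phase(render_frames(sc_flat, acq), 665, 0.2)
  m_tilt <- demodulate_sfdi_3phase(render_frames(sc_tilt, acq), 665, 0.2)
  # uncorrected maps are attenuated by cos(theta)
  expect_lt(max(m_tilt$m_dc / m_flat$m_dc), 1 / sqrt(1 + slope^2) + 1e-6)
  corr <- profile_correct(m_tilt, h, smooth_sigma_px = 0)
  interior <- matrix(FALSE, 64, 80); interior[3:62, 3:78] <- TRUE
  rel_dc <- abs(corr$m_dc - m_flat$m_dc) / m_flat$m_dc
  rel_ac <- abs(corr$m_ac - m_flat$m_ac) / m_flat$m_ac
  expect_lt(max(rel_dc[interior]), 0.01)
  expect_lt(max(rel_ac[interior]), 0.01)
})

test_that("extreme slopes are masked invalid", {
  mm <- modulation_maps(matrix(2, 16, 20), matrix(0.8, 16, 20), 0.2, 665,
                        "sfdi_3phase", pixel_pitch = QPITCH)
  h <- matrix(rep((seq_len(20) - 1) * QPITCH * 5, each = 16), 16, 20)
  out <- profile_correct(mm, h, smooth_sigma_px = 0)
  expect_false(any(out$valid[, 5:15]))
})

test_that("profile correction reduces end-to-end StO2 error on a curved lobe", {
  acq <- noiseless_acq()
  h <- gaussian_bump_height(128, 160, peak_mm = 20, sigma_px = 25)
  base <- liver_scene(resolution = c(128, 160), height_map = h)
  sc <- make_ischemia_scene("TVIO", "T0", base)
  stack <- render_frames(sc, acq)
  pitch <- base$pixel_pitch
  ph <- simulate_phantom_reference(acq, c(128, 160), pitch,
                                   default_phantom_props())
  lut <- shared_lut()
  sto2_err <- function(correct) {
    op <- list()
    for (wl in c(665, 860)) {
      mod <- demodulate_sfdi_3phase(stack, wl, 0.2)
      if (correct) {
        pm <- extract_phase_3step(stack, wl, 0.2)
        hm <- phase_to_height(pm, carrier_phase(128, 160, pitch, 0.2), 10)
        mod <- profile_correct(mod, hm)
      }
      cal <- calibrate_reflectance(mod, ph)
      op[[as.character(wl)]] <- invert_reflectance(cal, lut)
    }
    ox <- unmix_chromophores(op[["665"]], op[["860"]])
    mean(abs(ox$sto2 - sc$sto2)[ox$valid])
  }
  e_raw <- sto2_err(FALSE)
  e_cor <- sto2_err(TRUE)
  expect_lt(e_cor, e_raw)       # the point of the correction
  expect_lt(e_cor, 0.1)         # and it is nearly exact when noiseless
  expect_gt(e_raw, 0.5)
})
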