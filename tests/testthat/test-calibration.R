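# Phantom calibration to diffuse reflectance.

test_that("self-calibration returns the model-predicted phantom reflectance", {
  acq <- noiseless_acq()
  ph <- small_phantom(acq)
  known <- default_phantom_props()
  for (wl in c(665, 860)) {
    k <- known[known$wavelength_nm == wl, ]
    cal <- calibrate_reflectance(ph$modulation[[as.character(wl)]], ph)
    expect_equal(max(abs(cal$r_dc -
      diffuse_reflectance_forward(k$mu_a, k$mu_s_prime, 0))), 0,
      tolerance = 1e-12)
    expect_equal(max(abs(cal$r_ac -
      diffuse_reflectance_forward(k$mu_a, k$mu_s_prime, 0.2))), 0,
      tolerance = 1e-12)
  }
})

test_that("render -> demodulate -> calibrate round-trips the reflectance", {
  acq <- noiseless_acq()
  sc <- small_tissue_scene(sto2 = 40)
  stack <- render_frames(sc, acq)
  ph <- small_phantom(acq)
  for (wl in c(665, 860)) {
    mm <- demodulate_sfdi_3phase(stack, wl, 0.2)
    cal <- calibrate_reflectance(mm, ph)
    mu_a <- mu_a_from_chromophores(sc$c_hbo2[1, 1], sc$c_hb[1, 1], wl)
    mu_s <- sc$mu_s_prime[[as.character(wl)]][1, 1]
    expect_lt(max(abs(cal$r_dc - diffuse_reflectance_forward(mu_a, mu_s, 0))),
              1e-6)
    expect_lt(max(abs(cal$r_ac -
                        diffuse_reflectance_forward(mu_a, mu_s, 0.2))),
              1e-6)
    expect_true(all(cal$r_ac < cal$r_dc))
  }
})

test_that("a shared smooth illumination gain field cancels exactly", {
  acq <- noiseless_acq()
  sc <- small_tissue_scene(sto2 = 55)
  stack <- render_frames(sc, acq)
  ph <- small_phantom(acq)
  # multiply both sample and phantom frames by the same smooth x2 gain
  set.seed(42)
  g <- 1 + outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 80))
  scale_stack <- function(st) { st$frames <- lapply(st$frames,
                                                    function(f) f * g); st }
  stack_g <- scale_stack(stack)
  mm_ref <- demodulate_sfdi_3phase(stack, 665, 0.2)
  cal_ref <- calibrate_reflectance(mm_ref, ph)
  ph_g <- ph
  for (wl in names(ph_g$modulation)) {
    ph_g$modulation[[wl]]$m_dc <- ph$modulation[[wl]]$m_dc * g
    ph_g$modulation[[wl]]$m_ac <- ph$modulation[[wl]]$m_ac * g
  }
  cal_g <- calibrate_reflectance(demodulate_sfdi_3phase(stack_g, 665, 0.2),
                                 ph_g)
  expect_equal(cal_g$r_dc, cal_ref$r_dc, tolerance = 1e-12)
  expect_equal(cal_g$r_ac, cal_ref$r_ac, tolerance = 1e-12)
})

test_that("near-zero phantom pixels are flagged invalid, not errors", {
  acq <- noiseless_acq()
  sc <- small_tissue_scene()
  mm <- demodulate_sfdi_3phase(render_frames(sc, acq), 665, 0.2)
  ph <- small_phantom(acq)
  ph$modulation[["665"]]$m_dc[3, 5] <- 1e-9
  cal <- calibrate_reflectance(mm, ph)
  expect_false(cal$valid[3, 5])
  expect_true(is.na(cal$r_dc[3, 5]))
  expect_true(all(cal$valid[-3, ]))
})

test_that("calibration validates shape, method and wavelength pairing", {
  acq <- noiseless_acq()
  ph <- small_phantom(acq)
  mm <- demodulate_sfdi_3phase(render_frames(small_tissue_scene(), acq),
                               665, 0.2)
  big <- modulation_maps(matrix(1, 10, 10), matrix(0.5, 10, 10), 0.2, 665,
                         "sfdi_3phase")
  expect_error(calibrate_reflectance(big, ph), "shape")
  wrong_method <- mm; wrong_method$method <- "ssop_fourier"
  expect_error(calibrate_reflectance(wrong_method, ph), "method")
  wrong_wl <- mm; wrong_wl$wavelength_nm <- 532
  expect_error(calibrate_reflectance(wrong_wl, ph), "532")
})
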