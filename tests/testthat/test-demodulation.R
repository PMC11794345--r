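# Three-phase demodulation, SSOP Fourier demodulation, phase extraction.

test_that("3-phase demodulation is the exact sinusoid identity", {
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  # I_k = 10 + 4 cos(phi_k), pixelwise
  frames <- lapply(phases, function(p) matrix(10 + 4 * cos(p), 8, 9))
  stack <- structure(list(
    frames = c(list(matrix(10, 8, 9), matrix(10, 8, 9), matrix(10, 8, 9)),
               frames),
    index = data.frame(wavelength = 665, fx = rep(c(0, 0.2), each = 3),
                       phase = rep(phases, 2)),
    pixel_pitch = QPITCH, acquisition = NULL), class = "frame_stack")
  mm <- demodulate_sfdi_3phase(stack, 665, 0.2)
  expect_equal(max(abs(mm$m_ac - 4)), 0, tolerance = 1e-13)
  expect_equal(max(abs(mm$m_dc - 10)), 0, tolerance = 1e-13)
  # constant frames -> zero modulation
  stack$frames[4:6] <- list(matrix(3, 8, 9), matrix(3, 8, 9),
                            matrix(3, 8, 9))
  mm0 <- demodulate_sfdi_3phase(stack, 665, 0.2)
  expect_equal(max(mm0$m_ac), 0, tolerance = 1e-14)
})

test_that("noiseless render demodulates to the forward-model ratio", {
  acq <- noiseless_acq()
  sc <- small_tissue_scene()
  stack <- render_frames(sc, acq)
  for (wl in c(665, 860)) {
    mm <- demodulate_sfdi_3phase(stack, wl, 0.2)
    ratio <- mm$m_ac / mm$m_dc
    mu_a <- mu_a_from_chromophores(sc$c_hbo2[1, 1], sc$c_hb[1, 1], wl)
    mu_s <- sc$mu_s_prime[[as.character(wl)]][1, 1]
    expected <- diffuse_reflectance_forward(mu_a, mu_s, 0.2) /
      diffuse_reflectance_forward(mu_a, mu_s, 0) / 2
    expect_lt(max(abs(ratio - expected)) / expected, 1e-9)
    expect_lt(stats::sd(ratio), 1e-12)  # constant over the image
  }
})

test_that("fx = 0 frames are phase-independent", {
  stack <- render_frames(small_tissue_scene(), noiseless_acq())
  dc <- stack_frames(stack, 665, 0)
  expect_identical(dc$frames[[1]], dc$frames[[2]])
  expect_identical(dc$frames[[1]], dc$frames[[3]])
})

test_that("demodulation rejects malformed stacks", {
  stack <- render_frames(small_tissue_scene(), noiseless_acq())
  expect_error(demodulate_sfdi_3phase(stack, 665, 0.3), "no frames")
  bad <- stack
  bad$index$phase[bad$index$fx == 0.2 & bad$index$wavelength == 665] <-
    c(0, 1, 2)
  expect_error(demodulate_sfdi_3phase(bad, 665, 0.2), "phases must be")
})

test_that("demodulation is intensity-scale equivariant", {
  stack <- render_frames(small_tissue_scene(), noiseless_acq())
  m1 <- demodulate_sfdi_3phase(stack, 665, 0.2)
  stack$frames <- lapply(stack$frames, function(f) 3.7 * f)
  m2 <- demodulate_sfdi_3phase(stack, 665, 0.2)
  expect_equal(m2$m_ac, 3.7 * m1$m_ac, tolerance = 1e-12)
  expect_equal(m2$m_dc, 3.7 * m1$m_dc, tolerance = 1e-12)
  # SSOP path
  s1 <- demodulate_ssop_fourier(stack, 0.2, wavelength_nm = 665)
  stack$frames <- lapply(stack$frames, function(f) 2 * f)
  s2 <- demodulate_ssop_fourier(stack, 0.2, wavelength_nm = 665)
  expect_equal(s2$m_ac, 2 * s1$m_ac, tolerance = 1e-10)
  expect_equal(s2$m_dc, 2 * s1$m_dc, tolerance = 1e-10)
})

test_that("SSOP recovers a pure carrier's DC and AC amplitudes", {
  n <- 128; m <- 160
  x <- matrix(rep((seq_len(m) - 1) * QPITCH, each = n), n, m)
  frame <- 0.8 * (1 + cos(2 * pi * 0.2 * x)) / 2
  mm <- demodulate_ssop_fourier(frame, 0.2, QPITCH)
  # rendering convention: DC channel = planar-stack level (0.8),
  # AC = fringe amplitude (0.4)
  expect_lt(max(abs(mm$m_dc[mm$valid] - 0.8)) / 0.8, 0.01)
  expect_lt(max(abs(mm$m_ac[mm$valid] - 0.4)) / 0.4, 0.01)
})

test_that("SSOP rejects a carrier at/above Nyquist", {
  expect_error(demodulate_ssop_fourier(matrix(1, 32, 32), fx = 1.2,
                                       pixel_pitch = 0.5), "Nyquist")
})

test_that("SSOP agrees with 3-phase demodulation on a smooth scene", {
  acq <- noiseless_acq()
  base <- liver_scene()
  sc <- make_ischemia_scene("TVIO", "T1", base)
  stack <- render_frames(sc, acq)
  sf <- demodulate_sfdi_3phase(stack, 665, 0.2)
  ss <- demodulate_ssop_fourier(stack, 0.2, wavelength_nm = 665)
  rel <- abs(ss$m_ac / ss$m_dc - sf$m_ac / sf$m_dc) / (sf$m_ac / sf$m_dc)
  interior <- ss$valid
  expect_gte(mean(rel[interior] < 0.05), 0.95)
  expect_lt(stats::median(rel[interior]), 0.02)
})

test_that("SSOP ringing at a step edge stays within a filter width", {
  # step in reflectance: two homogeneous halves
  ch1 <- chromophores_from_sto2(20, 50e-6)
  ch2 <- chromophores_from_sto2(70, 50e-6)
  c_hbo2 <- matrix(ch1$c_hbo2, 128, 288); c_hb <- matrix(ch1$c_hb, 128, 288)
  c_hbo2[, 145:288] <- ch2$c_hbo2; c_hb[, 145:288] <- ch2$c_hb
  sc <- scene_spec(288, 128, QPITCH, c_hbo2 = c_hbo2, c_hb = c_hb)
  stack <- render_frames(sc, noiseless_acq())
  sf <- demodulate_sfdi_3phase(stack, 665, 0.2)
  ss <- demodulate_ssop_fourier(stack, 0.2, wavelength_nm = 665)
  rel <- abs(ss$m_dc - sf$m_dc) / sf$m_dc
  w <- ss$filter_width_px
  away <- ss$valid
  away[, (145 - w):(144 + w)] <- FALSE
  near <- ss$valid & !away
  # artifact is localized: large near the edge, small away from it
  expect_lt(stats::quantile(rel[away], 0.95), 0.02)
  expect_gt(max(rel[near]), max(rel[away]))
})

test_that("phase extraction recovers the carrier ramp and is equivariant", {
  acq <- noiseless_acq()
  sc <- small_tissue_scene()
  stack <- render_frames(sc, acq)
  pm <- extract_phase_3step(stack, 665, 0.2)
  ref <- carrier_phase(64, 80, QPITCH, 0.2)
  expect_lt(max(abs(pm$unwrapped - ref)), 1e-6)
  # shifting all three phase offsets by pi/2 shifts the recovered phase
  acq2 <- noiseless_acq(phases_rad = c(0, 2 * pi / 3, 4 * pi / 3) + pi / 2)
  stack2 <- render_frames(sc, acq2)
  # demodulate as if offsets were the nominal three-phase set
  stack2$index$phase <- stack$index$phase
  pm2 <- extract_phase_3step(stack2, 665, 0.2)
  d <- (pm2$wrapped - pm$wrapped) %% (2 * pi)
  expect_lt(max(abs(d - pi / 2)), 1e-9)
})

test_that("phase responds linearly to a height bump", {
  h <- gaussian_bump_height(64, 80)
  sc1 <- small_tissue_scene(height_map = h)
  sc2 <- small_tissue_scene(height_map = h / 2)
  ref <- carrier_phase(64, 80, QPITCH, 0.2)
  p1 <- extract_phase_3step(render_frames(sc1, noiseless_acq()), 665, 0.2)
  p2 <- extract_phase_3step(render_frames(sc2, noiseless_acq()), 665, 0.2)
  d1 <- p1$unwrapped - ref; d2 <- p2$unwrapped - ref
  expect_equal(d1, 2 * d2, tolerance = 1e-4)
  # proportional to the height map itself
  expect_equal(d1 / max(d1), h / max(h), tolerance = 1e-6)
})
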