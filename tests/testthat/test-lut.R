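# Look-up-table construction and inversion.

test_that("LUT nodes equal direct forward calls and satisfy R_AC < R_DC", {
  lut <- shared_lut()
  direct <- outer(lut$mu_a_grid, lut$mu_s_grid,
                  function(a, s) diffuse_reflectance_forward(a, s, 0))
  expect_identical(lut$r_dc_surface, direct)
  expect_true(all(lut$r_ac_surface < lut$r_dc_surface))
})

test_that("non-invertible configurations fail loudly at build time", {
  expect_error(build_lut(fx = 0), "fx must be")
  expect_error(build_lut(mu_a_grid = c(0.01, 0.02)), "at least 16")
})

test_that("forward -> invert round-trips within (1%, 0.5%) on interior grid", {
  lut <- shared_lut()
  mua <- lseq(0.005 * 1.05, 0.05 / 1.05, 20)
  mus <- seq(0.55, 2.9, length.out = 20)
  g <- expand.grid(a = mua, s = mus)
  maps <- reflectance_maps(
    matrix(diffuse_reflectance_forward(g$a, g$s, 0), 20),
    matrix(diffuse_reflectance_forward(g$a, g$s, 0.2), 20), 0.2, 665)
  op <- invert_reflectance(maps, lut)
  expect_true(all(op$valid))
  expect_lt(max(abs(op$mu_a - matrix(g$a, 20)) / matrix(g$a, 20)), 0.01)
  expect_lt(max(abs(op$mu_s_prime - matrix(g$s, 20)) / matrix(g$s, 20)),
            0.005)
})

test_that("doubling grid density changes mid-range inversions by < 0.5%", {
  lut64 <- shared_lut()
  lut128 <- build_lut(mu_a_grid = lseq(0.005, 0.05, 128),
                      mu_s_grid = seq(0.5, 3, length.out = 128))
  mua <- lseq(0.01, 0.03, 8); mus <- seq(1, 2.4, length.out = 8)
  g <- expand.grid(a = mua, s = mus)
  maps <- reflectance_maps(
    matrix(diffuse_reflectance_forward(g$a, g$s, 0), 8),
    matrix(diffuse_reflectance_forward(g$a, g$s, 0.2), 8), 0.2, 665)
  o1 <- invert_reflectance(maps, lut64)
  o2 <- invert_reflectance(maps, lut128)
  expect_lt(max(abs(o1$mu_a - o2$mu_a) / o2$mu_a), 0.005)
  expect_lt(max(abs(o1$mu_s_prime - o2$mu_s_prime) / o2$mu_s_prime), 0.005)
})

test_that("out-of-hull reflectance pairs are masked, never clamped", {
  lut <- shared_lut()
  rdc <- matrix(c(0.05, 0.5), 1)   # far below the hull / interior
  rac <- matrix(c(0.01, 0.2), 1)
  op <- invert_reflectance(reflectance_maps(rdc, rac, 0.2, 665), lut)
  expect_false(op$valid[1, 1])
  expect_true(is.na(op$mu_a[1, 1]))
  expect_true(op$valid[1, 2])
})

test_that("inversion is deterministic and independent of pixel order", {
  lut <- shared_lut()
  set.seed(3)
  a <- matrix(stats::runif(60, 0.008, 0.04), 6)
  s <- matrix(stats::runif(60, 0.7, 2.7), 6)
  maps <- reflectance_maps(diffuse_reflectance_forward(a, s, 0),
                           diffuse_reflectance_forward(a, s, 0.2),
                           0.2, 665)
  o1 <- invert_reflectance(maps, lut)
  o2 <- invert_reflectance(maps, lut)
  expect_identical(o1$mu_a, o2$mu_a)
  perm <- sample(60)
  maps_p <- reflectance_maps(matrix(maps$r_dc[perm], 6),
                             matrix(maps$r_ac[perm], 6), 0.2, 665)
  op <- invert_reflectance(maps_p, lut)
  expect_equal(as.vector(op$mu_a), as.vector(o1$mu_a)[perm],
               tolerance = 1e-14)
  expect_error(invert_reflectance(
    reflectance_maps(maps$r_dc, maps$r_ac, 0.1, 665), lut), "fx")
})

test_that("full pipeline recovers per-pixel absorption within 2%", {
  acq <- noiseless_acq()
  base <- liver_scene(resolution = c(64, 80))
  sc <- make_ischemia_scene("TVIO", "T1", base)
  stack <- render_frames(sc, acq)
  ph <- small_phantom(acq)
  lut <- shared_lut()
  for (wl in c(665, 860)) {
    cal <- calibrate_reflectance(demodulate_sfdi_3phase(stack, wl, 0.2), ph)
    op <- invert_reflectance(cal, lut)
    truth <- mu_a_from_chromophores(sc$c_hbo2, sc$c_hb, wl)
    err <- abs(op$mu_a - truth) / truth
    expect_gt(mean(op$valid), 0.99)
    expect_lt(max(err[op$valid]), 0.02)
  }
})
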