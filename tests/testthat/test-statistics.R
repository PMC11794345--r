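# Cell summaries, two-way ANOVA with multiple comparisons, correlations,
# demarcation detection.

test_that("zero-noise summaries reproduce the headline effect sizes", {
  cs <- cell_summaries(simulate_study(study_spec(seed = 1), noise = FALSE))
  d <- cs$deltas
  g <- function(gr, lb, col) d[d$group == gr & d$lobe == lb, col]
  expect_equal(g("TVIO", "LL", "sto2_drop"), 29.8, tolerance = 1e-10)
  expect_equal(g("TVIO", "LM", "sto2_drop"), 36.3, tolerance = 1e-10)
  expect_equal(g("HAO", "LL", "sto2_drop"), 13.6, tolerance = 1e-10)
  expect_equal(g("HAO", "LM", "sto2_drop"), 19.8, tolerance = 1e-10)
  expect_equal(g("TVIO", "LL", "ref_sto2_drop"), 23.0, tolerance = 1e-10)
  expect_equal(g("TVIO", "LM", "ref_sto2_drop"), 21.1, tolerance = 1e-10)
  expect_equal(g("HAO", "LL", "ref_sto2_drop"), 12.0, tolerance = 1e-10)
  expect_equal(g("HAO", "LM", "ref_sto2_drop"), 12.9, tolerance = 1e-10)
  expect_equal(g("TVIO", "LL", "lactate_rise"), 7.2, tolerance = 1e-10)
})

test_that("identical timepoints give zero deltas; missing cells flagged", {
  tab <- simulate_study(study_spec(seed = 2))
  tab$sto2[tab$timepoint == "T1"] <-
    tab$sto2[tab$timepoint == "T0"]
  cs <- cell_summaries(tab)
  expect_equal(cs$deltas$sto2_drop, rep(0, 6), tolerance = 1e-12)
  cs2 <- cell_summaries(tab[tab$timepoint != "T1", ])
  expect_true(all(is.na(cs2$deltas$sto2_drop)))
})

test_that("ANOVA F statistics match hand-computed sums of squares", {
  # 2 lobes x 2 timepoints x 2 animals, worked by pencil:
  # cell means 10,14 / 12,20; grand mean 14; every obs = mean +- 1
  d <- data.frame(
    group = "G",
    lobe = rep(c("LL", "LM"), each = 4),
    timepoint = rep(rep(c("T0", "T1"), each = 2), 2),
    sto2 = c(9, 11, 13, 15, 11, 13, 19, 21))
  # SS_lobe = 8*(12-14)^2 + ... = 32; SS_time = 72; SS_int = 8; SS_err = 8
  # F = (SS/df) / (8/4) with df = 1 each
  res <- two_way_anova(d, "sto2")
  f <- res$anova$F[match(c("lobe", "timepoint", "lobe:timepoint"),
                         res$anova$term)]
  expect_equal(f, c(32, 72, 8) / 2, tolerance = 1e-10)
  # adjusted never below raw
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-15))
})

test_that("ANOVA handles degenerate and malformed tables by contract", {
  d <- expand.grid(animal = 1:3, lobe = c("LL", "RM"),
                   timepoint = c("T0", "T1"))
  d$group <- "G"; d$sto2 <- 5
  res <- two_way_anova(d, "sto2")
  expect_equal(res$anova$F, c(0, 0, 0))
  expect_equal(res$anova$p, c(1, 1, 1))
  d2 <- d[-(1:3), ]   # empties the LL/T0 cell
  d2$sto2 <- rnorm(nrow(d2))
  expect_error(two_way_anova(d2, "sto2"), "LL:T0")
  both <- simulate_study(study_spec(seed = 3))
  expect_error(two_way_anova(both, "sto2"), "several groups")
})

test_that("ANOVA results are invariant to row order and animal labels", {
  tab <- simulate_study(study_spec(seed = 8))
  r1 <- two_way_anova(tab, "sto2", group = "TVIO")
  set.seed(1); tab2 <- tab[sample(nrow(tab)), ]
  tab2$animal_id <- paste0("x", tab2$animal_id)
  r2 <- two_way_anova(tab2, "sto2", group = "TVIO")
  expect_equal(r1$anova$F, r2$anova$F, tolerance = 1e-12)
  expect_equal(r1$comparisons$p_adj, r2$comparisons$p_adj,
               tolerance = 1e-12)
})

test_that("significance pattern matches the occlusion physiology", {
  # at reference means/sds with n = 6: T0-vs-T1 significant in the clamped
  # left lobes, not in the right medial lobe (checked over many seeds in
  # the acceptance suite; a single seed here)
  tab <- simulate_study(study_spec(seed = 42))
  res <- two_way_anova(tab, "sto2", group = "TVIO")
  cmp <- res$comparisons[res$comparisons$contrast == "T0 - T1", ]
  expect_lt(cmp$p_adj[cmp$lobe == "LL"], 0.05)
  expect_lt(cmp$p_adj[cmp$lobe == "LM"], 0.05)
  expect_gt(cmp$p_adj[cmp$lobe == "RM"], 0.05)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  tab <- simulate_study(study_spec(seed = 4))
  cm <- correlation_matrix(tab)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), c(sto2 = 1, lactate = 1, ref_sto2 = 1))
  expect_true(all(cm$p[upper.tri(cm$p)] >= 0 & cm$p[upper.tri(cm$p)] <= 1))
  # perfectly linear pair
  tab$lactate <- 10 - 0.1 * tab$sto2
  cm2 <- correlation_matrix(tab)
  expect_equal(cm2$r["sto2", "lactate"], -1, tolerance = 1e-12)
  # zero-variance variable reported as missing with a reason
  tab$ref_sto2 <- 7
  cm3 <- correlation_matrix(tab)
  expect_true(is.na(cm3$r["sto2", "ref_sto2"]))
  expect_true(any(grepl("zero variance", cm3$notes)))
})

test_that("demarcation detection segments the ischemic territory", {
  base <- liver_scene()
  scT <- make_ischemia_scene("TVIO", "T1", base)
  oxT <- oxygenation_maps(scT$sto2 * 0 + 1e-5, scT$sto2 * 0 + 1e-5,
                          scT$sto2, pixel_pitch = base$pixel_pitch)
  dT <- detect_demarcation(oxT)
  left <- base$lobe_masks$LL | base$lobe_masks$LM
  expect_gte(mean(dT$mask[left]), 0.95)
  expect_lte(mean(dT$mask[base$lobe_masks$RM]), 0.05)
  expect_gt(nrow(dT$boundary), 10)
  # HAO's wide graded demarcation scores lower sharpness
  scH <- make_ischemia_scene("HAO", "T1", base)
  dH <- detect_demarcation(scH$sto2, pixel_pitch = base$pixel_pitch)
  expect_lt(dH$sharpness, dT$sharpness)
  # uniform well-oxygenated map -> empty result by contract
  d0 <- detect_demarcation(matrix(100, 32, 32))
  expect_false(any(d0$mask))
  expect_true(is.na(d0$sharpness))
  expect_equal(nrow(d0$boundary), 0)
})
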