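#' Reference cell means and SDs of the hemi-hepatic ischemia study
#'
#' The lobe-level group summaries the simulator reproduces: SSOP-StO2,
#' capillary lactate and t-Stat (contact oximeter) reference StO2 for each
#' occlusion group (TVIO: total vascular inflow occlusion; HAO: hepatic
#' artery occlusion), liver lobe (LL, LM, RM) and timepoint (T0 baseline,
#' T1 ischemia at 30 min after clamping, T2 reperfusion at 30 min after
#' declamping). T2 is set equal to baseline: StO2 promptly returns to
#' baseline on declamping in this model. Total inflow occlusion produces a
#' deep left-lobe desaturation and a marked lactate rise; arterial-only
#' occlusion a moderate desaturation with stable lactate; the right medial
#' lobe is essentially unchanged in both.
#'
#' @return data frame with columns `group`, `lobe`, `timepoint`,
#'   `sto2_mean`, `sto2_sd`, `lactate_mean`, `lactate_sd`,
#'   `ref_sto2_mean`, `ref_sto2_sd`.
#' @export
ischemia_reference <- function() {
  t0 <- rbind(
    data.frame(group = "TVIO", lobe = c("LL", "LM", "RM"),
               sto2_mean = c(46.0, 42.7, 48.0), sto2_sd = c(5.1, 5.9, 7.7),
               lactate_mean = c(1.3, 1.3, 1.1), lactate_sd = c(0.4, 0.4, 0.4),
               ref_sto2_mean = c(49.8, 49.8, 48.0),
               ref_sto2_sd = c(1.6, 2.4, 3.0)),
    data.frame(group = "HAO", lobe = c("LL", "LM", "RM"),
               sto2_mean = c(32.7, 35.3, 42.5), sto2_sd = c(6.4, 8.2, 5.7),
               lactate_mean = c(2.4, 2.5, 2.9), lactate_sd = c(0.9, 1.3, 1.0),
               ref_sto2_mean = c(50.3, 51.7, 50.2),
               ref_sto2_sd = c(1.9, 1.7, 1.7)))
  t1 <- rbind(
    data.frame(group = "TVIO", lobe = c("LL", "LM", "RM"),
               sto2_mean = c(16.2, 6.4, 43.2), sto2_sd = c(5.1, 4.0, 5.3),
               lactate_mean = c(8.5, 8.2, 2.2), lactate_sd = c(2.4, 2.1, 2.4),
               ref_sto2_mean = c(26.8, 28.7, 50.7),
               ref_sto2_sd = c(2.2, 1.9, 2.2)),
    data.frame(group = "HAO", lobe = c("LL", "LM", "RM"),
               sto2_mean = c(19.1, 15.5, 38.9), sto2_sd = c(5.4, 5.8, 5.4),
               lactate_mean = c(2.6, 2.5, 2.6), lactate_sd = c(1.1, 1.3, 0.8),
               ref_sto2_mean = c(38.3, 38.8, 52.5),
               ref_sto2_sd = c(2.3, 1.8, 1.2)))
  t0$timepoint <- "T0"; t1$timepoint <- "T1"
  t2 <- t0; t2$timepoint <- "T2"
  out <- rbind(t0, t1, t2)
  cols <- c("group", "lobe", "timepoint", "sto2_mean", "sto2_sd",
            "lactate_mean", "lactate_sd", "ref_sto2_mean", "ref_sto2_sd")
  out <- out[order(out$group, out$lobe, out$timepoint), cols]
  rownames(out) <- NULL
  out
}

#' Calibrate a within-cell coupling to a target pooled correlation
#'
#' Given the cell means/SDs of two variables and a target Pearson
#' correlation over the pooled observations, solves in closed form for the
#' within-cell correlation `rw` that achieves it. With balanced cells, the
#' pooled covariance decomposes into the between-cell covariance of the
#' means plus `rw` times the mean within-cell SD product, and the pooled
#' variances into between-cell variance of means plus mean within-cell
#' variance; `rw` follows by inverting the ratio.
#'
#' @param mean_x,mean_y cell means of the two variables.
#' @param sd_x,sd_y cell standard deviations.
#' @param target_r desired pooled Pearson correlation.
#' @return the within-cell correlation (in \[-1, 1\]); errors if the target
#'   is unreachable for the given cell structure.
#' @export
calibrate_coupling <- function(mean_x, mean_y, sd_x, sd_y, target_r) {
  pvar <- function(m) mean(m^2) - mean(m)^2
  cov_b <- mean(mean_x * mean_y) - mean(mean_x) * mean(mean_y)
  v_x <- pvar(mean_x) + mean(sd_x^2)
  v_y <- pvar(mean_y) + mean(sd_y^2)
  rw <- (target_r * sqrt(v_x * v_y) - cov_b) / mean(sd_x * sd_y)
  if (!is.finite(rw) || abs(rw) > 1)
    stop("target pooled correlation ", target_r,
         " unreachable with the given cell structure (needs within-cell r = ",
         round(rw, 3), ")", call. = FALSE)
  rw
}

#' Specification of the synthetic two-group ischemia study
#'
#' Defines the statistical structure of the virtual TVIO/HAO experiment:
#' six animals per group, three lobes, three timepoints, with cell means
#' and SDs defaulting to the reference summaries of
#' [ischemia_reference()]. Within each animal-lobe-timepoint cell, lactate
#' is coupled negatively to the same observation's StO2 and the t-Stat
#' reference StO2 positively, with within-cell correlations calibrated in
#' closed form so the pooled Pearson correlations hit configurable targets
#' (defaults: r(StO2, lactate) = -0.76, r(StO2, t-Stat) = 0.82).
#'
#' @param n_animals_per_group animals per group (default 6).
#' @param cells cell means/SDs table, format of [ischemia_reference()].
#' @param lactate_coupling within-cell StO2-lactate correlation; default
#'   NULL = calibrate to `target_r_lactate`.
#' @param ref_coupling within-cell StO2 vs reference-StO2 correlation;
#'   default NULL = calibrate to `target_r_ref`.
#' @param target_r_lactate,target_r_ref pooled correlation targets.
#' @param seed integer seed fixing all randomness of the simulation.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(n_animals_per_group = 6,
                       cells = ischemia_reference(),
                       lactate_coupling = NULL, ref_coupling = NULL,
                       target_r_lactate = -0.76, target_r_ref = 0.82,
                       seed = 1L) {
  stopifnot(all(cells$sto2_sd >= 0), all(cells$lactate_sd >= 0),
            all(cells$ref_sto2_sd >= 0))
  if (is.null(lactate_coupling))
    lactate_coupling <- calibrate_coupling(
      cells$sto2_mean, cells$lactate_mean,
      cells$sto2_sd, cells$lactate_sd, target_r_lactate)
  if (is.null(ref_coupling))
    ref_coupling <- calibrate_coupling(
      cells$sto2_mean, cells$ref_sto2_mean,
      cells$sto2_sd, cells$ref_sto2_sd, target_r_ref)
  structure(list(n_animals_per_group = n_animals_per_group,
                 cells = cells, lactate_coupling = lactate_coupling,
                 ref_coupling = ref_coupling, seed = as.integer(seed)),
            class = "study_spec")
}

#' Simulate a lobe-level ischemia study table
#'
#' Draws per-animal lobe measurements from normal distributions with the
#' spec's cell means and SDs. For each observation, with standard normal
#' draws \eqn{z_s, z_l, z_r}:
#' \deqn{StO_2 = m_s + s_s z_s,\quad
#'   lactate = m_l + s_l(\rho_l z_s + \sqrt{1-\rho_l^2}\, z_l),\quad
#'   ref = m_r + s_r(\rho_r z_s + \sqrt{1-\rho_r^2}\, z_r)}
#' so each cell keeps its printed mean and SD while lactate and the
#' reference oximeter track the same animal's StO2 with the calibrated
#' within-cell correlations. The draw order is fixed, so a given seed
#' yields an identical table; with `noise = FALSE` every observation
#' equals its cell mean exactly.
#'
#' @param spec a [study_spec()].
#' @param noise logical; FALSE sets all SDs to zero.
#' @return data frame (`study_table`) with columns `animal_id`, `group`,
#'   `lobe`, `timepoint`, `sto2`, `lactate`, `ref_sto2`.
#' @export
simulate_study <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "study_spec"))
  cells <- spec$cells
  groups <- unique(cells$group)
  rows <- expand.grid(
    animal = seq_len(spec$n_animals_per_group), group = groups,
    lobe = unique(cells$lobe), timepoint = unique(cells$timepoint),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(rows$group, rows$animal, rows$lobe, rows$timepoint), ]
  key <- interaction(rows$group, rows$lobe, rows$timepoint, drop = TRUE)
  ckey <- interaction(cells$group, cells$lobe, cells$timepoint, drop = TRUE)
  idx <- match(key, ckey)
  if (anyNA(idx)) stop("cells table does not cover the full design",
                       call. = FALSE)
  n <- nrow(rows)
  z <- with_seed(derive_seed(spec$seed, "study"),
                 matrix(stats::rnorm(3 * n), n, 3))
  if (!noise) z[] <- 0
  sd_s <- cells$sto2_sd[idx]; sd_l <- cells$lactate_sd[idx]
  sd_r <- cells$ref_sto2_sd[idx]
  rl <- spec$lactate_coupling; rr <- spec$ref_coupling
  out <- data.frame(
    animal_id = paste0(rows$group, "_", rows$animal),
    group = rows$group, lobe = rows$lobe, timepoint = rows$timepoint,
    sto2 = cells$sto2_mean[idx] + sd_s * z[, 1],
    lactate = cells$lactate_mean[idx] +
      sd_l * (rl * z[, 1] + sqrt(1 - rl^2) * z[, 2]),
    ref_sto2 = cells$ref_sto2_mean[idx] +
      sd_r * (rr * z[, 1] + sqrt(1 - rr^2) * z[, 3]))
  rownames(out) <- NULL
  class(out) <- c("study_table", "data.frame")
  out
}
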