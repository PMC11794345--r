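#' Cell summaries and baseline-ischemia deltas
#'
#' Per (group, lobe, timepoint) means and SDs of StO2, lactate and the
#' reference oximeter StO2, plus the headline per-lobe effect sizes:
#' the StO2 drop `mean(T0) - mean(T1)` (percentage points, likewise for
#' the reference oximeter) and the lactate rise `mean(T1) - mean(T0)`
#' (mmol/L). Cells missing from the table yield explicit records with NA
#' summaries and `missing = TRUE` rather than being dropped.
#'
#' @param table a study table (see [simulate_study()]).
#' @return list of class `cell_summaries` with elements `cells` (long
#'   summary) and `deltas` (one row per group x lobe with `sto2_drop`,
#'   `ref_sto2_drop`, `lactate_rise`).
#' @export
cell_summaries <- function(table) {
  vars <- c("sto2", "lactate", "ref_sto2")
  stopifnot(all(c("group", "lobe", "timepoint", vars) %in% names(table)))
  grid <- expand.grid(group = unique(table$group),
                      lobe = unique(table$lobe),
                      timepoint = unique(table$timepoint),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- table$group == grid$group[i] & table$lobe == grid$lobe[i] &
      table$timepoint == grid$timepoint[i]
    n <- sum(sel)
    row <- grid[i, ]
    row$n <- n; row$missing <- n == 0L
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- if (n) mean(table[[v]][sel]) else NA_real_
      row[[paste0(v, "_sd")]] <- if (n > 1) stats::sd(table[[v]][sel]) else
        if (n == 1) 0 else NA_real_
    }
    row
  }))
  pick <- function(g, l, tp, col) {
    v <- cells[cells$group == g & cells$lobe == l & cells$timepoint == tp,
               col]
    if (length(v) == 1) v else NA_real_
  }
  gl <- unique(cells[, c("group", "lobe")])
  deltas <- do.call(rbind, lapply(seq_len(nrow(gl)), function(i) {
    g <- gl$group[i]; l <- gl$lobe[i]
    data.frame(
      group = g, lobe = l,
      sto2_drop = pick(g, l, "T0", "sto2_mean") -
        pick(g, l, "T1", "sto2_mean"),
      ref_sto2_drop = pick(g, l, "T0", "ref_sto2_mean") -
        pick(g, l, "T1", "ref_sto2_mean"),
      lactate_rise = pick(g, l, "T1", "lactate_mean") -
        pick(g, l, "T0", "lactate_mean"))
  }))
  rownames(cells) <- rownames(deltas) <- NULL
  structure(list(cells = cells, deltas = deltas), class = "cell_summaries")
}

#' @export
print.cell_summaries <- function(x, ...) {
  cat("Baseline - ischemia effect sizes per group and lobe:\n")
  print(x$deltas, digits = 3)
  invisible(x)
}

#' Two-way ANOVA with per-lobe multiple comparisons
#'
#' Classical two-factor (lobe x timepoint) ANOVA with interaction on one
#' response of a single-group study table, followed by pairwise timepoint
#' comparisons within each lobe (estimated via \pkg{emmeans}),
#' Sidak-adjusted across the whole family of comparisons.
#' Results are deterministic and invariant to row order. A degenerate
#' table with zero total variance returns F = 0 and p = 1 for all terms by
#' contract.
#'
#' @param table study table; must contain a single group, or pass `group`
#'   to select one.
#' @param response response column (default `"sto2"`).
#' @param group optional group to filter to.
#' @param adjust multiplicity adjustment for the pairwise comparisons
#'   (default `"sidak"`).
#' @return list of class `comparison_result` with `anova` (term table),
#'   `cells` (means/SDs), `comparisons` (per-lobe timepoint contrasts with
#'   raw and adjusted p), `response`.
#' @export
two_way_anova <- function(table, response = "sto2", group = NULL,
                          adjust = "sidak") {
  if (!is.null(group)) table <- table[table$group == group, ]
  if (length(unique(table$group)) > 1)
    stop("table contains several groups; pass `group` to select one",
         call. = FALSE)
  d <- data.frame(
    y = table[[response]],
    lobe = factor(table$lobe, levels = sort(unique(table$lobe))),
    timepoint = factor(table$timepoint,
                       levels = sort(unique(table$timepoint))))
  if (nlevels(d$lobe) < 2 || nlevels(d$timepoint) < 2)
    stop("need at least 2 levels per factor", call. = FALSE)
  counts <- table(d$lobe, d$timepoint)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)
    stop("cells with < 2 replicates: ",
         paste(rownames(counts)[bad[, 1]], colnames(counts)[bad[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(y ~ lobe + timepoint, d,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  cells <- data.frame(lobe = agg$lobe, timepoint = agg$timepoint,
                      mean = agg$y[, "mean"], sd = agg$y[, "sd"])
  if (stats::var(d$y) < .Machine$double.eps) {
    terms <- c("lobe", "timepoint", "lobe:timepoint")
    return(structure(list(
      anova = data.frame(term = terms, df = NA_real_, F = 0, p = 1),
      cells = cells,
      comparisons = data.frame(),
      response = response, adjust = adjust),
      class = "comparison_result"))
  }
  fit <- stats::aov(y ~ lobe * timepoint, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  anova_df <- data.frame(term = terms, df = tab$Df, F = tab$`F value`,
                         p = tab$`Pr(>F)`)
  anova_df <- anova_df[anova_df$term != "Residuals", ]
  em <- emmeans::emmeans(fit, ~ timepoint | lobe)
  ctr <- emmeans::contrast(em, method = "pairwise")
  raw <- as.data.frame(summary(ctr, adjust = "none"))
  # adjust across the whole family of pairwise comparisons (all lobes),
  # as the usual two-way-ANOVA multiple-comparison reports do
  k <- nrow(raw)
  p_adj <- switch(adjust,
                  sidak = 1 - (1 - raw$p.value)^k,
                  none = raw$p.value,
                  stats::p.adjust(raw$p.value, method = adjust))
  comparisons <- data.frame(
    lobe = raw$lobe, contrast = raw$contrast, estimate = raw$estimate,
    se = raw$SE, t = raw$t.ratio, df = raw$df,
    p_raw = raw$p.value, p_adj = pmax(p_adj, raw$p.value))
  structure(list(anova = anova_df, cells = cells,
                 comparisons = comparisons, response = response,
                 adjust = adjust),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Two-way ANOVA on", x$response, "\n")
  print(x$anova, digits = 4)
  if (nrow(x$comparisons)) {
    cat("\nPairwise timepoint comparisons per lobe (", x$adjust,
        "-adjusted):\n", sep = "")
    print(x$comparisons, digits = 4)
  }
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations between study variables over pooled observations
#' (pairwise-complete), with two-sided p-values. Zero-variance variables
#' yield NA entries with the reason recorded.
#'
#' @param table study table.
#' @param variables columns to correlate.
#' @param group optional single group to filter to (default: pool all).
#' @return list of class `correlation_matrix` with matrices `r`, `p`, `n`
#'   and a character vector `notes`.
#' @export
correlation_matrix <- function(table,
                               variables = c("sto2", "lactate", "ref_sto2"),
                               group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, ]
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k,
                           dimnames = list(variables, variables))
  diag(r) <- 1
  notes <- character()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    x <- table[[variables[i]]]; y <- table[[variables[j]]]
    ok <- stats::complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3) { notes <- c(notes, paste0(
      variables[i], "-", variables[j], ": fewer than 3 complete pairs"))
      next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      notes <- c(notes, paste0(variables[i], "-", variables[j],
                               ": zero variance, correlation undefined"))
      next
    }
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nmat, notes = notes),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pearson correlations (pooled, pairwise-complete):\n")
  print(round(x$r, 3))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Detect the ischemic demarcation on a StO2 map
#'
#' Thresholds the StO2 map at a fixed absolute ischemia cutoff (default
#' 25%), keeps the largest connected component of sub-threshold valid
#' pixels, and extracts its boundary. The sharpness score is the median
#' StO2 gradient magnitude along the boundary (%/mm when the pixel pitch
#' is known): a crisp demarcation line scores high, a graded transition
#' low. An absolute rather than relative cutoff mirrors the clinical use
#' of a fixed ischemia threshold. If no pixel falls below the cutoff the
#' mask is empty and the score is NA by contract.
#'
#' @param sto2 an [oxygenation_maps()] or a plain StO2 matrix (%).
#' @param threshold absolute StO2 cutoff, percent (default 25).
#' @param pixel_pitch mm/px; taken from the maps when available, else 1
#'   (score then in %/px).
#' @return list of class `demarcation` with `mask` (logical), `boundary`
#'   (n x 2 matrix of row/col coordinates ordered by polar angle around
#'   the component centroid), `sharpness` and `threshold`.
#' @export
detect_demarcation <- function(sto2, threshold = 25, pixel_pitch = NULL) {
  if (inherits(sto2, "oxygenation_maps")) {
    pixel_pitch <- pixel_pitch %||%
      (if (is.na(sto2$pixel_pitch)) 1 else sto2$pixel_pitch)
    valid <- sto2$valid
    sto2 <- sto2$sto2
  } else {
    pixel_pitch <- pixel_pitch %||% 1
    valid <- !is.na(sto2)
  }
  below <- valid & !is.na(sto2) & sto2 < threshold
  empty <- list(mask = matrix(FALSE, nrow(sto2), ncol(sto2)),
                boundary = matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("row", "col"))),
                sharpness = NA_real_, threshold = threshold)
  class(empty) <- "demarcation"
  if (!any(below)) return(empty)
  labels <- EBImage::bwlabel(below * 1)
  counts <- tabulate(labels[labels > 0])
  comp <- labels == which.max(counts)
  pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  interior <- pad[1:nrow(comp), 2:(ncol(comp) + 1)] &
    pad[3:(nrow(comp) + 2), 2:(ncol(comp) + 1)] &
    pad[2:(nrow(comp) + 1), 1:ncol(comp)] &
    pad[2:(nrow(comp) + 1), 3:(ncol(comp) + 2)]
  boundary_mask <- comp & !interior
  # the demarcation is the interior boundary; drop pixels lying on the
  # image border (field-of-view edges, not tissue boundaries)
  edge <- matrix(FALSE, nrow(comp), ncol(comp))
  edge[c(1, nrow(comp)), ] <- TRUE; edge[, c(1, ncol(comp))] <- TRUE
  if (any(boundary_mask & !edge)) boundary_mask <- boundary_mask & !edge
  coords <- which(boundary_mask, arr.ind = TRUE)
  ctr <- colMeans(coords)
  ord <- order(atan2(coords[, 1] - ctr[1], coords[, 2] - ctr[2]))
  coords <- coords[ord, , drop = FALSE]
  colnames(coords) <- c("row", "col")
  s_filled <- sto2
  s_filled[!valid] <- stats::median(sto2[valid])
  g <- gradient_mm(s_filled, pixel_pitch)
  gm <- sqrt(g$gx^2 + g$gy^2)
  sharpness <- stats::median(gm[boundary_mask])
  structure(list(mask = comp, boundary = coords, sharpness = sharpness,
                 threshold = threshold),
            class = "demarcation")
}
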