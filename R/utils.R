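# Internal helpers shared across the pipeline.

#' @noRd
stop_stage <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}

# Deterministic per-module seed derivation so that one top-level seed drives
# every random substream without streams colliding.
#' @noRd
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log-spaced sequence
#' @noRd
lseq <- function(from, to, length.out) exp(seq(log(from), log(to), length.out = length.out))

# Replicate-padded separable Gaussian smoothing of a matrix. sigma in pixels;
# sigma = 0 returns the input unchanged.
#' @noRd
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(x) {
    # x: matrix, convolve along rows (dim 1) with kernel k, replicate padding
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

# Centered-difference gradients of a matrix in metric units (per mm).
# Returns list(gx, gy) with gx along columns (image x) and gy along rows.
#' @noRd
gradient_mm <- function(m, pixel_pitch) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / (2 * pixel_pitch)
  gx[, 1] <- (m[, 2] - m[, 1]) / pixel_pitch
  gx[, nc] <- (m[, nc] - m[, nc - 1]) / pixel_pitch
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / (2 * pixel_pitch)
  gy[1, ] <- (m[2, ] - m[1, ]) / pixel_pitch
  gy[nr, ] <- (m[nr, ] - m[nr - 1, ]) / pixel_pitch
  list(gx = gx, gy = gy)
}

# Vectorized bilinear interpolation of a surface z defined on regular grids
# (xg, yg) at query points (x, y). Queries outside the grid, or touching an
# NA corner, return NA.
#' @noRd
bilinear_lookup <- function(xg, yg, z, x, y) {
  nx <- length(xg); ny <- length(yg)
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  ix <- floor((x - xg[1]) / dx) + 1
  iy <- floor((y - yg[1]) / dy) + 1
  ok <- !is.na(x) & !is.na(y) & ix >= 1 & ix <= nx - 1 & iy >= 1 & iy <= ny - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  ix <- pmin(pmax(ix[ok], 1), nx - 1); iy <- pmin(pmax(iy[ok], 1), ny - 1)
  tx <- (x[ok] - xg[ix]) / dx
  ty <- (y[ok] - yg[iy]) / dy
  z11 <- z[cbind(ix, iy)];     z21 <- z[cbind(ix + 1, iy)]
  z12 <- z[cbind(ix, iy + 1)]; z22 <- z[cbind(ix + 1, iy + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
    (1 - tx) * ty * z12 + tx * ty * z22
  out
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
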