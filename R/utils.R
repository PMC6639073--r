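# Internal numeric helpers shared across modules.

# Set the RNG locally when a seed is supplied; restores the caller's RNG
# state on exit of the *calling* function.
withSeed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), globalenv())),
                 add = TRUE), envir = envir)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}

# 2D convolution with edge replication, output same size as x.
# Kernel dims must be odd. Direct shifted-sum accumulation: fast enough for
# the small LoG kernels used here and free of FFT wrap-around.
conv2same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ridx <- pmin(pmax(seq_len(nr + 2L * hr) - hr, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2L * hc) - hc, 1L), nc)
  xp <- x[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- k[i, j]
      if (w == 0) next
      out <- out + w * xp[(kr - i) + seq_len(nr), (kc - j) + seq_len(nc)]
    }
  }
  out
}

# Scale-normalized negative Laplacian-of-Gaussian kernel: positive response
# on bright blobs of width ~sigma. Zero-mean so flat regions respond 0.
logKernel <- function(sigma, halfwidth = ceiling(4 * sigma)) {
  r <- -halfwidth:halfwidth
  g <- exp(-r^2 / (2 * sigma^2))
  G <- outer(g, g)
  rr2 <- outer(r^2, r^2, "+")
  k <- -(rr2 - 2 * sigma^2) / sigma^2 * G   # -sigma^2 * LoG
  k - mean(k)
}

# Bilinear interpolation of matrix m at sub-pixel 0-based (row, col)
# positions. Positions are clamped to the valid interpolation domain.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(row, 0), nr - 1)
  c <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i0 <- r0 + 1L; j0 <- c0 + 1L
  m[cbind(i0, j0)] * (1 - fr) * (1 - fc) +
    m[cbind(i0 + 1L, j0)] * fr * (1 - fc) +
    m[cbind(i0, j0 + 1L)] * (1 - fr) * fc +
    m[cbind(i0 + 1L, j0 + 1L)] * fr * fc
}

# Expected photons per pixel for a particle of total photon count 'photons'
# at sub-pixel (row0, col0): the 2D Gaussian PSF integrated over each pixel
# (pnorm differences), so the sum over the support window equals 'photons'
# up to window truncation. Returns list(rows, cols, values) of the window.
pixelatedGaussian <- function(row0, col0, sigma, photons, nr, nc,
                              halfwidth = ceiling(6 * sigma)) {
  r0 <- round(row0); c0 <- round(col0)
  rows <- max(0, r0 - halfwidth):min(nr - 1, r0 + halfwidth)
  cols <- max(0, c0 - halfwidth):min(nc - 1, c0 + halfwidth)
  fr <- pnorm(rows + 0.5, row0, sigma) - pnorm(rows - 0.5, row0, sigma)
  fc <- pnorm(cols + 0.5, col0, sigma) - pnorm(cols - 0.5, col0, sigma)
  list(rows = rows, cols = cols, values = photons * outer(fr, fc))
}

# Point-sampled unit-height Gaussian mask centred at sub-pixel (row0, col0),
# evaluated on the pixel grid rows x cols (0-based centres).
gaussMask <- function(rows, cols, row0, col0, sigma) {
  outer(exp(-(rows - row0)^2 / (2 * sigma^2)),
        exp(-(cols - col0)^2 / (2 * sigma^2)))
}

# Distance-to-edge map of a mask in pixels, sub-pixel convention: mask
# pixels adjacent to background sit 0.5 px from the boundary line that
# separates pixel centres, so the transform is distmap - 0.5, floored at 0.
#' @importFrom EBImage distmap
edgeDistanceMapPx <- function(mask) {
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  pmax(d - 0.5, 0)
}

# 0-based pixel-centre coordinate grids for a matrix.
gridRows <- function(m) matrix(seq_len(nrow(m)) - 1L, nrow(m), ncol(m))
gridCols <- function(m) matrix(rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
                               nrow(m), ncol(m))

geomMean <- function(x) exp(mean(log(x)))
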