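# Shared fixtures and independent oracles for the test suite.

# Small geometry used across tests (62 x 62 px at 0.32 um/px).
testGeometry <- function(sizeUm = 20, pixelSize = 0.32, nProtrusions = 0,
                         seed = 1) {
  makeCellGeometry(sizeUm, sizeUm, nProtrusions = nProtrusions,
                   pixelSize = pixelSize, seed = seed)
}

# Disc cell of radius R um centred in a square image, built directly so its
# analytic geometry is known exactly.
discGeometry <- function(radiusUm = 8, pixelSize = 0.32, marginPx = 4,
                         nucleusFrac = 0.3) {
  rPx <- radiusUm / pixelSize
  n <- ceiling(2 * (rPx + marginPx))
  ctr <- (n - 1) / 2
  gr <- matrix(seq_len(n) - 1, n, n)
  gc <- t(gr)
  d2 <- (gr - ctr)^2 + (gc - ctr)^2
  cell <- d2 <= rPx^2
  nuc <- d2 <= (nucleusFrac * rPx)^2
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  poly <- cbind(row = ctr + rPx * sin(th), col = ctr + rPx * cos(th))
  new("CellGeometry", cellMask = cell, nucleusMask = nuc,
      edgePolygon = poly, protrusionTips = matrix(numeric(0), 0, 2),
      pixelSize = pixelSize)
}

# Render a single pixel-integrated Gaussian spot on constant background,
# with optional Poisson + read noise, as a plain matrix.
spotImage <- function(row0, col0, photons, sigma = 1.3, bg = 50,
                      offset = 100, dims = c(21, 21), noise = TRUE,
                      readNoise = 2) {
  ph <- matrix(bg, dims[1], dims[2])
  g <- periTrans:::pixelatedGaussian(row0, col0, sigma, photons,
                                     dims[1], dims[2])
  ph[g$rows + 1, g$cols + 1] <- ph[g$rows + 1, g$cols + 1] + g$values
  if (noise) {
    matrix(offset + rpois(length(ph), ph) + rnorm(length(ph), 0, readNoise),
           dims[1], dims[2])
  } else {
    offset + ph
  }
}

# Independent localization oracle: nonlinear least-squares fit of a
# point-sampled 2D Gaussian (position, amplitude, constant background).
lsGaussianFit <- function(img, sigma, start) {
  rows <- 0:(nrow(img) - 1); cols <- 0:(ncol(img) - 1)
  obj <- function(p) {
    mdl <- p[3] * periTrans:::gaussMask(rows, cols, p[1], p[2], sigma) + p[4]
    sum((img - mdl)^2)
  }
  o <- optim(c(start, max(img) - median(img), median(img)), obj,
             control = list(maxit = 2000, reltol = 1e-12))
  list(row = o$par[1], col = o$par[2],
       intensity = 2 * pi * sigma^2 * o$par[3])
}

# Brute-force min distance (px) from points to a closed polygon's segments.
brutePolyDistance <- function(poly, pts) {
  nv <- nrow(poly)
  apply(pts, 1, function(p) {
    dmin <- Inf
    for (i in seq_len(nv)) {
      a <- poly[i, ]; b <- poly[if (i == nv) 1 else i + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      dmin <- min(dmin, sqrt(sum((p - (a + t * ab))^2)))
    }
    dmin
  })
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the same margins whose probability does
# not exceed the observed table's (with a tiny relative tolerance).
fisherEnumP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# A noise-free particle table for statistics-level tests.
syntheticParticleTable <- function(n, efficiency, distance, mcherryNorm = 2,
                                   gfpNorm = efficiency * mcherryNorm) {
  data.frame(particle_id = seq_len(n), row_px = 0, col_px = 0,
             mcherry_int = 1000, gfp_int = 1000,
             mcherry_norm = mcherryNorm, gfp_norm = gfpNorm,
             efficiency = efficiency, distance_um = distance,
             label = "unknown")
}
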