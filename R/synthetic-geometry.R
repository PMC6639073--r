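#' Generate a synthetic cell geometry
#'
#' Builds a star-shaped, simply connected cell mask from a smoothly
#' perturbed radial outline, optionally with narrow finger-like protrusions
#' whose tip coordinates are recorded, and an elliptical nucleus centred in
#' the cell body. The outline polygon is rasterized onto a pixel grid of
#' the requested physical size.
#'
#' @param widthUm,heightUm physical extent of the image in micrometres;
#'   must exceed 10 pixels each.
#' @param nProtrusions number of protrusions (>= 0).
#' @param pixelSize micrometres per pixel.
#' @param seed integer seed; the same seed reproduces the geometry exactly.
#' @param protrusionLengthUm length of each protrusion beyond the cell body.
#' @param bodyFraction cell-body radius as a fraction of the half-extent.
#' @param nucleusFraction nucleus semi-axis as a fraction of the body radius.
#' @return A \linkS4class{CellGeometry}.
#' @examples
#' geom <- makeCellGeometry(40, 40, nProtrusions = 3, pixelSize = 0.32,
#'                          seed = 1)
#' geom
#' @export
makeCellGeometry <- function(widthUm, heightUm, nProtrusions = 0,
                             pixelSize = 0.16, seed = NULL,
                             protrusionLengthUm = 6, bodyFraction = 0.32,
                             nucleusFraction = 0.38) {
  if (widthUm <= 10 * pixelSize || heightUm <= 10 * pixelSize) {
    stop("image extent must exceed 10 pixels in each direction")
  }
  if (nProtrusions < 0) stop("'nProtrusions' must be >= 0")
  withSeed(seed)

  nc <- round(widthUm / pixelSize)
  nr <- round(heightUm / pixelSize)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  aRow <- bodyFraction * nr
  aCol <- bodyFraction * nc

  # smooth radial perturbation: three random low-order harmonics, +/- ~8%
  nHarm <- 3L
  amp <- runif(nHarm, 0.02, 0.05)
  phase <- runif(nHarm, 0, 2 * pi)
  ord <- sample(2:5, nHarm)
  tipTheta <- if (nProtrusions > 0) {
    sort((seq_len(nProtrusions) - 1) * 2 * pi / nProtrusions +
           runif(1, 0, 2 * pi) + runif(nProtrusions, -0.2, 0.2)) %% (2 * pi)
  } else numeric(0)

  protLenPx <- protrusionLengthUm / pixelSize
  protWidth <- 0.07                     # angular half-width (radians)

  radiusAt <- function(theta) {
    base <- 1 / sqrt((cos(theta) / aCol)^2 + (sin(theta) / aRow)^2)
    pert <- rep(1, length(theta))
    for (h in seq_len(nHarm)) {
      pert <- pert + amp[h] * cos(ord[h] * theta + phase[h])
    }
    r <- base * pert
    for (t0 in tipTheta) {
      dth <- abs(theta - t0)
      dth <- pmin(dth, 2 * pi - dth)
      r <- r + protLenPx * exp(-0.5 * (dth / protWidth)^2)
    }
    # keep the outline inside the raster with a 2 px margin
    rmax <- 0.98 / sqrt((cos(theta) / ((nc - 5) / 2))^2 +
                        (sin(theta) / ((nr - 5) / 2))^2)
    pmin(r, rmax)
  }

  theta <- sort(unique(c(seq(0, 2 * pi, length.out = 1441L)[-1441L],
                         tipTheta)))
  r <- radiusAt(theta)
  poly <- cbind(row = ctr[1] + r * sin(theta), col = ctr[2] + r * cos(theta))
  rTip <- radiusAt(tipTheta)
  tips <- cbind(row = ctr[1] + rTip * sin(tipTheta),
                col = ctr[2] + rTip * cos(tipTheta))

  pts <- cbind(as.vector(gridRows(matrix(0, nr, nc))),
               as.vector(gridCols(matrix(0, nr, nc))))
  inside <- mgcv::in.out(poly, pts)
  cell <- matrix(inside, nr, nc)

  # axis-aligned elliptical nucleus centred in the cell body
  bRow <- nucleusFraction * aRow
  bCol <- nucleusFraction * aCol
  nuc <- ((gridRows(cell) - ctr[1]) / bRow)^2 +
         ((gridCols(cell) - ctr[2]) / bCol)^2 <= 1
  if (any(nuc & !cell)) {
    stop("nucleus does not fit inside the cell mask; ",
         "reduce 'nucleusFraction' or enlarge the cell")
  }
  new("CellGeometry", cellMask = cell, nucleusMask = nuc,
      edgePolygon = poly, protrusionTips = tips, pixelSize = pixelSize)
}
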