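#' Normalize a spot region to nearby diffuse cytoplasm
#'
#' Returns the ratio of the mean offset-corrected intensity in a disc
#' around the position to the mean in a surrounding annulus of diffuse
#' cytoplasm. The annulus is intersected with the cell mask (when given)
#' and excludes pixels near other detected spots, so the denominator
#' reflects free fluorophore only. A value of 1 means no local
#' concentration above the diffuse signal.
#'
#' @param frame an \linkS4class{ImageFrame}.
#' @param position numeric (row, col), sub-pixel, 0-based.
#' @param spotRadius disc radius in pixels (default 2.6 = 2 sigma at the
#'   default PSF).
#' @param annulusRadii numeric(2) inner/outer annulus radii in pixels;
#'   default 5 and 9 sigma at the default PSF.
#' @param mask optional logical cell mask; annulus pixels outside it are
#'   discarded.
#' @param excludePositions optional matrix/data.frame of other spot
#'   positions (\code{row_px}, \code{col_px}); annulus pixels within
#'   \code{excludeRadius} of any of them are discarded.
#' @param excludeRadius exclusion radius around other spots, pixels.
#' @param offset camera offset subtracted from both means before the ratio.
#' @return The normalized intensity (dimensionless).
#' @examples
#' img <- ImageFrame(matrix(150, 64, 64))
#' normalizeToLocalCytoplasm(img, c(32, 32), offset = 100)  # 1
#' @export
normalizeToLocalCytoplasm <- function(frame, position, spotRadius = 2.6,
                                      annulusRadii = c(6.5, 11.7),
                                      mask = NULL, excludePositions = NULL,
                                      excludeRadius = spotRadius,
                                      offset = 0) {
  stopifnot(is(frame, "ImageFrame"), length(annulusRadii) == 2,
            annulusRadii[1] > spotRadius, annulusRadii[2] > annulusRadii[1])
  x <- frame@pixels
  nr <- nrow(x); nc <- ncol(x)
  hw <- ceiling(annulusRadii[2])
  r0 <- position[1]; c0 <- position[2]
  if (round(r0) - hw < 0 || round(r0) + hw > nr - 1 ||
      round(c0) - hw < 0 || round(c0) + hw > nc - 1) {
    stop("normalization annulus extends beyond the image border",
         call. = FALSE)
  }
  rows <- (round(r0) - hw):(round(r0) + hw)
  cols <- (round(c0) - hw):(round(c0) + hw)
  rr <- outer((rows - r0)^2, (cols - c0)^2, "+")
  win <- x[rows + 1L, cols + 1L]
  inDisc <- rr <= spotRadius^2
  inAnn <- rr > annulusRadii[1]^2 & rr <= annulusRadii[2]^2
  if (!is.null(mask)) {
    # keep both regions inside the cell: pixels beyond the membrane carry
    # no diffuse fluorophore and would dilute the means
    inCell <- mask[rows + 1L, cols + 1L]
    inAnn <- inAnn & inCell
    inDisc <- inDisc & inCell
    if (!any(inDisc)) {
      stop("spot disc lies outside the cell mask", call. = FALSE)
    }
  }
  if (!is.null(excludePositions)) {
    ep <- as.matrix(as.data.frame(excludePositions)[,
            c("row_px", "col_px")])
    for (i in seq_len(nrow(ep))) {
      if (abs(ep[i, 1] - r0) < 1e-9 && abs(ep[i, 2] - c0) < 1e-9) next
      d2 <- outer((rows - ep[i, 1])^2, (cols - ep[i, 2])^2, "+")
      inAnn <- inAnn & d2 > excludeRadius^2
    }
  }
  if (!any(inAnn)) {
    stop("normalization annulus fully occluded; no diffuse pixels left",
         call. = FALSE)
  }
  denom <- mean(win[inAnn]) - offset
  if (denom <= 0) {
    stop("diffuse background at or below the camera offset; cannot ",
         "normalize", call. = FALSE)
  }
  (mean(win[inDisc]) - offset) / denom
}

#' Build two-channel particles anchored on RNA spots
#'
#' For every localized RNA (mCherry) spot, records the nascent-chain (GFP)
#' intensity at the same position by fixed-position Gaussian-mask
#' photometry, normalizes both channels to nearby diffuse cytoplasm, and
#' computes the per-particle translation efficiency. Spots whose photometry
#' or normalization windows hit the image border are dropped and counted in
#' the \code{"qc"} attribute.
#'
#' @param mcherrySpots data.frame of localized mCherry spots
#'   (\code{\link{localizeSpot}} rows).
#' @param gfpFrame,mcherryFrame the two \linkS4class{ImageFrame}s.
#' @param geometry a \linkS4class{CellGeometry}; provides the cell mask for
#'   normalization and the edge distances.
#' @param psfSigma PSF sigma in pixels.
#' @param offset camera offset in counts.
#' @param efficiencyMode \code{"normalized"} (default): efficiency =
#'   normalized GFP / normalized mCherry; \code{"raw"}: ratio of
#'   background-subtracted integrated intensities.
#' @return A data.frame with one row per retained particle:
#'   \code{particle_id}, \code{row_px}, \code{col_px}, \code{mcherry_int},
#'   \code{gfp_int}, \code{mcherry_norm}, \code{gfp_norm},
#'   \code{efficiency}, \code{distance_um}, \code{label} (initialised to
#'   \code{"unknown"}). Attribute \code{"qc"}: counts of dropped spots.
#' @export
buildParticles <- function(mcherrySpots, gfpFrame, mcherryFrame, geometry,
                           psfSigma = 1.3, offset = 100,
                           efficiencyMode = c("normalized", "raw")) {
  efficiencyMode <- match.arg(efficiencyMode)
  stopifnot(is(gfpFrame, "ImageFrame"), is(mcherryFrame, "ImageFrame"),
            is(geometry, "CellGeometry"))
  n <- nrow(mcherrySpots)
  rows <- vector("list", n)
  dropped <- 0L
  mask <- geometry@cellMask
  for (i in seq_len(n)) {
    pos <- c(mcherrySpots$row_px[i], mcherrySpots$col_px[i])
    res <- tryCatch({
      gfp <- measureAt(gfpFrame, pos, psfSigma)
      mcN <- normalizeToLocalCytoplasm(
        mcherryFrame, pos, spotRadius = 2 * psfSigma,
        annulusRadii = c(5, 9) * psfSigma, mask = mask,
        excludePositions = mcherrySpots, excludeRadius = 2 * psfSigma,
        offset = offset)
      gfN <- normalizeToLocalCytoplasm(
        gfpFrame, pos, spotRadius = 2 * psfSigma,
        annulusRadii = c(5, 9) * psfSigma, mask = mask,
        excludePositions = mcherrySpots, excludeRadius = 2 * psfSigma,
        offset = offset)
      dist <- distanceToEdge(geometry, matrix(pos, 1, 2))
      mcInt <- if (!is.null(mcherrySpots$intensity)) {
        mcherrySpots$intensity[i]
      } else {
        measureAt(mcherryFrame, pos, psfSigma)$intensity
      }
      eff <- if (efficiencyMode == "normalized") gfN / mcN
             else if (mcInt > 0) gfp$intensity / mcInt else NA_real_
      data.frame(particle_id = i, row_px = pos[1], col_px = pos[2],
                 mcherry_int = mcInt, gfp_int = gfp$intensity,
                 mcherry_norm = mcN, gfp_norm = gfN, efficiency = eff,
                 distance_um = dist, label = "unknown")
    }, error = function(e) NULL)
    if (is.null(res)) dropped <- dropped + 1L else rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(particle_id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), mcherry_int = numeric(0),
                      gfp_int = numeric(0), mcherry_norm = numeric(0),
                      gfp_norm = numeric(0), efficiency = numeric(0),
                      distance_um = numeric(0), label = character(0))
  }
  rownames(out) <- NULL
  attr(out, "qc") <- c(input = n, kept = nrow(out), dropped = dropped)
  out
}

#' Compare a particle metric between two conditions
#'
#' Welch two-sample t-test on a per-particle metric (translation
#' efficiency or a normalized channel intensity) between two particle
#' tables, e.g. before and after puromycin.
#'
#' @param particlesA,particlesB particle tables from
#'   \code{\link{buildParticles}} (or any data.frame with the metric
#'   column).
#' @param metric one of \code{"efficiency"}, \code{"gfp_norm"},
#'   \code{"mcherry_norm"}.
#' @return A list with class \code{"conditionComparison"}: \code{metric},
#'   \code{meanA}, \code{meanB}, \code{difference}, \code{statistic},
#'   \code{p}, \code{nA}, \code{nB}.
#' @export
compareConditions <- function(particlesA, particlesB,
                              metric = c("efficiency", "gfp_norm",
                                         "mcherry_norm")) {
  metric <- match.arg(metric)
  a <- particlesA[[metric]]; b <- particlesB[[metric]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values of '", metric, "'")
  }
  tt <- t.test(a, b)
  structure(list(metric = metric, meanA = mean(a), meanB = mean(b),
                 difference = mean(a) - mean(b),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 nA = length(a), nB = length(b)),
            class = "conditionComparison")
}

#' @export
print.conditionComparison <- function(x, ...) {
  cat(sprintf("Condition comparison on %s (Welch t-test)\n", x$metric))
  cat(sprintf("  mean A = %.4g (n=%d), mean B = %.4g (n=%d)\n",
              x$meanA, x$nA, x$meanB, x$nB))
  cat(sprintf("  difference = %.4g, t = %.3f, p = %.3g\n",
              x$difference, x$statistic, x$p))
  invisible(x)
}

#' Threshold for calling a particle translating
#'
#' Computes \code{1 + k * sd(gfp_norm)} from particles measured in a
#' control simulation (or dataset) with no nascent-chain signal, so the
#' threshold reflects the spread of the normalized GFP ratio under the
#' no-translation null.
#'
#' @param controlParticles particle table with no true GFP enrichment.
#' @param k multiplier on the null standard deviation (default 3).
#' @return The threshold (dimensionless, > 1).
#' @export
translatingThreshold <- function(controlParticles, k = 3) {
  g <- controlParticles$gfp_norm
  g <- g[is.finite(g)]
  if (length(g) < 2) stop("need at least 2 control particles")
  1 + k * sd(g)
}

#' Flag translating particles
#'
#' A particle is translating when its normalized GFP intensity exceeds the
#' threshold — i.e. the nascent-chain signal at the RNA position stands
#' clearly above nearby diffuse cytoplasm.
#'
#' @param particles particle table from \code{\link{buildParticles}}.
#' @param gfpNormThreshold threshold on \code{gfp_norm}; must be > 1. See
#'   \code{\link{translatingThreshold}}.
#' @return The particle table with a logical \code{translating} column.
#' @export
classifyTranslating <- function(particles, gfpNormThreshold) {
  stopifnot(gfpNormThreshold > 1)
  particles$translating <- is.finite(particles$gfp_norm) &
    particles$gfp_norm > gfpNormThreshold
  particles
}
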