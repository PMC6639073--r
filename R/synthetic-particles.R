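#' Spatial placement model for synthetic RNA particles
#'
#' Single molecules are placed so that their distance to the cell edge
#' follows a truncated exponential with the stated median: 5 um for a
#' peripherally localized species and 15 um for a uniformly targeted
#' control. Multi-copy clusters are confined to a narrow band (default
#' 2 um) around protrusion tips.
#'
#' @param kind \code{"localized"}, \code{"control"} or \code{"uniform"}
#'   (area-uniform placement, no edge bias).
#' @param medianEdgeDistanceUm median of the edge-distance law; defaults to
#'   5 um (localized) or 15 um (control), ignored for \code{"uniform"}.
#'   When the geometry cannot reach the requested median (a small cell
#'   truncates the distance range) the closest achievable law is used.
#' @param clusterBandWidthUm width of the peripheral band holding clusters.
#' @param clusterFraction proportion of particles that are clusters.
#' @return A list with class \code{"spatialModel"}.
#' @examples
#' spatialModel("localized")
#' spatialModel("control", clusterFraction = 0)
#' @export
spatialModel <- function(kind = c("localized", "control", "uniform"),
                         medianEdgeDistanceUm = NULL,
                         clusterBandWidthUm = 2, clusterFraction = 0) {
  kind <- match.arg(kind)
  if (is.null(medianEdgeDistanceUm)) {
    medianEdgeDistanceUm <- switch(kind, localized = 5, control = 15,
                                   uniform = NA_real_)
  }
  stopifnot(kind == "uniform" || medianEdgeDistanceUm > 0,
            clusterBandWidthUm > 0,
            clusterFraction >= 0, clusterFraction <= 1)
  structure(list(kind = kind, medianEdgeDistanceUm = medianEdgeDistanceUm,
                 clusterBandWidthUm = clusterBandWidthUm,
                 clusterFraction = clusterFraction),
            class = "spatialModel")
}

#' Cluster composition model
#'
#' Copy numbers of multi-RNA clusters are discrete-uniform on
#' \code{[minCopies, maxCopies]}; when \code{silent} is TRUE clusters carry
#' zero ribosome load, emulating translationally silent peripheral RNA
#' clusters.
#'
#' @param minCopies minimum RNA copies that define a cluster (>= 2).
#' @param maxCopies maximum RNA copies per cluster.
#' @param silent logical; silence clusters (ribosome load 0)?
#' @return A list with class \code{"clusterParams"}.
#' @examples
#' clusterParams()
#' @export
clusterParams <- function(minCopies = 4, maxCopies = 12, silent = TRUE) {
  stopifnot(minCopies >= 2, maxCopies >= minCopies)
  structure(list(minCopies = minCopies, maxCopies = maxCopies,
                 silent = silent), class = "clusterParams")
}

#' Ribosome-load model for synthetic particles
#'
#' Under the null model (the default) the ribosome load of a translating
#' single molecule is Poisson with mean \code{meanLoad}, drawn
#' independently of the particle's distance to the cell edge.
#' \code{silentFraction} single molecules carry load 0.
#'
#' @param meanLoad mean ribosomes per translating RNA.
#' @param silentFraction proportion of single molecules with load 0.
#' @param rnaPhotonsPerCopy expected photons collected per RNA copy
#'   (mCherry channel).
#' @param gfpPhotonsPerRibosome expected photons per ribosome-bound nascent
#'   chain (GFP channel).
#' @return A list with class \code{"efficiencyModel"}.
#' @examples
#' efficiencyModel(meanLoad = 6)
#' @export
efficiencyModel <- function(meanLoad = 6, silentFraction = 0,
                            rnaPhotonsPerCopy = 2000,
                            gfpPhotonsPerRibosome = 1000) {
  stopifnot(meanLoad >= 0, silentFraction >= 0, silentFraction <= 1,
            rnaPhotonsPerCopy >= 0, gfpPhotonsPerRibosome >= 0)
  structure(list(meanLoad = meanLoad, silentFraction = silentFraction,
                 rnaPhotonsPerCopy = rnaPhotonsPerCopy,
                 gfpPhotonsPerRibosome = gfpPhotonsPerRibosome),
            class = "efficiencyModel")
}

#' Sample ground-truth particles inside a cell geometry
#'
#' Places \code{nParticles} RNA particles inside the cell mask. Single
#' molecules get an edge distance drawn from a truncated exponential with
#' the model's median; the requested fraction of clusters is placed within
#' \code{clusterBandWidthUm} of protrusion tips. Ribosome loads follow the
#' efficiency model and are independent of position (the null used for
#' translation-vs-distance analyses); silent clusters carry load 0.
#'
#' @param geometry a \linkS4class{CellGeometry}.
#' @param nParticles number of particles (>= 0).
#' @param spatial a \code{\link{spatialModel}}.
#' @param clusters a \code{\link{clusterParams}}; used when
#'   \code{spatial$clusterFraction > 0}.
#' @param efficiency an \code{\link{efficiencyModel}}.
#' @param seed integer seed.
#' @return A data.frame with one row per particle: \code{id},
#'   \code{row_px}, \code{col_px} (sub-pixel, 0-based), \code{copy_number},
#'   \code{rna_photons_per_copy}, \code{ribosome_load},
#'   \code{gfp_photons_per_ribosome}, \code{is_cluster},
#'   \code{distance_um} (distance to the cell edge).
#' @examples
#' geom <- makeCellGeometry(40, 40, pixelSize = 0.32, seed = 1)
#' p <- sampleParticles(geom, 50, spatialModel("localized"), seed = 2)
#' median(p$distance_um)
#' @export
sampleParticles <- function(geometry, nParticles,
                            spatial = spatialModel("localized"),
                            clusters = clusterParams(),
                            efficiency = efficiencyModel(), seed = NULL) {
  stopifnot(is(geometry, "CellGeometry"), nParticles >= 0)
  withSeed(seed)
  empty <- data.frame(id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), copy_number = integer(0),
                      rna_photons_per_copy = numeric(0),
                      ribosome_load = integer(0),
                      gfp_photons_per_ribosome = numeric(0),
                      is_cluster = logical(0), distance_um = numeric(0))
  if (nParticles == 0) return(empty)

  ps <- geometry@pixelSize
  mask <- geometry@cellMask
  dpx <- edgeDistanceMapPx(mask)
  dum <- dpx * ps

  nCluster <- round(spatial$clusterFraction * nParticles)
  nSingle <- nParticles - nCluster
  if (nCluster > 0 && nrow(geometry@protrusionTips) == 0) {
    stop("spatial model requests clusters but the geometry has no ",
         "protrusion tips")
  }

  # --- single molecules: edge distance ~ truncated exponential -------------
  singles <- NULL
  if (nSingle > 0) {
    idx <- which(mask & dum > 0)
    dVals <- dum[idx]
    binW <- ps / 2
    bins <- floor(dVals / binW)
    # exponentially tilted spatial density: pixel weight exp(-rate * d).
    # The tilt rate is calibrated on this geometry so the realized
    # edge-distance marginal hits the requested median; weights stay
    # bounded, so particles never pile up on the few deepest pixels.
    binTab <- split(idx, bins)
    binD <- (as.numeric(names(binTab)) + 0.5) * binW
    binN <- vapply(binTab, length, integer(1))
    medOf <- function(rate) {
      w <- exp(-rate * binD) * binN
      cw <- cumsum(w) / sum(w)
      binD[which(cw >= 0.5)[1]]
    }
    rate <- if (spatial$kind == "uniform") 0 else {
      lo <- -0.5; hi <- 10
      target <- spatial$medianEdgeDistanceUm
      if (medOf(lo) <= target) lo         # median unreachable: closest law
      else if (medOf(hi) >= target) hi
      else uniroot(function(r) medOf(r) - target, c(lo, hi),
                   tol = 1e-4)$root
    }
    wBin <- exp(-rate * binD) * binN
    pickBin <- sample.int(length(binTab), nSingle, replace = TRUE,
                          prob = wBin)
    pix <- vapply(pickBin, function(b) {
      v <- binTab[[b]]
      if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
    }, integer(1))
    rr <- (pix - 1L) %% nrow(mask)
    cc <- (pix - 1L) %/% nrow(mask)
    jr <- runif(nSingle, -0.5, 0.5); jc <- runif(nSingle, -0.5, 0.5)
    rj <- rr + jr; cj <- cc + jc
    # keep the jittered position on a mask pixel
    bad <- !mask[cbind(pmin(pmax(round(rj), 0), nrow(mask) - 1) + 1L,
                       pmin(pmax(round(cj), 0), ncol(mask) - 1) + 1L)]
    rj[bad] <- rr[bad]; cj[bad] <- cc[bad]
    load <- rpois(nSingle, efficiency$meanLoad)
    if (efficiency$silentFraction > 0) {
      load[runif(nSingle) < efficiency$silentFraction] <- 0L
    }
    singles <- data.frame(row_px = rj, col_px = cj, copy_number = 1L,
                          ribosome_load = as.integer(load),
                          is_cluster = FALSE)
  }

  # --- clusters: within the peripheral band around protrusion tips ---------
  clus <- NULL
  if (nCluster > 0) {
    tips <- geometry@protrusionTips
    bandPx <- spatial$clusterBandWidthUm / ps
    gr <- gridRows(mask); gc <- gridCols(mask)
    tipIdx <- sample.int(nrow(tips), nCluster, replace = TRUE)
    pos <- matrix(NA_real_, nCluster, 2)
    for (i in seq_len(nCluster)) {
      t0 <- tips[tipIdx[i], ]
      cand <- which(mask & dum <= spatial$clusterBandWidthUm &
                    (gr - t0[1])^2 + (gc - t0[2])^2 <= (2 * bandPx)^2)
      if (length(cand) == 0) {                     # fall back to whole band
        cand <- which(mask & dum <= spatial$clusterBandWidthUm)
      }
      p <- cand[sample.int(length(cand), 1L)]
      pos[i, ] <- c((p - 1L) %% nrow(mask), (p - 1L) %/% nrow(mask))
    }
    copies <- sample(clusters$minCopies:clusters$maxCopies, nCluster,
                     replace = TRUE)
    load <- if (clusters$silent) rep(0L, nCluster) else
      as.integer(rpois(nCluster, efficiency$meanLoad))
    clus <- data.frame(row_px = pos[, 1], col_px = pos[, 2],
                       copy_number = as.integer(copies),
                       ribosome_load = load, is_cluster = TRUE)
  }

  out <- rbind(singles, clus)
  out$id <- seq_len(nrow(out))
  out$rna_photons_per_copy <- efficiency$rnaPhotonsPerCopy
  out$gfp_photons_per_ribosome <- efficiency$gfpPhotonsPerRibosome
  out$distance_um <- bilinear(dum, out$row_px, out$col_px)
  out[, c("id", "row_px", "col_px", "copy_number", "rna_photons_per_copy",
          "ribosome_load", "gfp_photons_per_ribosome", "is_cluster",
          "distance_um")]
}
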