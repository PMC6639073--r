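#' Estimate the single-molecule unit intensity
#'
#' From a population of background-subtracted integrated spot intensities,
#' estimates the intensity of a single RNA molecule. The default
#' \code{"kde_mode"} method takes the mode of a Gaussian kernel density
#' (Silverman's bandwidth) — robust to a minority of bright multi-copy
#' clusters — and a robust spread (MAD) of the intensities within +/- 50%
#' of the mode. When the mass within that window is below 40% the
#' population is flagged as lacking a dominant single-molecule peak.
#'
#' @param intensities numeric vector, length >= 20.
#' @param method \code{"kde_mode"} or \code{"median"}.
#' @return A list: \code{unit}, \code{sd}, \code{mode_mass}, and
#'   \code{warning} (NULL or a message). A condition of class
#'   \code{"warning"} is also signalled when no dominant peak exists.
#' @examples
#' estimateUnitIntensity(rnorm(200, 100, 15))$unit
#' @export
estimateUnitIntensity <- function(intensities,
                                  method = c("kde_mode", "median")) {
  method <- match.arg(method)
  x <- intensities[is.finite(intensities)]
  if (length(x) < 20) stop("need at least 20 intensities")
  if (method == "median") {
    unit <- median(x)
  } else {
    dens <- density(x, bw = "nrd0")
    unit <- dens$x[which.max(dens$y)]
  }
  near <- x[abs(x - unit) <= 0.5 * abs(unit)]
  s <- if (length(near) >= 2) mad(near, center = unit) else 0
  massNear <- length(near) / length(x)
  warn <- NULL
  if (massNear < 0.4) {
    warn <- sprintf(
      "no dominant single-molecule peak: only %.0f%% of intensities near the mode",
      100 * massNear)
    warning(warn, call. = FALSE)
  }
  list(unit = unit, sd = s, mode_mass = massNear, warning = warn)
}

#' Classification rules for single RNAs vs clusters
#'
#' @param threshold absolute intensity above which a particle is a cluster.
#' @param unit,sd single-molecule unit intensity and spread (see
#'   \code{\link{estimateUnitIntensity}}).
#' @param kSd multiplier for the relative rule: cluster when intensity >
#'   unit + kSd * sd.
#' @param minCopies minimum rounded copy number that defines a cluster.
#' @return A list with class \code{"clusterRule"}.
#' @name clusterRules
#' @examples
#' relativeRule(unit = 100, sd = 20)
NULL

#' @rdname clusterRules
#' @export
absoluteRule <- function(threshold) {
  if (threshold <= 0) stop("'threshold' must be positive")
  structure(list(kind = "absolute", threshold = threshold),
            class = "clusterRule")
}

#' @rdname clusterRules
#' @export
relativeRule <- function(unit, sd, kSd = 3) {
  if (unit <= 0) stop("'unit' must be positive")
  structure(list(kind = "relative", unit = unit, sd = sd, kSd = kSd),
            class = "clusterRule")
}

#' @rdname clusterRules
#' @export
copiesRule <- function(unit, minCopies = 2) {
  if (unit <= 0) stop("'unit' must be positive")
  structure(list(kind = "copies", unit = unit, minCopies = minCopies),
            class = "clusterRule")
}

#' Classify particles into single RNAs vs RNA clusters
#'
#' Applies one of three rules to a vector of integrated intensities:
#' an absolute intensity threshold (replicating instrument-specific
#' cutoffs such as "intensities above 400 are clusters"), a relative rule
#' (\code{unit + kSd * sd}), or a copy-number rule
#' (\code{round(intensity / unit) >= minCopies}). Estimated copy numbers
#' are \code{max(1, round(intensity / unit))} whenever a unit intensity is
#' available.
#'
#' @param intensities numeric vector of integrated intensities.
#' @param rule a rule built by \code{\link{absoluteRule}},
#'   \code{\link{relativeRule}} or \code{\link{copiesRule}}.
#' @return A data.frame: \code{intensity}, \code{label} ("single" /
#'   "cluster"), \code{estimated_copies}.
#' @examples
#' classifyParticles(c(350, 450), absoluteRule(400))
#' @export
classifyParticles <- function(intensities, rule) {
  stopifnot(inherits(rule, "clusterRule"))
  x <- intensities
  isCluster <- switch(rule$kind,
    absolute = x > rule$threshold,
    relative = x > rule$unit + rule$kSd * rule$sd,
    copies = round(x / rule$unit) >= rule$minCopies
  )
  copies <- if (!is.null(rule$unit)) {
    pmax(1, round(x / rule$unit))
  } else {
    rep(1L, length(x))
  }
  copies[isCluster & copies < 2] <- 2L   # cluster implies >= 2 copies
  data.frame(intensity = x,
             label = ifelse(isCluster, "cluster", "single"),
             estimated_copies = as.integer(copies))
}

#' Compare single/cluster composition between regions or species
#'
#' Builds the 2 x k contingency table of single vs cluster calls across
#' regions (or RNA species) and tests association with Fisher's exact test
#' (two-sided: the sum of all tables with probability at most that of the
#' observed table). For tables larger than 2 x 2 with total count above
#' \code{exactLimit} a seeded Monte-Carlo p-value (1e5 draws) is used.
#'
#' @param callsByRegion named list of \code{\link{classifyParticles}}
#'   outputs (or character vectors of "single"/"cluster" labels).
#' @param exactLimit largest total count for which the exact network
#'   algorithm is used on 2 x k tables.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A list: \code{table} (2 x k matrix), \code{p},
#'   \code{method}. When a margin is zero, \code{p = 1} with a warning.
#' @examples
#' compareRegions(list(internal = rep("single", 20),
#'                     edge = c(rep("single", 10), rep("cluster", 10))))
#' @export
compareRegions <- function(callsByRegion, exactLimit = 200, seed = 1) {
  labs <- lapply(callsByRegion, function(x) {
    if (is.data.frame(x)) x$label else as.character(x)
  })
  tab <- vapply(labs, function(l) {
    as.numeric(c(sum(l == "single"), sum(l == "cluster")))
  }, numeric(2))
  tab <- matrix(as.integer(tab), 2, length(labs),
                dimnames = list(c("single", "cluster"), names(labs)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the contingency table is zero; p = 1")
    return(list(table = tab, p = 1, method = "degenerate margin"))
  }
  if (ncol(tab) == 2 || sum(tab) <= exactLimit) {
    ft <- fisher.test(tab)
    method <- "exact"
  } else {
    withSeed(seed)
    ft <- fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
    method <- "monte carlo (1e5 draws)"
  }
  list(table = tab, p = ft$p.value, method = method)
}

#' Percent overlap of one cluster set with another
#'
#' Fraction of A-clusters that have at least one B-cluster within
#' \code{maxDistUm}, as a percentage — e.g. the percent of RNA clusters
#' overlapping polyA RNA clusters.
#'
#' @param clustersA,clustersB matrices or data.frames of positions in
#'   micrometres (columns \code{row_um}, \code{col_um}, or two unnamed
#'   columns).
#' @param maxDistUm matching radius in micrometres (default 0.5).
#' @return Percentage in [0, 100].
#' @examples
#' a <- cbind(row_um = c(1, 5), col_um = c(1, 5))
#' clusterOverlap(a, a)  # 100
#' @export
clusterOverlap <- function(clustersA, clustersB, maxDistUm = 0.5) {
  toMat <- function(x) {
    x <- as.data.frame(x)
    if (all(c("row_um", "col_um") %in% names(x))) {
      cbind(x$row_um, x$col_um)
    } else as.matrix(x[, 1:2])
  }
  a <- toMat(clustersA)
  if (nrow(a) == 0) stop("'clustersA' is empty; overlap undefined")
  b <- if (is.null(clustersB) || NROW(clustersB) == 0) {
    matrix(numeric(0), 0, 2)
  } else toMat(clustersB)
  if (nrow(b) == 0) return(0)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  100 * mean(apply(d2, 1, min) <= maxDistUm^2)
}

#' Score protrusion ROIs for RNA granules
#'
#' Labels each protrusion region of interest positive or negative per
#' channel, by the presence of at least one cluster-called particle inside
#' the ROI polygon (particle criterion) or by the ROI's mean intensity
#' exceeding the diffuse cytoplasmic level by \code{k} standard deviations
#' (intensity criterion). With two channels, also tabulates the
#' A-/B-, A+/B-, A+/B+ (and A-/B+) breakdown.
#'
#' @param rois list of polygon matrices (columns row, col in pixel
#'   coordinates) lying within the cell mask.
#' @param geometry a \linkS4class{CellGeometry}.
#' @param particles named list, one element per channel, each a data.frame
#'   with \code{row_px}, \code{col_px} and \code{label} columns (cluster
#'   calls); used by the particle criterion.
#' @param images named list of \linkS4class{ImageFrame}s for the intensity
#'   criterion.
#' @param criteria \code{"particles"} or \code{"intensity"}.
#' @param k sd multiplier for the intensity criterion.
#' @return A list: \code{perRoi} data.frame of logicals per channel,
#'   \code{positiveFraction} named vector, \code{categories} (for exactly
#'   two channels) the 4-way count table, \code{n_rois}.
#' @export
scoreProtrusions <- function(rois, geometry, particles = NULL,
                             images = NULL,
                             criteria = c("particles", "intensity"),
                             k = 3) {
  criteria <- match.arg(criteria)
  stopifnot(is(geometry, "CellGeometry"))
  if (length(rois) == 0) {
    return(list(perRoi = data.frame(), positiveFraction = numeric(0),
                categories = NULL, n_rois = 0L))
  }
  mask <- geometry@cellMask
  for (ri in seq_along(rois)) {
    v <- rois[[ri]]
    ok <- mask[cbind(pmin(pmax(round(v[, 1]), 0), nrow(mask) - 1) + 1L,
                     pmin(pmax(round(v[, 2]), 0), ncol(mask) - 1) + 1L)]
    if (!all(ok)) stop("ROI ", ri, " extends outside the cell mask")
  }

  channels <- names(if (criteria == "particles") particles else images)
  if (is.null(channels)) stop("supply named 'particles' or 'images'")
  perRoi <- matrix(FALSE, length(rois), length(channels),
                   dimnames = list(NULL, channels))
  if (criteria == "particles") {
    for (ch in channels) {
      p <- particles[[ch]]
      cl <- p[p$label == "cluster", , drop = FALSE]
      for (ri in seq_along(rois)) {
        if (nrow(cl) > 0) {
          perRoi[ri, ch] <- any(mgcv::in.out(
            rois[[ri]], cbind(cl$row_px, cl$col_px)))
        }
      }
    }
  } else {
    gr <- gridRows(mask); gc <- gridCols(mask)
    for (ch in channels) {
      img <- images[[ch]]@pixels
      inAnyRoi <- matrix(FALSE, nrow(mask), ncol(mask))
      pts <- cbind(as.vector(gr), as.vector(gc))
      for (ri in seq_along(rois)) {
        inAnyRoi <- inAnyRoi | matrix(mgcv::in.out(rois[[ri]], pts),
                                      nrow(mask), ncol(mask))
      }
      cyto <- img[mask & !inAnyRoi]
      thr <- mean(cyto) + k * sd(cyto)
      for (ri in seq_along(rois)) {
        inRoi <- matrix(mgcv::in.out(rois[[ri]], pts), nrow(mask),
                        ncol(mask)) & mask
        perRoi[ri, ch] <- mean(img[inRoi]) > thr
      }
    }
  }
  perRoi <- as.data.frame(perRoi)
  posFrac <- vapply(perRoi, mean, numeric(1))
  categories <- NULL
  if (length(channels) == 2) {
    a <- perRoi[[1]]; b <- perRoi[[2]]
    nm <- c(paste0(channels[1], "-/", channels[2], "-"),
            paste0(channels[1], "+/", channels[2], "-"),
            paste0(channels[1], "-/", channels[2], "+"),
            paste0(channels[1], "+/", channels[2], "+"))
    categories <- setNames(c(sum(!a & !b), sum(a & !b), sum(!a & b),
                             sum(a & b)), nm)
  }
  list(perRoi = perRoi, positiveFraction = posFrac,
       categories = categories, n_rois = length(rois))
}
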