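#' @import methods
#' @importFrom stats rnorm rpois runif rnbinom rexp median mad sd quantile
#'   density t.test cor.test ks.test fisher.test loess predict lm aov
#'   complete.cases setNames coef pnorm qnorm p.adjust ecdf optim var
#' @importFrom utils head read.csv write.csv modifyList
#' @importFrom graphics par
NULL

#' Single-channel image frame
#'
#' A 2D intensity raster from one microscopy channel, together with the
#' physical pixel size, a channel label and (for time-lapse data) the frame
#' index. This is the unit every image operation in the package consumes.
#'
#' @slot pixels numeric matrix of non-negative intensities (camera counts),
#'   indexed \code{[row, col]}.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot channel channel label, e.g. \code{"mcherry"} or \code{"gfp"}.
#' @slot frameIndex zero-based frame index within a time-lapse.
#'
#' @section Coordinates:
#' All pixel coordinates in the package are 0-based \code{(row, col)} with
#' pixel centres at integer coordinates; distances are converted to
#' micrometres via \code{pixelSize} at the API boundary (columns suffixed
#' \code{_um}).
#'
#' @name ImageFrame-class
#' @aliases ImageFrame-class
#' @exportClass ImageFrame
setClass("ImageFrame",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    channel = "character",
    frameIndex = "integer"
  ),
  prototype(pixelSize = 0.16, channel = "unknown", frameIndex = 0L)
)

setValidity("ImageFrame", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels)) {
    msg <- c(msg, "'pixels' must be a numeric matrix")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    msg <- c(msg, "'pixelSize' must be a single positive number")
  }
  if (any(!is.finite(object@pixels))) {
    msg <- c(msg, "'pixels' must be finite")
  }
  if (length(object@frameIndex) != 1L || object@frameIndex < 0L) {
    msg <- c(msg, "'frameIndex' must be a single non-negative integer")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageFrame
#'
#' @param pixels numeric matrix of intensities, \code{[row, col]}.
#' @param pixelSize micrometres per pixel.
#' @param channel channel label.
#' @param frameIndex zero-based frame index.
#' @return An \linkS4class{ImageFrame}.
#' @examples
#' ImageFrame(matrix(100, 32, 32), pixelSize = 0.16, channel = "gfp")
#' @export
ImageFrame <- function(pixels, pixelSize = 0.16, channel = "unknown",
                       frameIndex = 0L) {
  new("ImageFrame", pixels = pixels, pixelSize = pixelSize,
      channel = channel, frameIndex = as.integer(frameIndex))
}

#' Cell geometry: masks, edge polygon, protrusion tips
#'
#' Holds a binary cell mask and nucleus mask, the polygon tracing the cell
#' boundary, recorded protrusion tip coordinates and the pixel size. It is
#' the source of all distance transforms and peripheral band masks.
#'
#' @slot cellMask logical matrix, TRUE inside the cell.
#' @slot nucleusMask logical matrix, TRUE inside the nucleus; a strict
#'   subset of \code{cellMask}.
#' @slot edgePolygon numeric matrix with columns \code{row}, \code{col}
#'   (0-based pixel coordinates) tracing the cell boundary in order.
#' @slot protrusionTips numeric matrix with columns \code{row}, \code{col};
#'   zero rows when the cell has no recorded protrusions.
#' @slot pixelSize micrometres per pixel.
#' @name CellGeometry-class
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(
    cellMask = "matrix",
    nucleusMask = "matrix",
    edgePolygon = "matrix",
    protrusionTips = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("CellGeometry", function(object) {
  msg <- NULL
  if (!is.logical(object@cellMask) || !is.logical(object@nucleusMask)) {
    msg <- c(msg, "masks must be logical matrices")
  }
  if (!identical(dim(object@cellMask), dim(object@nucleusMask))) {
    msg <- c(msg, "cell and nucleus masks must have identical dimensions")
  }
  if (any(object@nucleusMask & !object@cellMask)) {
    msg <- c(msg, "'nucleusMask' must be a subset of 'cellMask'")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
    msg <- c(msg, "'pixelSize' must be a single positive number")
  }
  if (ncol(object@edgePolygon) != 2L) {
    msg <- c(msg, "'edgePolygon' must have two columns (row, col)")
  }
  if (nrow(object@protrusionTips) > 0 && ncol(object@protrusionTips) != 2L) {
    msg <- c(msg, "'protrusionTips' must have two columns (row, col)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Imaging model: PSF and camera parameters
#'
#' Describes the optical point spread function (isotropic 2D Gaussian) and
#' the camera model (offset, gain, Gaussian read noise) used both to render
#' synthetic images and to localize spots.
#'
#' @slot psfSigma Gaussian PSF standard deviation in pixels.
#' @slot pixelSize micrometres per pixel.
#' @slot cameraOffset camera counts added to every pixel.
#' @slot cameraGain counts per detected photon.
#' @slot readNoiseSd standard deviation of additive Gaussian read noise,
#'   in counts.
#' @name OpticsModel-class
#' @exportClass OpticsModel
setClass("OpticsModel",
  representation(
    psfSigma = "numeric",
    pixelSize = "numeric",
    cameraOffset = "numeric",
    cameraGain = "numeric",
    readNoiseSd = "numeric"
  ),
  prototype(psfSigma = 1.3, pixelSize = 0.16, cameraOffset = 100,
            cameraGain = 1, readNoiseSd = 2)
)

setValidity("OpticsModel", function(object) {
  msg <- NULL
  if (object@psfSigma <= 0) msg <- c(msg, "'psfSigma' must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "'readNoiseSd' must be >= 0")
  if (object@cameraGain <= 0) msg <- c(msg, "'cameraGain' must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an OpticsModel
#'
#' Default values describe a confocal/sCMOS-like system at 63x: a 1.3 px
#' Gaussian PSF at 0.16 um/px, offset 100 counts, unit gain and 2 counts of
#' read noise.
#'
#' @param psfSigma PSF sigma in pixels.
#' @param pixelSize micrometres per pixel.
#' @param cameraOffset counts.
#' @param cameraGain counts per photon.
#' @param readNoiseSd counts.
#' @return An \linkS4class{OpticsModel}.
#' @examples
#' opticsModel(psfSigma = 1.3)
#' @export
opticsModel <- function(psfSigma = 1.3, pixelSize = 0.16, cameraOffset = 100,
                        cameraGain = 1, readNoiseSd = 2) {
  new("OpticsModel", psfSigma = psfSigma, pixelSize = pixelSize,
      cameraOffset = cameraOffset, cameraGain = cameraGain,
      readNoiseSd = readNoiseSd)
}

#' Four-fraction polysome gradient count table
#'
#' Genes-by-fraction counts from a sucrose gradient divided into four
#' fractions (F1 free RNPs/subunits, F2 monosomes, F3 light polysomes,
#' F4 heavy polysomes), together with the counts of a spike-in RNA added in
#' equal amount to every fraction, per-gene group annotations and the
#' condition/replicate labels. Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}; the count matrix is in
#' \code{assay(x, "counts")} and gene groups in \code{rowData(x)$group}.
#'
#' @slot spikeCounts numeric vector of length 4; spike-in counts per
#'   fraction, all strictly positive.
#' @slot condition condition label.
#' @slot replicate replicate index.
#' @name FractionCountTable-class
#' @exportClass FractionCountTable
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("FractionCountTable",
  contains = "SummarizedExperiment",
  representation(
    spikeCounts = "numeric",
    condition = "character",
    replicate = "integer"
  )
)

setValidity("FractionCountTable", function(object) {
  msg <- NULL
  if (ncol(object) != 4L) {
    msg <- c(msg, "a fraction count table must have exactly 4 fraction columns")
  }
  if (length(object@spikeCounts) != 4L || any(object@spikeCounts <= 0)) {
    msg <- c(msg, "'spikeCounts' must be 4 strictly positive values")
  }
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FractionCountTable
#'
#' @param counts numeric matrix, genes x 4 fractions, non-negative; row
#'   names are gene identifiers.
#' @param spikeCounts numeric(4), spike-in counts per fraction.
#' @param geneGroups character vector (or factor) of per-gene group labels,
#'   e.g. \code{"APC_dependent"}, \code{"APC_independent"}, \code{"control"}.
#' @param condition condition label.
#' @param replicate replicate index.
#' @return A \linkS4class{FractionCountTable}.
#' @examples
#' cts <- matrix(rpois(8, 100), 2, 4,
#'               dimnames = list(c("Rab13", "Net1"), paste0("F", 1:4)))
#' FractionCountTable(cts, spikeCounts = c(900, 1100, 1000, 950),
#'                    geneGroups = c("APC_dependent", "APC_dependent"),
#'                    condition = "control", replicate = 1)
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
FractionCountTable <- function(counts, spikeCounts, geneGroups = NULL,
                               condition = "control", replicate = 1L) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("F", 1:4)
  if (is.null(geneGroups)) geneGroups <- rep("unassigned", nrow(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(group = as.character(geneGroups)),
    colData = S4Vectors::DataFrame(fraction = 1:4,
                                   row.names = colnames(counts))
  )
  new("FractionCountTable", se, spikeCounts = as.numeric(spikeCounts),
      condition = condition, replicate = as.integer(replicate))
}

#' Per-gene fraction distributions
#'
#' Row-normalized proportions of each gene across the four gradient
#' fractions (averaged over replicates), and the translated fraction
#' defined as the proportion in the polysomal fractions, p3 + p4.
#'
#' @slot proportions genes x 4 matrix; rows sum to 1.
#' @slot translatedFraction named numeric vector, p3 + p4 per gene.
#' @slot condition condition label.
#' @slot nReplicates number of replicates averaged.
#' @name FractionDistribution-class
#' @exportClass FractionDistribution
setClass("FractionDistribution",
  representation(
    proportions = "matrix",
    translatedFraction = "numeric",
    condition = "character",
    nReplicates = "integer"
  )
)

setValidity("FractionDistribution", function(object) {
  msg <- NULL
  if (ncol(object@proportions) != 4L) {
    msg <- c(msg, "'proportions' must have 4 columns")
  }
  if (nrow(object@proportions) > 0 &&
      any(abs(rowSums(object@proportions) - 1) > 1e-9)) {
    msg <- c(msg, "each row of 'proportions' must sum to 1")
  }
  if (any(object@translatedFraction < -1e-12 |
          object@translatedFraction > 1 + 1e-12)) {
    msg <- c(msg, "'translatedFraction' must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})
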