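#' Accessors for the package's core classes
#'
#' @param x an object of one of the package's classes.
#' @return The slot value: \code{pixels} the intensity matrix,
#'   \code{pixelSize} micrometres per pixel, \code{channelName} the channel
#'   label, \code{cellMask}/\code{nucleusMask} logical matrices,
#'   \code{edgePolygon}/\code{protrusionTips} coordinate matrices,
#'   \code{spikeCounts} the per-fraction spike-in counts, \code{geneGroups}
#'   per-gene group labels, \code{conditionLabel}/\code{replicateIndex} the
#'   sample annotation, \code{proportions}/\code{translatedFraction} the
#'   fraction-distribution results.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setGeneric("edgePolygon", function(x) standardGeneric("edgePolygon"))
#' @rdname accessors
#' @export
setGeneric("protrusionTips", function(x) standardGeneric("protrusionTips"))
#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))
#' @rdname accessors
#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))
#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
#' @rdname accessors
#' @export
setGeneric("translatedFraction", function(x) standardGeneric("translatedFraction"))

#' @rdname accessors
setMethod("pixels", "ImageFrame", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSize", "ImageFrame", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "CellGeometry", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "OpticsModel", function(x) x@pixelSize)
#' @rdname accessors
setMethod("channelName", "ImageFrame", function(x) x@channel)
#' @rdname accessors
setMethod("cellMask", "CellGeometry", function(x) x@cellMask)
#' @rdname accessors
setMethod("nucleusMask", "CellGeometry", function(x) x@nucleusMask)
#' @rdname accessors
setMethod("edgePolygon", "CellGeometry", function(x) x@edgePolygon)
#' @rdname accessors
setMethod("protrusionTips", "CellGeometry", function(x) x@protrusionTips)
#' @rdname accessors
setMethod("spikeCounts", "FractionCountTable", function(x) x@spikeCounts)
#' @rdname accessors
setMethod("geneGroups", "FractionCountTable",
          function(x) setNames(SummarizedExperiment::rowData(x)$group,
                               rownames(x)))
#' @rdname accessors
setMethod("conditionLabel", "FractionCountTable", function(x) x@condition)
#' @rdname accessors
setMethod("replicateIndex", "FractionCountTable", function(x) x@replicate)
#' @rdname accessors
setMethod("conditionLabel", "FractionDistribution", function(x) x@condition)
#' @rdname accessors
setMethod("proportions", "FractionDistribution", function(x) x@proportions)
#' @rdname accessors
setMethod("translatedFraction", "FractionDistribution",
          function(x) x@translatedFraction)

setMethod("show", "ImageFrame", function(object) {
  cat(sprintf("ImageFrame '%s': %d x %d px, %.3g um/px, frame %d\n",
              object@channel, nrow(object@pixels), ncol(object@pixels),
              object@pixelSize, object@frameIndex))
  rng <- range(object@pixels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "CellGeometry", function(object) {
  area <- sum(object@cellMask) * object@pixelSize^2
  cat(sprintf("CellGeometry: %d x %d px grid, %.3g um/px\n",
              nrow(object@cellMask), ncol(object@cellMask),
              object@pixelSize))
  cat(sprintf("  cell area %.1f um^2, nucleus area %.1f um^2, %d protrusion tip(s)\n",
              area, sum(object@nucleusMask) * object@pixelSize^2,
              nrow(object@protrusionTips)))
})

setMethod("show", "OpticsModel", function(object) {
  cat(sprintf(
    "OpticsModel: PSF sigma %.2f px, %.3g um/px, offset %g, gain %g, read noise %g\n",
    object@psfSigma, object@pixelSize, object@cameraOffset,
    object@cameraGain, object@readNoiseSd))
})

setMethod("show", "FractionCountTable", function(object) {
  cat(sprintf("FractionCountTable: %d genes x 4 fractions (%s, replicate %d)\n",
              nrow(object), object@condition, object@replicate))
  cat("  spike counts:", paste(signif(object@spikeCounts, 4), collapse = ", "),
      "\n")
  grp <- table(SummarizedExperiment::rowData(object)$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FractionDistribution", function(object) {
  cat(sprintf(
    "FractionDistribution: %d genes (%s, mean of %d replicate(s))\n",
    nrow(object@proportions), object@condition, object@nReplicates))
  tf <- object@translatedFraction
  if (length(tf)) {
    cat(sprintf("  translated fraction (p3+p4): median %.3f, range [%.3f, %.3f]\n",
                median(tf), min(tf), max(tf)))
  }
})
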