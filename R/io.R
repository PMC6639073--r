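#' Read and write grayscale TIFF image stacks
#'
#' Images are stored as 8- or 16-bit grayscale TIFF (single- or
#' multi-page); the physical pixel size and channel label travel in a YAML
#' sidecar file (\code{<path>.yaml}) so they survive any TIFF dialect.
#' Pixel data round-trip losslessly for integer counts in [0, 65535].
#'
#' @param frames an \linkS4class{ImageFrame} or a list of them (pages of
#'   one stack, same channel).
#' @param path TIFF file path.
#' @return \code{writeImageFrames} returns \code{path} invisibly;
#'   \code{readImageFrames} returns a list of \linkS4class{ImageFrame}s
#'   with frame indices 0..n-1.
#' @examples
#' f <- file.path(tempdir(), "frame.tif")
#' writeImageFrames(ImageFrame(matrix(100L, 8, 8)), f)
#' readImageFrames(f)[[1]]
#' @name imageIO
NULL

#' @rdname imageIO
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom yaml write_yaml read_yaml
#' @export
writeImageFrames <- function(frames, path) {
  if (is(frames, "ImageFrame")) frames <- list(frames)
  stopifnot(length(frames) >= 1,
            all(vapply(frames, is, logical(1), "ImageFrame")))
  pages <- lapply(frames, function(f) {
    px <- f@pixels
    if (any(px < 0 | px > 65535)) {
      stop("pixel values outside the 16-bit range; cannot write")
    }
    round(px) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_um = frames[[1]]@pixelSize,
                        channel = frames[[1]]@channel,
                        n_frames = length(frames)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname imageIO
#' @export
readImageFrames <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  meta <- list(pixel_size_um = 0.16, channel = "unknown")
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- utils::modifyList(meta, yaml::read_yaml(side))
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) {
      stop("multi-channel (RGB) TIFF without a grayscale convention: ", path)
    }
    bits <- attr(p, "bits.per.sample")
    scale <- if (!is.null(bits) && bits == 8) 255 else 65535
    ImageFrame(matrix(round(p * scale), nrow(p), ncol(p)),
               pixelSize = meta$pixel_size_um,
               channel = meta$channel, frameIndex = i - 1L)
  })
}

#' Write a cell geometry's masks as 8-bit TIFFs
#'
#' @param geometry a \linkS4class{CellGeometry}.
#' @param cellPath,nucleusPath output TIFF paths.
#' @return Invisibly, the two paths.
#' @export
writeMasks <- function(geometry, cellPath, nucleusPath) {
  stopifnot(is(geometry, "CellGeometry"))
  tiff::writeTIFF(matrix(as.numeric(geometry@cellMask),
                         nrow(geometry@cellMask)), cellPath,
                  bits.per.sample = 8L)
  tiff::writeTIFF(matrix(as.numeric(geometry@nucleusMask),
                         nrow(geometry@nucleusMask)), nucleusPath,
                  bits.per.sample = 8L)
  invisible(c(cellPath, nucleusPath))
}

#' Read and write four-fraction count tables as CSV
#'
#' The CSV has a \code{gene} column, fraction columns \code{F1..F4}, a
#' \code{group} column and \code{condition}/\code{replicate} columns, with
#' the spike-in on a row whose gene is \code{"SPIKE"}. One file may hold
#' several condition x replicate tables.
#'
#' @param tables a \linkS4class{FractionCountTable} or list of them.
#' @param path CSV file path.
#' @return \code{writeFractionCounts}: \code{path}, invisibly.
#'   \code{readFractionCounts}: a list of
#'   \linkS4class{FractionCountTable}s.
#' @name countIO
NULL

#' @rdname countIO
#' @export
writeFractionCounts <- function(tables, path) {
  if (is(tables, "FractionCountTable")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(tab) {
    cts <- SummarizedExperiment::assay(tab, "counts")
    rbind(
      data.frame(gene = rownames(cts), F1 = cts[, 1], F2 = cts[, 2],
                 F3 = cts[, 3], F4 = cts[, 4],
                 group = SummarizedExperiment::rowData(tab)$group,
                 condition = tab@condition, replicate = tab@replicate),
      data.frame(gene = "SPIKE", F1 = tab@spikeCounts[1],
                 F2 = tab@spikeCounts[2], F3 = tab@spikeCounts[3],
                 F4 = tab@spikeCounts[4], group = "spike",
                 condition = tab@condition, replicate = tab@replicate)
    )
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname countIO
#' @export
readFractionCounts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "F1", "F2", "F3", "F4")
  if (!all(need %in% names(df))) {
    stop("count CSV must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$condition)) df$condition <- "unknown"
  if (is.null(df$replicate)) df$replicate <- 1L
  if (is.null(df$group)) df$group <- "unassigned"
  keys <- unique(df[, c("condition", "replicate")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$condition == keys$condition[i] &
              df$replicate == keys$replicate[i], ]
    spike <- sub[sub$gene == "SPIKE", ]
    if (nrow(spike) != 1) {
      stop("expected exactly one SPIKE row per condition x replicate in ",
           path)
    }
    genes <- sub[sub$gene != "SPIKE", ]
    cts <- as.matrix(genes[, c("F1", "F2", "F3", "F4")])
    rownames(cts) <- genes$gene
    out[[sprintf("%s_rep%d", keys$condition[i], keys$replicate[i])]] <-
      FractionCountTable(cts,
                         spikeCounts = as.numeric(spike[, c("F1", "F2",
                                                            "F3", "F4")]),
                         geneGroups = genes$group,
                         condition = keys$condition[i],
                         replicate = keys$replicate[i])
  }
  out
}

#' Write a particle table as CSV
#'
#' @param particles particle table (see \code{\link{buildParticles}}).
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeParticles <- function(particles, path) {
  write.csv(particles, path, row.names = FALSE)
  invisible(path)
}
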