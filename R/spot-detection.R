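#' Detect diffraction-limited spot candidates
#'
#' Filters the image with a scale-normalized Laplacian-of-Gaussian matched
#' to the PSF width and returns local maxima whose response exceeds
#' \code{snrThreshold} times a robust (MAD-based) estimate of the filtered
#' image's noise. An empty or constant image yields no candidates.
#'
#' @param frame an \linkS4class{ImageFrame}.
#' @param psfSigma PSF sigma in pixels.
#' @param snrThreshold detection threshold in robust-noise units.
#' @param mask optional logical matrix restricting the search (e.g. the
#'   cell interior).
#' @return A data.frame of candidates sorted by score (descending):
#'   \code{row_px}, \code{col_px} (integer, 0-based), \code{score}.
#' @examples
#' img <- matrix(100, 64, 64)
#' g <- pnorm(outer(0:63, rep(1, 64)) + 0.5, 32, 1.3) -
#'      pnorm(outer(0:63, rep(1, 64)) - 0.5, 32, 1.3)
#' img <- img + 2000 * g * t(g)
#' detectSpots(ImageFrame(img), psfSigma = 1.3)
#' @export
detectSpots <- function(frame, psfSigma = 1.3, snrThreshold = 5,
                        mask = NULL) {
  stopifnot(is(frame, "ImageFrame"), psfSigma > 0)
  x <- frame@pixels
  inRegion <- if (is.null(mask)) matrix(TRUE, nrow(x), ncol(x)) else mask
  if (!all(inRegion)) {
    # flatten the cell-edge intensity step so it cannot ring the filter
    x[!inRegion] <- median(x[inRegion])
  }
  resp <- conv2same(x, logKernel(psfSigma))
  noiseSd <- mad(resp[inRegion])
  if (!is.finite(noiseSd) || noiseSd == 0) {
    return(data.frame(row_px = integer(0), col_px = integer(0),
                      score = numeric(0)))
  }
  thr <- snrThreshold * noiseSd

  nr <- nrow(x); nc <- ncol(x)
  isMax <- matrix(TRUE, nr, nc)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  neigh <- matrix(TRUE, nr - 2, nc - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    neigh <- neigh & core > resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  isMax[] <- FALSE
  isMax[2:(nr - 1), 2:(nc - 1)] <- neigh
  hit <- which(isMax & inRegion & resp > thr)
  if (length(hit) == 0) {
    return(data.frame(row_px = integer(0), col_px = integer(0),
                      score = numeric(0)))
  }
  out <- data.frame(row_px = (hit - 1L) %% nr,
                    col_px = (hit - 1L) %/% nr,
                    score = resp[hit] / noiseSd)
  out[order(-out$score), , drop = FALSE]
}

# Median background in an annulus (inner, outer] around an integer-rounded
# centre; radii in pixels.
annulusBackground <- function(x, row0, col0, inner, outer) {
  nr <- nrow(x); nc <- ncol(x)
  r0 <- round(row0); c0 <- round(col0)
  hw <- ceiling(outer)
  if (r0 - hw < 0 || r0 + hw > nr - 1 || c0 - hw < 0 || c0 + hw > nc - 1) {
    stop("background annulus extends beyond the image border",
         call. = FALSE)
  }
  rows <- (r0 - hw):(r0 + hw); cols <- (c0 - hw):(c0 + hw)
  rr <- outer((rows - row0)^2, (cols - col0)^2, "+")
  win <- x[rows + 1L, cols + 1L]
  sel <- rr > inner^2 & rr <= outer^2
  median(win[sel])
}

#' Localize a spot by iterative Gaussian-mask fitting
#'
#' Estimates the sub-pixel position and background-subtracted integrated
#' intensity of a diffraction-limited spot. The local background is the
#' median of an annulus (3 to 5 sigma) around the candidate and is
#' subtracted; the position is then iterated as the Gaussian-mask-weighted
#' centroid (unit-height Gaussian of width \code{psfSigma} centred at the
#' current estimate) until it moves less than \code{tol} pixels or
#' \code{maxIter} is reached. The integrated intensity uses the mask
#' photometry convention under which a noiseless Gaussian of amplitude A
#' returns \code{2 * pi * sigma^2 * A}, i.e. its total volume.
#'
#' @param frame an \linkS4class{ImageFrame}.
#' @param candidate integer (row, col) position, e.g. one row of
#'   \code{\link{detectSpots}} output (a data.frame row or numeric(2)).
#' @param psfSigma PSF sigma in pixels (fixed, not fitted).
#' @param windowHalfwidth photometry window half-width; default
#'   \code{ceiling(4 * psfSigma)}.
#' @param maxIter maximum mask iterations.
#' @param tol convergence tolerance in pixels.
#' @return A one-row data.frame: \code{row_px}, \code{col_px} (sub-pixel),
#'   \code{intensity}, \code{background}, \code{n_iterations},
#'   \code{converged}, \code{channel}, \code{frame_index}.
#' @seealso \code{\link{measureAt}} for fixed-position photometry.
#' @export
localizeSpot <- function(frame, candidate, psfSigma = 1.3,
                         windowHalfwidth = ceiling(4 * psfSigma),
                         maxIter = 50, tol = 0.01) {
  stopifnot(is(frame, "ImageFrame"), maxIter >= 1, tol > 0)
  if (is.data.frame(candidate)) {
    candidate <- c(candidate$row_px[1], candidate$col_px[1])
  }
  x <- frame@pixels
  nr <- nrow(x); nc <- ncol(x)
  r0 <- round(candidate[1]); c0 <- round(candidate[2])
  hw <- windowHalfwidth
  if (r0 - hw < 0 || r0 + hw > nr - 1 || c0 - hw < 0 || c0 + hw > nc - 1) {
    stop("candidate window extends beyond the image border", call. = FALSE)
  }
  bg <- annulusBackground(x, r0, c0, 3 * psfSigma,
                          max(5 * psfSigma, hw + 0.5))
  rows <- (r0 - hw):(r0 + hw); cols <- (c0 - hw):(c0 + hw)
  S <- x[rows + 1L, cols + 1L] - bg

  pos <- c(candidate[1], candidate[2])
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    M <- gaussMask(rows, cols, pos[1], pos[2], psfSigma)
    w <- S * M
    sw <- sum(w)
    if (!is.finite(sw) || sw <= 0) break   # no signal to centre on
    newPos <- c(sum(w * rows) / sw, sum(t(w) * cols) / sw)
    if (newPos[1] < rows[1] || newPos[1] > rows[length(rows)] ||
        newPos[2] < cols[1] || newPos[2] > cols[length(cols)]) {
      stop("position estimate escaped the fitting window", call. = FALSE)
    }
    shift <- sqrt(sum((newPos - pos)^2))
    pos <- newPos
    if (shift < tol) { converged <- TRUE; break }
  }
  M <- gaussMask(rows, cols, pos[1], pos[2], psfSigma)
  intensity <- sum(S * M) / sum(M^2) * 2 * pi * psfSigma^2
  data.frame(row_px = pos[1], col_px = pos[2], intensity = intensity,
             background = bg, n_iterations = it, converged = converged,
             channel = frame@channel, frame_index = frame@frameIndex)
}

#' Gaussian-mask photometry at a fixed position
#'
#' Single-pass, non-iterative version of \code{\link{localizeSpot}}: the
#' Gaussian mask is centred at the supplied (sub-pixel) position and never
#' re-centred, with the same background-annulus and intensity conventions.
#' Used to record the nascent-chain (GFP) intensity at an RNA spot's
#' position.
#'
#' @inheritParams localizeSpot
#' @param position numeric (row, col), sub-pixel, 0-based.
#' @return A list: \code{intensity}, \code{background}.
#' @export
measureAt <- function(frame, position, psfSigma = 1.3,
                      windowHalfwidth = ceiling(4 * psfSigma)) {
  stopifnot(is(frame, "ImageFrame"))
  x <- frame@pixels
  nr <- nrow(x); nc <- ncol(x)
  r0 <- round(position[1]); c0 <- round(position[2])
  hw <- windowHalfwidth
  if (r0 - hw < 0 || r0 + hw > nr - 1 || c0 - hw < 0 || c0 + hw > nc - 1) {
    stop("photometry window extends beyond the image border", call. = FALSE)
  }
  bg <- annulusBackground(x, r0, c0, 3 * psfSigma,
                          max(5 * psfSigma, hw + 0.5))
  rows <- (r0 - hw):(r0 + hw); cols <- (c0 - hw):(c0 + hw)
  S <- x[rows + 1L, cols + 1L] - bg
  M <- gaussMask(rows, cols, position[1], position[2], psfSigma)
  list(intensity = sum(S * M) / sum(M^2) * 2 * pi * psfSigma^2,
       background = bg)
}

#' Link per-frame spots into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames under
#' a displacement gate: the closest available pair is linked first, ties
#' broken by the lower spot index, and unmatched spots start new tracks.
#' Deterministic for a given input.
#'
#' @param spots a data.frame of localized spots with columns \code{row_px},
#'   \code{col_px} and \code{frame_index} (or \code{frame}).
#' @param maxDisplacementPx displacement gate between consecutive frames,
#'   pixels.
#' @return The input with a \code{track_id} column appended, ordered by
#'   track then frame.
#' @examples
#' s <- data.frame(row_px = c(5, 5.1, 5.2), col_px = c(7, 7, 7.1),
#'                 frame_index = 0:2)
#' linkTracks(s, maxDisplacementPx = 2)
#' @export
linkTracks <- function(spots, maxDisplacementPx = 2) {
  stopifnot(maxDisplacementPx > 0)
  if (is.null(spots$frame_index) && !is.null(spots$frame)) {
    spots$frame_index <- spots$frame
  }
  if (nrow(spots) == 0) {
    spots$track_id <- integer(0)
    return(spots)
  }
  spots <- spots[order(spots$frame_index), , drop = FALSE]
  spots$track_id <- NA_integer_
  frames <- sort(unique(spots$frame_index))
  nextId <- 1L
  first <- which(spots$frame_index == frames[1])
  spots$track_id[first] <- seq_along(first)
  nextId <- length(first) + 1L
  for (k in seq_along(frames)[-1]) {
    prev <- which(spots$frame_index == frames[k - 1] &
                  !is.na(spots$track_id))
    cur <- which(spots$frame_index == frames[k])
    # tracks only continue across consecutive frames (no gap closing)
    linkable <- if (frames[k] - frames[k - 1] == 1L) prev else integer(0)
    if (length(linkable) > 0 && length(cur) > 0) {
      d <- outer(spots$row_px[linkable], spots$row_px[cur], "-")^2 +
           outer(spots$col_px[linkable], spots$col_px[cur], "-")^2
      d[d > maxDisplacementPx^2] <- Inf
      while (any(is.finite(d))) {
        m <- which(d == min(d), arr.ind = TRUE)
        m <- m[order(m[, 1], m[, 2]), , drop = FALSE][1, ]  # tie-break
        spots$track_id[cur[m[2]]] <- spots$track_id[linkable[m[1]]]
        d[m[1], ] <- Inf
        d[, m[2]] <- Inf
      }
    }
    new <- cur[is.na(spots$track_id[cur])]
    if (length(new) > 0) {
      spots$track_id[new] <- nextId + seq_along(new) - 1L
      nextId <- nextId + length(new)
    }
  }
  spots[order(spots$track_id, spots$frame_index), , drop = FALSE]
}

# RMS deviation of a track's positions from its mean position, pixels.
trackRms <- function(rows, cols) {
  sqrt(mean((rows - mean(rows))^2 + (cols - mean(cols))^2))
}

#' Keep persistent, stationary tracks
#'
#' Retains tracks that persist for at least \code{minFrames} frames
#' (default 7, i.e. strictly more than 6 imaging frames) and whose RMS
#' deviation from their mean position does not exceed
#' \code{maxRmsDisplacementPx}. This is the persistence filter used to
#' restrict analysis to stationary particles.
#'
#' @param tracks output of \code{\link{linkTracks}}.
#' @param minFrames minimum track length in frames.
#' @param maxRmsDisplacementPx maximum RMS positional deviation, pixels.
#' @return The filtered track data.frame with an \code{rms_displacement}
#'   column appended.
#' @export
filterStationary <- function(tracks, minFrames = 7,
                             maxRmsDisplacementPx = 1) {
  stopifnot(minFrames >= 1)
  if (nrow(tracks) == 0) {
    tracks$rms_displacement <- numeric(0)
    return(tracks)
  }
  rms <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(i) {
    trackRms(tracks$row_px[i], tracks$col_px[i])
  }, numeric(1))
  len <- table(tracks$track_id)
  keepIds <- names(rms)[rms <= maxRmsDisplacementPx &
                        as.vector(len[names(rms)]) >= minFrames]
  out <- tracks[tracks$track_id %in% keepIds, , drop = FALSE]
  out$rms_displacement <- rms[as.character(out$track_id)]
  rownames(out) <- NULL
  out
}
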