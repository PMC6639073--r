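#' Render a two-channel image of ground-truth particles
#'
#' Builds the expected photon image for each channel — a diffuse fluorophore
#' background inside the cell mask plus one pixel-integrated 2D Gaussian PSF
#' per particle — and passes it through the camera model. mCherry amplitude
#' is \code{copy_number * rna_photons_per_copy}; GFP amplitude is
#' \code{ribosome_load * gfp_photons_per_ribosome}, so a silent cluster is
#' invisible in the GFP channel. With \code{noise = TRUE} the counts are
#' \code{offset + gain * Poisson(photons) + N(0, readNoise)}, rounded and
#' clipped to 16-bit; with \code{noise = FALSE} the continuous expectation
#' \code{offset + gain * photons} is returned.
#'
#' @param particles data.frame from \code{\link{sampleParticles}}.
#' @param geometry a \linkS4class{CellGeometry}.
#' @param optics an \linkS4class{OpticsModel}.
#' @param backgroundLevels named numeric: diffuse photons/pixel inside the
#'   cell mask for \code{mcherry} and \code{gfp}.
#' @param noise apply Poisson + read noise?
#' @param seed integer seed for the noise draw.
#' @param frameIndex frame index stamped on the output frames.
#' @return A list of two \linkS4class{ImageFrame}s, \code{mcherry} and
#'   \code{gfp}.
#' @examples
#' geom <- makeCellGeometry(20, 20, pixelSize = 0.32, seed = 1)
#' p <- sampleParticles(geom, 10, seed = 2)
#' ch <- renderChannels(p, geom, opticsModel(pixelSize = 0.32), seed = 3)
#' ch$mcherry
#' @export
renderChannels <- function(particles, geometry, optics = opticsModel(),
                           backgroundLevels = c(mcherry = 50, gfp = 50),
                           noise = TRUE, seed = NULL, frameIndex = 0L) {
  stopifnot(is(geometry, "CellGeometry"), is(optics, "OpticsModel"))
  withSeed(seed)
  mask <- geometry@cellMask
  nr <- nrow(mask); nc <- ncol(mask)
  if (nrow(particles) > 0 &&
      any(particles$row_px < 0 | particles$row_px > nr - 1 |
          particles$col_px < 0 | particles$col_px > nc - 1)) {
    stop("particle position outside image bounds")
  }
  sig <- optics@psfSigma

  photonImage <- function(bg, amps) {
    img <- matrix(0, nr, nc)
    img[mask] <- bg
    if (nrow(particles) > 0) {
      for (i in seq_len(nrow(particles))) {
        if (amps[i] <= 0) next
        g <- pixelatedGaussian(particles$row_px[i], particles$col_px[i],
                               sig, amps[i], nr, nc)
        img[g$rows + 1L, g$cols + 1L] <- img[g$rows + 1L, g$cols + 1L] +
          g$values
      }
    }
    img
  }

  ampM <- particles$copy_number * particles$rna_photons_per_copy
  ampG <- particles$ribosome_load * particles$gfp_photons_per_ribosome
  phM <- photonImage(backgroundLevels[["mcherry"]], ampM)
  phG <- photonImage(backgroundLevels[["gfp"]], ampG)

  toCounts <- function(ph) {
    if (!noise) return(optics@cameraOffset + optics@cameraGain * ph)
    x <- optics@cameraOffset +
      optics@cameraGain * rpois(length(ph), ph) +
      rnorm(length(ph), 0, optics@readNoiseSd)
    matrix(pmin(pmax(round(x), 0), 65535), nr, nc)
  }

  list(
    mcherry = ImageFrame(toCounts(phM), pixelSize = optics@pixelSize,
                         channel = "mcherry", frameIndex = frameIndex),
    gfp = ImageFrame(toCounts(phG), pixelSize = optics@pixelSize,
                     channel = "gfp", frameIndex = frameIndex)
  )
}

#' Motion model for time-lapse simulation
#'
#' Particles are split into a stationary majority that jitters with a
#' small-amplitude oscillation, a diffusing fraction performing 2D Brownian
#' motion, and a minority undergoing directed runs; clusters are always
#' stationary. The frame interval defaults to 0.5 s.
#'
#' @param stationaryFraction,diffusiveFraction,directedFraction proportions
#'   (directed is the remainder check; the three must sum to 1).
#' @param oscillationAmpPx amplitude of the stationary oscillation, pixels.
#' @param oscillationPeriodS oscillation period, seconds.
#' @param jitterSdPx per-frame Gaussian jitter of stationary particles.
#' @param diffusionUm2PerS diffusion coefficient D, um^2/s.
#' @param runSpeedUmPerS speed of directed runs, um/s.
#' @param frameIntervalS frame interval, seconds.
#' @return A list with class \code{"motionModel"}.
#' @examples
#' motionModel(stationaryFraction = 1, diffusiveFraction = 0,
#'             directedFraction = 0)
#' @export
motionModel <- function(stationaryFraction = 0.8, diffusiveFraction = 0.15,
                        directedFraction = 0.05, oscillationAmpPx = 0.3,
                        oscillationPeriodS = 4, jitterSdPx = 0.1,
                        diffusionUm2PerS = 0.05, runSpeedUmPerS = 1,
                        frameIntervalS = 0.5) {
  tot <- stationaryFraction + diffusiveFraction + directedFraction
  if (abs(tot - 1) > 1e-9) stop("motion fractions must sum to 1")
  structure(list(stationaryFraction = stationaryFraction,
                 diffusiveFraction = diffusiveFraction,
                 directedFraction = directedFraction,
                 oscillationAmpPx = oscillationAmpPx,
                 oscillationPeriodS = oscillationPeriodS,
                 jitterSdPx = jitterSdPx,
                 diffusionUm2PerS = diffusionUm2PerS,
                 runSpeedUmPerS = runSpeedUmPerS,
                 frameIntervalS = frameIntervalS),
            class = "motionModel")
}

#' Simulate a two-channel time-lapse with ground-truth tracks
#'
#' Propagates particle positions over \code{nFrames} frames under the
#' motion model and renders each frame pair. True per-frame positions and
#' motion classes are returned alongside the images. Positions may leave the
#' cell mask (diffusion is unconstrained) but an error is raised if a
#' particle leaves the image.
#'
#' @param particles data.frame from \code{\link{sampleParticles}}.
#' @param geometry a \linkS4class{CellGeometry}.
#' @param optics an \linkS4class{OpticsModel}.
#' @param nFrames number of frames (>= 1).
#' @param motion a \code{\link{motionModel}}.
#' @param backgroundLevels diffuse photon levels, as in
#'   \code{\link{renderChannels}}.
#' @param noise apply camera noise?
#' @param seed integer seed.
#' @return A list: \code{frames}, a list of per-frame channel pairs;
#'   \code{tracks}, a data.frame with \code{id}, \code{frame},
#'   \code{row_px}, \code{col_px}, \code{motion_class}.
#' @examples
#' geom <- makeCellGeometry(15, 15, pixelSize = 0.32, seed = 1)
#' p <- sampleParticles(geom, 5, seed = 2)
#' tl <- simulateTimelapse(p, geom, opticsModel(pixelSize = 0.32),
#'                         nFrames = 3, seed = 3)
#' head(tl$tracks)
#' @export
simulateTimelapse <- function(particles, geometry, optics = opticsModel(),
                              nFrames = 10,
                              motion = motionModel(),
                              backgroundLevels = c(mcherry = 50, gfp = 50),
                              noise = TRUE, seed = NULL) {
  if (nFrames < 1) stop("'nFrames' must be >= 1")
  withSeed(seed)
  n <- nrow(particles)
  dt <- motion$frameIntervalS
  ps <- optics@pixelSize

  cls <- if (n > 0) {
    cl <- sample(c("stationary", "diffusive", "directed"), n, replace = TRUE,
                 prob = c(motion$stationaryFraction,
                          motion$diffusiveFraction,
                          motion$directedFraction))
    cl[particles$is_cluster] <- "stationary"
    cl
  } else character(0)

  phase <- runif(n, 0, 2 * pi)
  oscDir <- runif(n, 0, 2 * pi)
  runDir <- runif(n, 0, 2 * pi)
  stepSdPx <- sqrt(2 * motion$diffusionUm2PerS * dt) / ps
  runStepPx <- motion$runSpeedUmPerS * dt / ps

  posR <- matrix(NA_real_, n, nFrames)
  posC <- matrix(NA_real_, n, nFrames)
  if (n > 0) {
    posR[, 1] <- particles$row_px
    posC[, 1] <- particles$col_px
    for (f in seq_len(nFrames)) {
      if (f > 1) {
        dR <- dC <- numeric(n)
        di <- cls == "diffusive"
        dR[di] <- rnorm(sum(di), 0, stepSdPx)
        dC[di] <- rnorm(sum(di), 0, stepSdPx)
        dr <- cls == "directed"
        dR[dr] <- runStepPx * sin(runDir[dr]) + rnorm(sum(dr), 0, 0.05)
        dC[dr] <- runStepPx * cos(runDir[dr]) + rnorm(sum(dr), 0, 0.05)
        posR[, f] <- posR[, f - 1] + dR
        posC[, f] <- posC[, f - 1] + dC
      }
      st <- cls == "stationary"
      if (any(st)) {
        osc <- motion$oscillationAmpPx *
          sin(2 * pi * (f - 1) * dt / motion$oscillationPeriodS + phase[st])
        posR[st, f] <- particles$row_px[st] + osc * sin(oscDir[st]) +
          rnorm(sum(st), 0, motion$jitterSdPx)
        posC[st, f] <- particles$col_px[st] + osc * cos(oscDir[st]) +
          rnorm(sum(st), 0, motion$jitterSdPx)
      }
    }
  }

  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    pf <- particles
    if (n > 0) {
      pf$row_px <- posR[, f]
      pf$col_px <- posC[, f]
    }
    frames[[f]] <- renderChannels(pf, geometry, optics, backgroundLevels,
                                  noise = noise, frameIndex = f - 1L)
  }

  tracks <- if (n > 0) {
    data.frame(id = rep(particles$id, nFrames),
               frame = rep(seq_len(nFrames) - 1L, each = n),
               row_px = as.vector(posR), col_px = as.vector(posC),
               motion_class = rep(cls, nFrames))
  } else {
    data.frame(id = integer(0), frame = integer(0), row_px = numeric(0),
               col_px = numeric(0), motion_class = character(0))
  }
  list(frames = frames, tracks = tracks)
}
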