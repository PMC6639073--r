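test_that("flat and noise-only images produce no or few candidates", {
  expect_equal(nrow(detectSpots(ImageFrame(matrix(100, 64, 64)))), 0)
  fp <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      img <- matrix(100 + rnorm(128 * 128, 0, 2), 128, 128)
    })
    nrow(detectSpots(ImageFrame(img), psfSigma = 1.3, snrThreshold = 5))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.98)
})

test_that("a rendered spot is found once, near the truth", {
  found <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      img <- spotImage(10.3, 11.6, photons = 1500, bg = 50)
    })
    cand <- detectSpots(ImageFrame(img), psfSigma = 1.3, snrThreshold = 5)
    nrow(cand) == 1 &&
      abs(cand$row_px - 10.3) <= 1 && abs(cand$col_px - 11.6) <= 1
  }, logical(1))
  expect_gte(mean(found), 0.99)

  # two well-separated spots give two candidates
  withr::with_seed(1, {
    img <- matrix(100 + rpois(41 * 41, 50), 41, 41)
  })
  for (pos in list(c(10, 10), c(30, 30))) {
    g <- periTrans:::pixelatedGaussian(pos[1], pos[2], 1.3, 3000, 41, 41)
    img[g$rows + 1, g$cols + 1] <- img[g$rows + 1, g$cols + 1] + g$values
  }
  expect_equal(nrow(detectSpots(ImageFrame(img), 1.3, 5)), 2)
})

test_that("noiseless Gaussian is localized exactly with volume intensity", {
  A <- 200; sig <- 1.3
  img <- 100 + A * periTrans:::gaussMask(0:40, 0:40, 20, 20, sig)
  s <- localizeSpot(ImageFrame(img), c(20, 20), sig)
  expect_lt(abs(s$row_px - 20), 1e-3)
  expect_lt(abs(s$col_px - 20), 1e-3)
  expect_lt(abs(s$intensity - 2 * pi * sig^2 * A) / (2 * pi * sig^2 * A),
            0.01)
  expect_true(s$converged)

  # intensity estimator is linear in amplitude
  s2 <- localizeSpot(ImageFrame(100 + 2 * A *
    periTrans:::gaussMask(0:40, 0:40, 20, 20, sig)), c(20, 20), sig)
  expect_lt(abs(s2$intensity / s$intensity - 2), 0.005)
})

test_that("localization is translation-equivariant and near the LS oracle", {
  withr::with_seed(3, {
    img <- spotImage(10.3, 10.7, photons = 3000, dims = c(25, 25))
  })
  s <- localizeSpot(ImageFrame(img), c(10, 11), 1.3)
  shifted <- matrix(100, 29, 29)
  shifted[5:29 - 1, 5:29 - 1] <- img   # shift by (+3, +3) px
  sS <- localizeSpot(ImageFrame(shifted), c(13, 14), 1.3)
  expect_equal(sS$row_px - s$row_px, 3, tolerance = 1e-6)
  expect_equal(sS$col_px - s$col_px, 3, tolerance = 1e-6)

  # mask fit vs least-squares Gaussian fit on simulated spots at SNR >= 7
  dpos <- dint <- numeric(60)
  for (i in 1:60) {
    withr::with_seed(100 + i, {
      im <- spotImage(10 + runif(1), 10 + runif(1), photons = 3000)
    })
    m <- localizeSpot(ImageFrame(im), c(10, 11), 1.3)
    ls <- lsGaussianFit(im, 1.3, c(m$row_px, m$col_px))
    dpos[i] <- sqrt((m$row_px - ls$row)^2 + (m$col_px - ls$col)^2)
    dint[i] <- abs(m$intensity - ls$intensity) / ls$intensity
  }
  expect_lt(max(dpos), 0.05)
  expect_lt(median(dint), 0.03)
})

test_that("photometry at a fixed position follows the overlap integral", {
  sig <- 1.3
  img <- 100 + 200 * periTrans:::gaussMask(0:40, 0:40, 20, 20, sig)
  fr <- ImageFrame(img)
  on <- measureAt(fr, c(20, 20), sig)
  loc <- localizeSpot(fr, c(20, 20), sig)
  expect_lt(abs(on$intensity - loc$intensity) / loc$intensity, 1e-3)

  # offset by d: mask overlap is exp(-d^2 / (4 sigma^2))
  for (d in c(2, 3, 3.5) * sig) {
    off <- measureAt(fr, c(20 + d, 20), sig)
    expect_equal(off$intensity / on$intensity, exp(-d^2 / (4 * sig^2)),
                 tolerance = 0.02)
  }

  # pure diffuse region: intensity ~ 0, background ~ diffuse level
  flat <- ImageFrame(matrix(150, 41, 41))
  m <- measureAt(flat, c(20, 20), sig)
  expect_equal(m$intensity, 0, tolerance = 1e-9)
  expect_equal(m$background, 150)
  expect_error(measureAt(flat, c(1, 20), sig), "border")
})

test_that("linking follows identities and respects the gate", {
  # one stationary spot over 10 frames
  s <- data.frame(row_px = rep(5, 10) + 0.01 * (1:10),
                  col_px = rep(8, 10), frame_index = 0:9)
  tr <- linkTracks(s, maxDisplacementPx = 2)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # approaching spots that jump apart beyond the gate: tracks terminate
  # rather than swapping identity (verified against what an exhaustive
  # assignment under the gate would allow: no links at all on frame 2)
  s2 <- data.frame(
    row_px = c(0, 3, 1.2, 1.8, 4.5, -1.5),
    col_px = rep(5, 6),
    frame_index = c(0, 0, 1, 1, 2, 2))
  tr2 <- linkTracks(s2, maxDisplacementPx = 1.5)
  expect_equal(length(unique(tr2$track_id)), 4)
  # the frame-0 -> frame-1 links pair each spot with its nearer partner
  t1 <- tr2$track_id[tr2$frame_index == 0]
  t2 <- tr2$track_id[tr2$frame_index == 1]
  expect_setequal(t1, t2)

  expect_equal(nrow(linkTracks(data.frame(row_px = numeric(0),
                                          col_px = numeric(0),
                                          frame_index = integer(0)))), 0)
})

test_that("the persistence filter keeps > 6-frame stationary tracks", {
  mk <- function(n, id, jitter) {
    data.frame(row_px = 5 + jitter * sin(1:n), col_px = 5 + jitter * cos(1:n),
               frame_index = 0:(n - 1), track_id = id)
  }
  tracks <- rbind(mk(7, 1, 0.1), mk(6, 2, 0.1), mk(10, 3, 3))
  kept <- filterStationary(tracks, minFrames = 7, maxRmsDisplacementPx = 1)
  expect_equal(unique(kept$track_id), 1)
  expect_equal(nrow(filterStationary(mk(3, 1, 0.1), minFrames = 7)), 0)
})

test_that("tracking separates stationary particles from fast diffusers", {
  geom <- makeCellGeometry(32, 32, pixelSize = 0.32, seed = 21)
  opt <- opticsModel(pixelSize = 0.32)
  p <- sampleParticles(geom, 30,
                       spatialModel("control", medianEdgeDistanceUm = 8),
                       seed = 22)
  tl <- simulateTimelapse(p, geom, opt, nFrames = 10,
                          motion = motionModel(stationaryFraction = 0.5,
                                               diffusiveFraction = 0.5,
                                               directedFraction = 0,
                                               diffusionUm2PerS = 0.2),
                          noise = FALSE, seed = 23)
  # link true positions (localization quality is tested elsewhere)
  tr <- linkTracks(tl$tracks, maxDisplacementPx = 3)
  kept <- filterStationary(tr, minFrames = 7, maxRmsDisplacementPx = 1)
  clsOf <- tapply(tl$tracks$motion_class, tl$tracks$id, `[`, 1)
  keptIds <- unique(kept$id)
  recallStationary <- mean(names(clsOf)[clsOf == "stationary"] %in% keptIds)
  leakDiffusive <- mean(names(clsOf)[clsOf == "diffusive"] %in% keptIds)
  expect_gte(recallStationary, 0.9)
  expect_lte(leakDiffusive, 0.1)
})
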