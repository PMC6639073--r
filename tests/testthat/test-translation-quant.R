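test_that("local-cytoplasm normalization has the right fixed points", {
  # uniform image: exactly 1 regardless of offset correction
  flat <- ImageFrame(matrix(150, 64, 64))
  expect_identical(normalizeToLocalCytoplasm(flat, c(32, 32), offset = 100),
                   1)

  # disc at twice the diffuse level: ratio 2 (top-hat spot, no PSF tails)
  img <- matrix(200, 64, 64)
  rr <- outer((0:63 - 32)^2, (0:63 - 32)^2, "+")
  img[rr <= 2.6^2] <- 300
  v <- normalizeToLocalCytoplasm(ImageFrame(img), c(32, 32),
                                 spotRadius = 2.6, offset = 100)
  expect_equal(v, 2, tolerance = 1e-9)

  # fully occluded annulus errors
  others <- expand.grid(row_px = seq(20, 44, 4), col_px = seq(20, 44, 4))
  expect_error(
    normalizeToLocalCytoplasm(flat, c(32, 32), excludePositions = others,
                              excludeRadius = 12),
    "occluded")
})

test_that("no-enrichment simulations give normalized intensity near 1", {
  geom <- makeCellGeometry(30, 30, pixelSize = 0.16, seed = 31)
  # RNA channel carries no spot photons (a -PP7-style reporter)
  p <- sampleParticles(geom, 200,
                       spatialModel("control", medianEdgeDistanceUm = 6),
                       efficiency = efficiencyModel(rnaPhotonsPerCopy = 0),
                       seed = 32)
  ch <- renderChannels(p, geom, seed = 33)
  vals <- vapply(seq_len(nrow(p)), function(i) {
    tryCatch(normalizeToLocalCytoplasm(
      ch$mcherry, c(p$row_px[i], p$col_px[i]), spotRadius = 2.6,
      annulusRadii = c(6.5, 11.7), mask = cellMask(geom), offset = 100),
      error = function(e) NA_real_)
  }, numeric(1))
  expect_gt(sum(!is.na(vals)), 150)
  expect_true(mean(vals, na.rm = TRUE) > 0.95 &&
              mean(vals, na.rm = TRUE) < 1.05)
})

test_that("particle building pairs channels and flags translation", {
  geom <- makeCellGeometry(30, 30, pixelSize = 0.16, seed = 34)
  p <- sampleParticles(geom, 120,
                       spatialModel("control", medianEdgeDistanceUm = 6),
                       seed = 35)
  ch <- renderChannels(p, geom, seed = 36)
  spots <- data.frame(row_px = p$row_px, col_px = p$col_px)
  parts <- buildParticles(spots, ch$gfp, ch$mcherry, geom, offset = 100)
  qc <- attr(parts, "qc")
  expect_equal(unname(qc["input"]), 120)
  expect_equal(unname(qc["kept"] + qc["dropped"]), 120)
  expect_true(all(parts$mcherry_norm > 0 & parts$gfp_norm > 0))

  # determinism: identical inputs give identical tables
  parts2 <- buildParticles(spots, ch$gfp, ch$mcherry, geom, offset = 100)
  expect_identical(parts, parts2)

  # translating singles (load 6) vs silent (load 0) separate by > 5x
  pSil <- p; pSil$ribosome_load <- 0L
  chS <- renderChannels(pSil, geom, seed = 36)
  silent <- buildParticles(spots, chS$gfp, chS$mcherry, geom, offset = 100)
  expect_gt(mean(parts$efficiency), 5 * mean(silent$efficiency))

  # threshold from the silent population flags the right groups
  thr <- translatingThreshold(silent)
  expect_gt(thr, 1)
  expect_lte(mean(classifyTranslating(silent, thr)$translating), 0.05)
  expect_gte(mean(classifyTranslating(parts, thr)$translating), 0.9)
  expect_equal(sum(classifyTranslating(parts, 1e9)$translating), 0)
})

test_that("no GFP signal anywhere gives gfp_norm near 1", {
  geom <- makeCellGeometry(25, 25, pixelSize = 0.16, seed = 37)
  p <- sampleParticles(geom, 80,
                       spatialModel("control", medianEdgeDistanceUm = 5),
                       efficiency = efficiencyModel(gfpPhotonsPerRibosome = 0),
                       seed = 38)
  ch <- renderChannels(p, geom, seed = 39)
  parts <- buildParticles(data.frame(row_px = p$row_px, col_px = p$col_px),
                          ch$gfp, ch$mcherry, geom, offset = 100)
  expect_lt(abs(mean(parts$gfp_norm) - 1), 0.05)
})

test_that("efficiency is invariant to global illumination scaling", {
  geom <- makeCellGeometry(25, 25, pixelSize = 0.16, seed = 40)
  p <- sampleParticles(geom, 40,
                       spatialModel("control", medianEdgeDistanceUm = 5),
                       seed = 41)
  opt0 <- opticsModel(cameraOffset = 0)
  ch <- renderChannels(p, geom, opt0, noise = FALSE)
  spots <- data.frame(row_px = p$row_px, col_px = p$col_px)
  a <- buildParticles(spots, ch$gfp, ch$mcherry, geom, offset = 0)
  chScaled <- list(
    mcherry = ImageFrame(pixels(ch$mcherry) * 3.7, 0.16, "mcherry"),
    gfp = ImageFrame(pixels(ch$gfp) * 3.7, 0.16, "gfp"))
  b <- buildParticles(spots, chScaled$gfp, chScaled$mcherry, geom,
                      offset = 0)
  expect_equal(a$efficiency, b$efficiency, tolerance = 1e-9)
})

test_that("group mean efficiency rises monotonically with ribosome load", {
  geom <- makeCellGeometry(30, 30, pixelSize = 0.16, seed = 42)
  means <- vapply(c(0, 2, 6, 12), function(lam) {
    p <- sampleParticles(geom, 80,
                         spatialModel("control", medianEdgeDistanceUm = 6),
                         efficiency = efficiencyModel(meanLoad = lam),
                         seed = 43 + lam)
    ch <- renderChannels(p, geom, seed = 44 + lam)
    parts <- buildParticles(data.frame(row_px = p$row_px,
                                       col_px = p$col_px),
                            ch$gfp, ch$mcherry, geom, offset = 100)
    mean(parts$efficiency, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("condition comparison computes a Welch t-test", {
  a <- syntheticParticleTable(50, efficiency = rnorm(50, 1, 0.2),
                              distance = runif(50, 0, 10))
  cmpSame <- compareConditions(a, a)
  expect_equal(cmpSame$difference, 0)
  expect_equal(cmpSame$p, 1)

  b <- a; b$efficiency <- b$efficiency + 1
  cmp <- compareConditions(a, b)
  expect_lt(cmp$p, 1e-6)
  expect_equal(cmp$difference, -1, tolerance = 1e-9)
  expect_error(compareConditions(a[0, ], b), "at least 2")

  # type-I control under permutation
  withr::with_seed(7, {
    x <- rnorm(60); y <- rnorm(60)
    ps <- replicate(400, {
      z <- sample(c(x, y))
      compareConditions(data.frame(efficiency = z[1:60]),
                        data.frame(efficiency = z[61:120]))$p
    })
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})
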