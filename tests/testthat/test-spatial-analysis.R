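test_that("distance to edge matches geometry on a disc and a polygon", {
  disc <- discGeometry(radiusUm = 8, pixelSize = 0.32)
  ctr <- (dim(cellMask(disc)) - 1) / 2
  # centre of a disc of radius R is R from the edge; bilinear sampling at
  # the ridge of the distance map costs up to ~1 px extra
  expect_lt(abs(distanceToEdge(disc, matrix(ctr, 1, 2)) - 8), 1.5 * 0.32)
  # a point on the boundary is at distance ~0
  bnd <- edgePolygon(disc)[1, , drop = FALSE]
  inward <- bnd + 0.6 * sign(ctr - bnd)     # just inside the raster edge
  expect_lt(distanceToEdge(disc, inward), 2 * 0.32)

  # random interior points vs brute-force polygon-segment oracle
  geom <- makeCellGeometry(35, 35, nProtrusions = 2, pixelSize = 0.32,
                           seed = 51)
  p <- sampleParticles(geom, 50,
                       spatialModel("control", medianEdgeDistanceUm = 5),
                       seed = 52)
  pts <- cbind(p$row_px, p$col_px)
  dPkg <- distanceToEdge(geom, pts)
  dOracle <- brutePolyDistance(edgePolygon(geom), pts) * 0.32
  expect_lt(max(abs(dPkg - dOracle)), 1.5 * 0.32)

  # outside-mask positions error with the particle index
  out <- matrix(c(0, 0), 1, 2)
  expect_error(distanceToEdge(geom, out), "outside the cell mask")
})

test_that("edge band mask matches the analytic annulus area on a disc", {
  disc <- discGeometry(radiusUm = 10, pixelSize = 0.16)
  band <- edgeBandMask(disc, widthUm = 2)
  frac <- sum(band) / sum(cellMask(disc))
  expect_lt(abs(frac - (1 - (8 / 10)^2)), 0.03)
  # width exceeding the radius: band is the whole cell
  expect_true(all(edgeBandMask(disc, 20) == cellMask(disc)))
  # infinitesimal width: only boundary-adjacent pixels
  thin <- edgeBandMask(disc, 1e-6)
  d <- EBImage::distmap(matrix(as.numeric(cellMask(disc)),
                               nrow(cellMask(disc))))
  expect_true(all(d[thin] == 1))
  expect_equal(sum(thin), sum(d == 1))
  expect_gt(sum(thin), 0)
})

test_that("efficiency-vs-distance statistics behave at the fixed points", {
  withr::with_seed(53, {
    d <- runif(100, 0, 15)
    pJit <- syntheticParticleTable(100, 1 + rnorm(100, 0, 1e-4), d)
  })
  prof <- efficiencyVsDistance(pJit, nBoot = 50)
  expect_lt(abs(prof$r), 0.25)
  expect_true(prof$conf_int[1] < 0 && prof$conf_int[2] > 0)
  # perfectly linear: r = 1
  pLin <- syntheticParticleTable(50, efficiency = 0.3 * sort(runif(50, 1, 9)),
                                 distance = sort(runif(50, 1, 9)))
  pLin$efficiency <- 0.3 * pLin$distance_um
  expect_equal(efficiencyVsDistance(pLin, nBoot = 10)$r, 1)
  expect_error(efficiencyVsDistance(pLin[1:5, ]), "at least 10")
  pConst <- syntheticParticleTable(20, efficiency = 1, distance = 1:20)
  expect_error(efficiencyVsDistance(pConst), "zero variance")
})

test_that("null simulations give near-nominal CI coverage for r", {
  geom <- makeCellGeometry(30, 30, pixelSize = 0.32, seed = 54)
  cover <- vapply(1:60, function(s) {
    p <- sampleParticles(geom, 300, spatialModel("localized"), seed = s)
    withr::with_seed(1000 + s, {
      eff <- p$ribosome_load / 6 + rnorm(300, 0, 0.1)
    })
    tab <- syntheticParticleTable(300, eff, p$distance_um)
    prof <- efficiencyVsDistance(tab, nBoot = 2)
    prof$conf_int[1] <= 0 && prof$conf_int[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.88)
})

test_that("distance ECDF reports median, band fraction and dominance", {
  e <- distanceEcdf(c(1, 2, 3, 4))
  expect_equal(e$median, 2.5)
  expect_equal(e$ecdf(2.5), 0.5)
  expect_equal(distanceEcdf(c(1, 1, 2, 2))$ecdf(2), 1)
  expect_error(distanceEcdf(numeric(0)), "no distances")

  geom <- makeCellGeometry(45, 45, pixelSize = 0.32, seed = 55)
  loc <- sampleParticles(geom, 300, spatialModel("localized"), seed = 56)
  ctl <- sampleParticles(geom, 300, spatialModel("control"), seed = 57)
  expect_lt(distanceEcdf(loc)$median, distanceEcdf(ctl)$median)
  ks <- suppressWarnings(ks.test(loc$distance_um, ctl$distance_um,
                                 alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})

test_that("PDI has its defining fixed points and oracle agreement", {
  disc <- discGeometry(radiusUm = 8, pixelSize = 0.32, nucleusFrac = 0.25)
  mask <- cellMask(disc)
  uniform <- matrix(1, nrow(mask), ncol(mask))
  expect_equal(pdi(uniform, disc)$pdi, 1, tolerance = 1e-6)

  # all mass at the nucleus centroid
  res <- pdi(uniform, disc)
  ctr <- res$nucleus_centroid
  atCentroid <- data.frame(row_px = ctr[1], col_px = ctr[2])
  expect_equal(pdi(atCentroid, disc)$pdi, 0)

  # edge-band mass: brute-force double-sum oracle, and PDI > 1
  band <- edgeBandMask(disc, 2)
  sig <- matrix(0, nrow(mask), ncol(mask)); sig[band] <- 1
  got <- pdi(sig, disc)$pdi
  gr <- periTrans:::gridRows(mask); gc <- periTrans:::gridCols(mask)
  d2 <- (gr - ctr[1])^2 + (gc - ctr[2])^2
  oracle <- (sum(d2[band]) / sum(band)) / (sum(d2[mask]) / sum(mask))
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_gt(got, 1)

  # scale invariance and monotone outward transport
  expect_equal(pdi(sig * 7.3, disc)$pdi, got, tolerance = 1e-12)
  inner <- data.frame(row_px = ctr[1] + c(2, -2), col_px = ctr[2] + c(1, 0))
  outer <- inner; outer$row_px <- ctr[1] + c(20, -20)
  expect_gt(pdi(outer, disc)$pdi, pdi(inner, disc)$pdi)
  expect_error(pdi(data.frame(row_px = 1, col_px = 1, weight = 0), disc),
               "zero")
})

test_that("peripherally biased draws score higher PDI than uniform draws", {
  geom <- makeCellGeometry(30, 30, pixelSize = 0.32, seed = 58)
  pdiOf <- function(model, seed) {
    p <- sampleParticles(geom, 150, model, seed = seed)
    pdi(p, geom)$pdi
  }
  peri <- vapply(1:25, function(s)
    pdiOf(spatialModel("localized", medianEdgeDistanceUm = 2), s),
    numeric(1))
  unif <- vapply(1:25, function(s)
    pdiOf(spatialModel("uniform"), 100 + s),
    numeric(1))
  expect_gt(mean(peri), mean(unif))
  expect_lt(t.test(peri, unif, alternative = "greater")$p.value, 0.01)
})
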