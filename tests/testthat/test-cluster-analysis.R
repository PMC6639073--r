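test_that("unit intensity estimation finds the single-molecule peak", {
  withr::with_seed(61, {
    x <- rnorm(500, 100, 15)
  })
  u <- estimateUnitIntensity(x)
  expect_true(u$unit > 95 && u$unit < 105)
  expect_null(u$warning)

  # identical values: unit equals the value, sd 0
  u2 <- estimateUnitIntensity(rep(80, 30), method = "median")
  expect_equal(u2$unit, 80)
  expect_equal(u2$sd, 0)

  # 10% cluster tail does not move the mode
  withr::with_seed(62, {
    mix <- c(rnorm(450, 100, 15), rnorm(50, 500, 50))
  })
  u3 <- estimateUnitIntensity(mix)
  expect_true(u3$unit > 95 && u3$unit < 105)

  expect_error(estimateUnitIntensity(rnorm(5)), "at least 20")
  # three comparable peaks: no mode holds 40% of the mass
  withr::with_seed(63, {
    multimodal <- c(rnorm(150, 100, 5), rnorm(130, 300, 5),
                    rnorm(120, 900, 5))
  })
  expect_warning(estimateUnitIntensity(multimodal), "dominant")
})

test_that("classification rules implement their thresholds", {
  calls <- classifyParticles(c(350, 450), absoluteRule(400))
  expect_equal(calls$label, c("single", "cluster"))
  expect_error(absoluteRule(-1), "positive")

  # all at the unit: all single under the relative rule
  rel <- classifyParticles(rep(100, 10), relativeRule(100, 10))
  expect_true(all(rel$label == "single"))
  expect_true(all(rel$estimated_copies == 1))

  # copies rule rounds to the nearest multiple
  cp <- classifyParticles(c(95, 210, 480), copiesRule(100))
  expect_equal(cp$label, c("single", "cluster", "cluster"))
  expect_equal(cp$estimated_copies, c(1L, 2L, 5L))

  # scale equivariance of relative and copies calls
  x <- c(80, 120, 400, 900)
  a <- classifyParticles(x, relativeRule(100, 20))
  b <- classifyParticles(3 * x, relativeRule(300, 60))
  expect_equal(a$label, b$label)
  expect_equal(a$estimated_copies, b$estimated_copies)
})

test_that("mixture classification reaches high sensitivity and specificity", {
  withr::with_seed(64, {
    sing <- rnorm(800, 100, 20)
    k <- sample(4:12, 200, TRUE)
    clus <- rnorm(200, 100 * k, 0.2 * 100 * k)
  })
  ints <- c(sing, clus)
  isClus <- rep(c(FALSE, TRUE), c(800, 200))
  u <- estimateUnitIntensity(ints)
  calls <- classifyParticles(ints, relativeRule(u$unit, u$sd))
  expect_gte(mean(calls$label[isClus] == "cluster"), 0.95)
  expect_gte(mean(calls$label[!isClus] == "single"), 0.95)

  # median estimated copies is exact for k = 2..8 at 20% CV
  for (kk in 2:8) {
    withr::with_seed(64 + kk, {
      x <- rnorm(300, 100 * kk, 0.2 * 100 * kk)
    })
    cc <- classifyParticles(x, copiesRule(100))
    expect_equal(median(cc$estimated_copies), kk)
  }
})

test_that("region comparison matches the enumeration oracle", {
  # diagonal table with unit margins: p = 1 by enumeration
  mk <- function(n) rep(c("single", "cluster"), n)
  r <- compareRegions(list(a = c("single"), b = c("cluster")))
  expect_equal(r$p, 1)

  # identical rows: no association
  r2 <- compareRegions(list(a = mk(c(10, 5)), b = mk(c(10, 5))))
  expect_equal(r2$p, 1)

  # strong association: agrees with exhaustive enumeration
  tab <- matrix(c(20, 2, 1, 19), 2)
  r3 <- compareRegions(list(a = rep(c("single", "cluster"), tab[, 1]),
                            b = rep(c("single", "cluster"), tab[, 2])))
  expect_lt(abs(r3$p - fisherEnumP(tab)), 1e-12)

  # property: equality with enumeration over random small tables
  withr::with_seed(65, {
    tabs <- replicate(300, matrix(rpois(4, 4), 2), simplify = FALSE)
  })
  for (t0 in tabs) {
    if (any(rowSums(t0) == 0) || any(colSums(t0) == 0)) next
    got <- compareRegions(list(
      a = rep(c("single", "cluster"), t0[, 1]),
      b = rep(c("single", "cluster"), t0[, 2])))$p
    expect_lt(abs(got - fisherEnumP(t0)), 1e-10)
  }

  # zero margin: p = 1 with a warning
  expect_warning(rz <- compareRegions(list(a = mk(c(5, 0)), b = mk(c(3, 0)))),
                 "margin")
  expect_equal(rz$p, 1)
})

test_that("cluster overlap follows the geometry and the Poisson law", {
  a <- cbind(row_um = c(1, 5, 9), col_um = c(1, 5, 9))
  expect_equal(clusterOverlap(a, a), 100)
  b <- a + 20
  expect_equal(clusterOverlap(a, b, maxDistUm = 0.5), 0)
  expect_error(clusterOverlap(a[0, ], b), "empty")

  # Poisson-random B at density rho: P(hit) = 1 - exp(-rho pi r^2)
  rho <- 0.8; r <- 0.5
  withr::with_seed(66, {
    hits <- vapply(1:300, function(i) {
      nB <- rpois(1, rho * 400)
      bb <- cbind(runif(nB, 0, 20), runif(nB, 0, 20))
      aa <- cbind(10, 10)
      if (nB == 0) 0 else clusterOverlap(aa, bb, maxDistUm = r)
    }, numeric(1))
  })
  expect_lt(abs(mean(hits) / 100 - (1 - exp(-rho * pi * r^2))), 0.06)
})

test_that("protrusion scoring recovers the seeded positive fraction", {
  geom <- makeCellGeometry(40, 40, nProtrusions = 3, pixelSize = 0.32,
                           seed = 67)
  tips <- protrusionTips(geom)
  mkRoi <- function(tip, r = 6) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    ctrDir <- (dim(cellMask(geom)) - 1) / 2 - tip
    inward <- tip + 0.35 * ctrDir
    cbind(inward[1] + r * sin(th), inward[2] + r * cos(th))
  }
  rois <- lapply(seq_len(nrow(tips)), function(i) mkRoi(tips[i, ]))
  # seed a cluster particle inside ROI 1 only
  parts <- list(rna = data.frame(row_px = mean(rois[[1]][, 1]),
                                 col_px = mean(rois[[1]][, 2]),
                                 label = "cluster"))
  sc <- scoreProtrusions(rois, geom, particles = parts)
  expect_identical(sc$perRoi$rna, c(TRUE, FALSE, FALSE))
  expect_equal(unname(sc$positiveFraction["rna"]), 1 / 3)

  # two channels produce the 4-way category table
  parts$polyA <- parts$rna
  sc2 <- scoreProtrusions(rois, geom, particles = parts)
  expect_equal(sum(sc2$categories), 3)
  expect_equal(unname(sc2$categories[4]), 1)  # rna+/polyA+

  expect_equal(scoreProtrusions(list(), geom, particles = parts)$n_rois, 0)
  badRoi <- list(cbind(c(-3, -3, -1), c(0, 2, 1)))
  expect_error(scoreProtrusions(badRoi, geom, particles = parts),
               "outside the cell mask")
})

test_that("seeded granule fractions are recovered across many ROIs", {
  geom <- discGeometry(radiusUm = 25, pixelSize = 0.32)
  ctr <- (dim(cellMask(geom)) - 1) / 2
  rPx <- 25 / 0.32
  # non-overlapping ROIs on a grid inside the cell
  g <- as.matrix(expand.grid(seq(8, 2 * ctr[1] - 8, by = 8),
                             seq(8, 2 * ctr[2] - 8, by = 8)))
  g <- g[sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2) < 0.85 * rPx, ]
  nRoi <- min(300, nrow(g))
  g <- g[seq_len(nRoi), , drop = FALSE]
  withr::with_seed(68, {
    hasGranule <- runif(nRoi) < 0.3
  })
  rois <- lapply(seq_len(nRoi), function(i) {
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(g[i, 1] + 3 * sin(th), g[i, 2] + 3 * cos(th))
  })
  pts <- g[hasGranule, , drop = FALSE]
  parts <- list(polyA = data.frame(row_px = pts[, 1], col_px = pts[, 2],
                                   label = "cluster"))
  sc <- scoreProtrusions(rois, geom, particles = parts)
  expect_lt(abs(sc$positiveFraction[["polyA"]] - 0.3), 0.05)
})
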