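test_that("lesion phantom: disk area matches a brute-force pixel count", {
  g <- ScanGrid(120, 120, pitchX = 12)
  ph <- makeLesionPhantom(g, centerXY = c(60, 60), radiusUm = 500, seed = 1)
  # oracle: count pixel centers within 500 um of the center, by direct loop
  cnt <- 0L
  for (y in 1:120) for (x in 1:120)
    if (((x - 60) * 12)^2 + ((y - 60) * 12)^2 <= 500^2) cnt <- cnt + 1L
  expect_identical(sum(pixels(ph$truthMNV)), cnt)
  expect_true(all(pixels(ph$truthVessels) <= pixels(ph$truthMNV)))
})

test_that("lesion phantom is deterministic under a fixed seed and empty on request", {
  g <- ScanGrid(80, 80, pitchX = 12)
  a <- makeLesionPhantom(g, radiusUm = 400, seed = 42)
  b <- makeLesionPhantom(g, radiusUm = 400, seed = 42)
  expect_identical(voxels(a$flow), voxels(b$flow))
  expect_identical(pixels(a$truthVessels), pixels(b$truthVessels))
  e <- makeLesionPhantom(g, radiusUm = 0)
  expect_false(any(pixels(e$truthMNV)))
  expect_false(any(pixels(e$truthVessels)))
  expect_error(makeLesionPhantom(g, radiusUm = 20), "2 pixels")
})

test_that("cc phantom: truth FD fraction equals the rasterized disk count", {
  g <- ScanGrid(84, 84, pitchX = 12)   # ~1 mm^2 region
  disks <- data.frame(x = c(20, 42, 64), y = c(30, 50, 30), diameter_um = 50)
  cc <- makeCcPhantom(g, disks)
  cnt <- 0L
  for (i in 1:3) for (y in 1:84) for (x in 1:84)
    if (((x - disks$x[i]) * 12)^2 + ((y - disks$y[i]) * 12)^2 <= 25^2) cnt <- cnt + 1L
  expect_identical(sum(pixels(cc$truthFD)), cnt)   # disks are disjoint here
  expect_true(all(pixels(cc$ccFlow)[pixels(cc$truthFD)] <
                  min(pixels(cc$ccFlow)[!pixels(cc$truthFD)])))
  none <- makeCcPhantom(g)
  expect_false(any(pixels(none$truthFD)))
  expect_error(makeCcPhantom(g, data.frame(x = 2, y = 2, diameter_um = 200)),
               "beyond the grid")
})

test_that("sampled deficit disks are disjoint and avoid the lesion", {
  g <- ScanGrid(200, 200, pitchX = 12)
  mnv <- BinaryMask(octamnv:::diskMask(g, c(100, 100), 400), g, "t")
  d <- sampleFdDisks(g, 15, c(30, 90), avoidMask = mnv, avoidBufferUm = 24, seed = 3)
  expect_equal(nrow(d), 15L)
  for (i in 1:14) for (j in (i + 1):15) {
    cc <- sqrt(((d$x[i] - d$x[j]) * 12)^2 + ((d$y[i] - d$y[j]) * 12)^2)
    expect_gt(cc, (d$diameter_um[i] + d$diameter_um[j]) / 2)
  }
  cc2 <- makeCcPhantom(g, d)
  expect_false(any(pixels(cc2$truthFD) & pixels(mnv)))
})

test_that("ped phantom closed-form volume agrees with numeric integration", {
  g <- ScanGrid(300, 300, pitchX = 12)
  ped <- makePedPhantom(g, data.frame(x = 150, y = 150, h_um = 100, sigma_um = 250))
  expect_equal(ped$truthTotalVolumeMm3, 2 * pi * 250^2 * 100 / 1e9)
  expect_equal(ped$truthTotalVolumeMm3, numericBumpVolumeMm3(100, 250),
               tolerance = 1e-4)
  none <- makePedPhantom(g)
  expect_true(all(zUm(none$rpe) == zUm(none$bm)))
  expect_equal(none$truthTotalVolumeMm3, 0)
  two <- makePedPhantom(g, data.frame(x = c(75, 225), y = 150, h_um = 50, sigma_um = 80))
  expect_equal(two$truthTotalVolumeMm3, 2 * (2 * pi * 80^2 * 50 / 1e9))
  expect_error(makePedPhantom(g, data.frame(x = 10, y = 10, h_um = 5, sigma_um = 5)),
               "sigma")
})

test_that("choroid phantom truths come from construction and voxel counting", {
  g <- ScanGrid(100, 100, pitchX = 40, pitchZ = 4)
  ch <- makeChoroidPhantom(g, 200, 0.3, "planes")
  expect_equal(ch$truth$mct_um, 200)
  expect_equal(ch$truth$cvi, 0.3)
  z <- makeChoroidPhantom(g, 200, 0, "planes")
  expect_equal(z$truth$cvi, 0)
  cyl <- makeChoroidPhantom(g, 250, mode = "cylinders", nCylinders = 30, seed = 8)
  slab <- octamnv:::.slabVoxels(g, dim(voxels(cyl$volume))[1], cyl$bm, cyl$csi)
  circ <- octamnv:::circleMask(g, 5)
  circA <- aperm(array(circ, c(100, 100, dim(slab)[1])), c(3, 1, 2))
  expect_equal(cyl$truth$cvi,
               sum(cyl$vesselTruth & slab & circA) / sum(slab & circA))
  expect_error(makeChoroidPhantom(g, 200, 0.97), "0.95")
  expect_error(makeChoroidPhantom(g, -5, 0.3), "positive")
})

test_that("cohort generator reproduces the requested moments", {
  mom <- referenceCohortMoments()
  big <- makeCohort(mom, nPerGroup = c(no_exudation = 1e5, exudation = 1e5), seed = 11)
  for (grp in c("no_exudation", "exudation")) {
    sub <- big[big$group == grp, ]
    for (m in c("vad", "mct_um")) {
      row <- mom[mom$metric == m & mom$group == grp, ]
      se <- row$sd_visit2 / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[paste0(m, "_v2")]]) - row$mean_visit2), 3 * se + 1e-12)
    }
  }
  expect_true(all(big$days_between > 0))
})

test_that("cohort generator: zero SD collapses to the mean; seed fixes the table", {
  mom <- referenceCohortMoments()
  mom$sd_visit2 <- 0; mom$sd_rate <- 0
  flat <- makeCohort(mom, seed = 2)
  expect_true(all(flat$vsd_v2[flat$group == "exudation"] == 0.149))
  a <- makeCohort(seed = 5); b <- makeCohort(seed = 5)
  expect_identical(a, b)
  skewed <- makeCohort(distribution = "lognormal_shifted",
                       nPerGroup = c(no_exudation = 2e4, exudation = 2e4), seed = 3)
  x <- skewed$mct_um_v2[skewed$group == "exudation"]
  expect_equal(mean(x), 244.7, tolerance = 0.02)
  expect_equal(sd(x), 95.3, tolerance = 0.05)
  expect_gt(mean(((x - mean(x)) / sd(x))^3), 1)   # right-skewed
})
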