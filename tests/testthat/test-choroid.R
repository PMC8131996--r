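test_that("attenuation compensation: constant A-scan, scale invariance, flags", {
  g <- ScanGrid(4, 4, pitchX = 12, pitchZ = 4)
  vol <- OctVolume(array(1, c(60, 4, 4)), g)
  comp <- attenuationCompensate(vol)
  prof <- voxels(comp)[, 2, 2]
  expect_true(all(diff(prof) > 0))        # tail shrinks with depth

  set.seed(5)
  arr <- array(runif(60 * 4 * 4, 0.1, 1), c(60, 4, 4))
  c1 <- attenuationCompensate(OctVolume(arr, g))
  c2 <- attenuationCompensate(OctVolume(7.3 * arr, g))
  expect_equal(voxels(c1) / max(voxels(c1)), voxels(c2) / max(voxels(c2)),
               tolerance = 1e-9)

  arr0 <- arr; arr0[, 1, 1] <- 0
  cz <- attenuationCompensate(OctVolume(arr0, g))
  expect_identical(attr(cz, "flaggedAScans"), 1L)
  expect_true(all(voxels(cz)[, 1, 1] == 0))
})

test_that("compensation suppresses a cast shadow by at least 2x", {
  g <- ScanGrid(20, 20, pitchX = 12, pitchZ = 4)
  nz <- 80
  arr <- array(0.5, c(nz, 20, 20))
  arr[10, , 1:10] <- 5                    # bright layer over the left half
  arr[11:nz, , 1:10] <- 0.25              # halves everything beneath it
  vol <- OctVolume(arr, g)
  comp <- attenuationCompensate(vol)
  rawContrast <- mean(arr[30:40, , 11:20]) / mean(arr[30:40, , 1:10])
  compContrast <- mean(voxels(comp)[30:40, , 11:20]) / mean(voxels(comp)[30:40, , 1:10])
  expect_gte(rawContrast / max(compContrast, 1 / compContrast), 2 - 1e-4)
})

test_that("choroidal thickness map and MCT match brute-force oracles", {
  g <- ScanGrid(160, 160, pitchX = 40, pitchZ = 4)   # 6.4 mm scan, 5-mm circle fits
  ct <- choroidalThickness(Surface("bm", 40, g), Surface("csi", 240, g))
  expect_equal(ct$mct_um, 200)

  ramp <- matrix(rep(seq(-100, 100, length.out = 160), each = 160), 160, 160)
  ct2 <- choroidalThickness(Surface("bm", 40, g), Surface("csi", 240 + ramp, g))
  expect_equal(ct2$mct_um, 200, tolerance = 1e-9)    # symmetric about fovea

  set.seed(8)
  th <- matrix(150 + runif(160 * 160, 0, 100), 160, 160)
  ct3 <- choroidalThickness(Surface("bm", 40, g), Surface("csi", 40 + th, g))
  circ <- octamnv:::circleMask(g, 5)
  expect_equal(ct3$mct_um, mean(th[circ]), tolerance = 1e-9)

  small <- ScanGrid(100, 100, pitchX = 40)
  expect_error(choroidalThickness(Surface("bm", 40, small),
                                  Surface("csi", 240, small)), "clipped")
  expect_error(choroidalThickness(Surface("bm", 240, g), Surface("csi", 40, g)),
               "posterior")
})

test_that("Otsu vessel segmentation is exact on a two-valued slab", {
  g <- ScanGrid(60, 60, pitchX = 40, pitchZ = 4)
  ch <- makeChoroidPhantom(g, 200, 0.3, "planes", attenuation = FALSE)
  ves <- segmentChoroidVessels(ch$volume, ch$bm, ch$csi)
  expect_identical(unname(ves & attr(ves, "slab")), unname(ch$vesselTruth))
  z <- makeChoroidPhantom(g, 200, 0, "planes", attenuation = FALSE)
  vz <- segmentChoroidVessels(z$volume, z$bm, z$csi)
  expect_false(any(vz & attr(vz, "slab")))
})

test_that("CVI equals construction and the weighted-map identity holds", {
  g <- ScanGrid(150, 150, pitchX = 40, pitchZ = 4)
  ch <- makeChoroidPhantom(g, 200, 0.3, "planes", attenuation = FALSE)
  ves <- segmentChoroidVessels(ch$volume, ch$bm, ch$csi)
  cv <- cviMetrics(ves, g)
  expect_equal(cv$cvi, 0.3)

  slab <- attr(ves, "slab")
  allVessel <- slab
  attr(allVessel, "slab") <- slab
  expect_equal(cviMetrics(allVessel, g)$cvi, 1)

  circ <- octamnv:::circleMask(g, 5)
  nslab <- colSums(slab)
  w <- nslab[circ]
  expect_equal(cv$cvi, sum(cv$cvi_map[circ] * w, na.rm = TRUE) / sum(w))
})

test_that("compensated-route CVI recovers cylinder phantoms within 0.02", {
  g <- ScanGrid(140, 140, pitchX = 40, pitchZ = 4)
  for (s in c(5, 9)) {
    ch <- makeChoroidPhantom(g, 250, mode = "cylinders", nCylinders = 50, seed = s)
    comp <- attenuationCompensate(ch$volume)
    cv <- cviMetrics(segmentChoroidVessels(comp, ch$bm, ch$csi), g)
    expect_lt(abs(cv$cvi - ch$truth$cvi), 0.02)
  }
})

test_that("CVI is stable under intensity scaling and choroid thickening", {
  g <- ScanGrid(140, 140, pitchX = 40, pitchZ = 4)
  ch <- makeChoroidPhantom(g, 250, mode = "cylinders", nCylinders = 50, seed = 7)
  v1 <- cviMetrics(segmentChoroidVessels(attenuationCompensate(ch$volume),
                                         ch$bm, ch$csi), g)$cvi
  scaled <- OctVolume(3 * voxels(ch$volume), scanGrid(ch$volume))
  v2 <- cviMetrics(segmentChoroidVessels(attenuationCompensate(scaled),
                                         ch$bm, ch$csi), g)$cvi
  expect_equal(v1, v2, tolerance = 1e-9)

  thin <- makeChoroidPhantom(g, 200, 0.3, "planes", attenuation = FALSE)
  thick <- makeChoroidPhantom(g, 320, 0.3, "planes", attenuation = FALSE)
  cThin <- cviMetrics(segmentChoroidVessels(thin$volume, thin$bm, thin$csi), g)$cvi
  cThick <- cviMetrics(segmentChoroidVessels(thick$volume, thick$bm, thick$csi), g)$cvi
  expect_lt(abs(cThick - cThin), 0.01)
})
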