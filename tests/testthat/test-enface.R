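test_that("mean projection of a constant volume is constant for any slab", {
  g <- ScanGrid(20, 20, pitchX = 12, pitchZ = 4)
  vol <- OctVolume(array(0.37, c(30, 20, 20)), g)
  surf <- list(bm = Surface("bm", 40, g), outer_retina = Surface("outer_retina", 12, g))
  for (slab in list(slabPreset("cc_16um"), slabPreset("orcc"),
                    slabDefinition("outer_retina", 3.5, thicknessUm = 21.7))) {
    en <- extractEnface(vol, surf, slab)
    expect_true(all(abs(pixels(en) - 0.37) < 1e-12))
  }
})

test_that("CC slab offsets select exactly the stated voxel planes", {
  # BM at 300 um, slab top 304 um, 16 um thick, pitch 4 um -> planes 77..80
  g <- ScanGrid(5, 4, pitchX = 12, pitchZ = 4)
  nz <- 100
  arr <- array(rep(seq_len(nz), 4 * 5), c(nz, 4, 5))   # value = plane index
  vol <- OctVolume(arr, g)
  en <- extractEnface(vol, list(bm = Surface("bm", 300, g)), slabPreset("cc_16um"))
  expect_true(all(abs(pixels(en) - mean(77:80)) < 1e-12))
})

test_that("CC slab extraction reproduces the phantom en face image", {
  g <- ScanGrid(60, 60, pitchX = 12, pitchZ = 4)
  disks <- data.frame(x = c(20, 45), y = c(20, 40), diameter_um = 60)
  cc <- makeCcPhantom(g, disks)
  nz <- 12
  arr <- aperm(array(pixels(cc$ccFlow), c(60, 60, nz)), c(3, 1, 2))
  vol <- FlowVolume(arr, g)
  en <- extractEnface(vol, list(bm = Surface("bm", 10, g)), slabPreset("cc_16um"))
  expect_equal(pixels(en), pixels(cc$ccFlow), tolerance = 1e-6)
})

test_that("a slab leaving the volume fails beyond the clipped-fraction limit", {
  g <- ScanGrid(10, 10, pitchX = 12, pitchZ = 4)
  vol <- OctVolume(array(1, c(10, 10, 10)), g)
  expect_error(extractEnface(vol, list(bm = Surface("bm", 38, g)), slabPreset("cc_16um")),
               "exits volume")
  en <- extractEnface(vol, list(bm = Surface("bm", 38, g)), slabPreset("cc_16um"),
                      maxClippedFraction = 1)
  expect_equal(attr(en, "clippedFraction"), 1)
})

test_that("projection-artifact removal: identity, constancy, idempotence", {
  g <- ScanGrid(40, 40, pitchX = 12)
  img <- EnFaceImage(matrix(0.8, 40, 40), g)
  none <- BinaryMask(matrix(FALSE, 40, 40), g, "rv")
  expect_identical(pixels(removeProjectionArtifacts(img, none)), pixels(img))

  stripe <- matrix(FALSE, 40, 40); stripe[, 18:20] <- TRUE
  mask <- BinaryMask(stripe, g, "rv")
  expect_lt(max(abs(pixels(removeProjectionArtifacts(img, mask)) - 0.8)), 1e-12)

  set.seed(1)
  noisy <- matrix(0.8 + rnorm(1600, 0, 0.02), 40, 40)
  bright <- noisy; bright[stripe] <- 2   # projection artifact under the mask
  rem <- removeProjectionArtifacts(EnFaceImage(bright, g), mask)
  expect_lt(max(pixels(rem)[stripe]) - 0.8, 3 * 0.02)      # stripe suppressed
  expect_identical(pixels(rem)[!stripe], bright[!stripe])  # others untouched
  again <- removeProjectionArtifacts(rem, mask)
  expect_lt(max(abs(pixels(again) - pixels(rem))), 1e-6)   # idempotent
  big <- BinaryMask(matrix(TRUE, 40, 40), g, "rv")
  expect_error(removeProjectionArtifacts(img, big), "50%")
})

test_that("structural compensation flattens shading and is scale-equivariant", {
  g <- ScanGrid(60, 60, pitchX = 12)
  shading <- matrix(1, 60, 60); shading[, 1:30] <- 0.5
  cc <- makeCcPhantom(g, shading = shading, background = 0.8)
  # knife-edge shading: exact division (no structural smoothing) flattens it
  comp <- compensateCC(cc$ccFlow, cc$ccStructure, sigmaPx = 0)
  px <- pixels(comp)
  expect_lt((max(px) - min(px)) / mean(px), 0.01)       # uniform within 1%
  expect_equal(mean(px), mean(pixels(cc$ccFlow)))       # mean preserved
  # with the default smoothing, flatness holds away from the edge band
  compSm <- compensateCC(cc$ccFlow, cc$ccStructure)
  interior <- pixels(compSm)[, c(1:18, 43:60)]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.01)

  uni <- compensateCC(cc$ccFlow, EnFaceImage(matrix(3.3, 60, 60), g))
  expect_equal(pixels(uni), pixels(cc$ccFlow), tolerance = 1e-12)

  scaled <- compensateCC(cc$ccFlow, EnFaceImage(7 * pixels(cc$ccStructure), g))
  expect_equal(pixels(scaled), pixels(compSm), tolerance = 1e-12)
  expect_error(compensateCC(cc$ccFlow, EnFaceImage(matrix(0, 60, 60), g)), "zero")
})

test_that("compensation preserves FD% ranking between shaded phantoms", {
  g <- ScanGrid(80, 80, pitchX = 12)
  disksA <- data.frame(x = c(20, 60), y = c(20, 60), diameter_um = 80)
  disksB <- data.frame(x = c(20, 60, 40), y = c(20, 60, 40), diameter_um = 80)
  shading <- matrix(seq(0.4, 1, length.out = 80), 80, 80, byrow = TRUE)
  fdpct <- sapply(list(disksA, disksB), function(d) {
    cc <- makeCcPhantom(g, d, shading = shading)
    comp <- compensateCC(cc$ccFlow, cc$ccStructure)
    fd <- segmentFlowDeficits(comp, "fixed", threshold = 0.5)
    100 * sum(pixels(fd)) / length(pixels(fd))
  })
  expect_lt(fdpct[1], fdpct[2])   # more deficit area ranks higher
})
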