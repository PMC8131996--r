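test_that("lesion-flow masking zeroes everything outside the mask", {
  g <- ScanGrid(30, 30, pitchX = 12)
  img <- EnFaceImage(matrix(runif(900), 30, 30), g)
  full <- BinaryMask(matrix(TRUE, 30, 30), g, "t")
  expect_identical(pixels(maskLesionFlow(img, full)), pixels(img))
  none <- BinaryMask(matrix(FALSE, 30, 30), g, "t")
  expect_true(all(pixels(maskLesionFlow(img, none)) == 0))
  check <- BinaryMask(outer(1:30, 1:30, function(a, b) (a + b) %% 2 == 0), g, "t")
  out <- pixels(maskLesionFlow(img, check))
  expect_true(all(out[!pixels(check)] == 0))
  expect_identical(out[pixels(check)], pixels(img)[pixels(check)])
})

test_that("vessel binarization recovers noise-free phantom trees (Dice >= 0.9)", {
  g <- ScanGrid(250, 250, pitchX = 12)
  for (s in c(7, 23)) {
    ph <- makeLesionPhantom(g, radiusUm = 600, seed = s, nz = 2)
    en <- EnFaceImage(voxels(ph$flow)[1, , ], scanGrid(ph$flow))
    vb <- binarizeVessels(maskLesionFlow(en, ph$truthMNV), ph$truthMNV)
    expect_gte(dice(vb, ph$truthVessels), 0.9)
    expect_true(all(pixels(vb) <= pixels(ph$truthMNV)))   # output within mask
  }
})

test_that("binarization of a zero image is empty", {
  g <- ScanGrid(60, 60, pitchX = 12)
  m <- BinaryMask(octamnv:::diskMask(g, c(30, 30), 250), g, "t")
  z <- EnFaceImage(matrix(0, 60, 60), g)
  expect_false(any(pixels(binarizeVessels(z, m))))
})

test_that("an oversized adaptive window is auto-shrunk with a warning", {
  g <- ScanGrid(60, 60, pitchX = 12)
  m <- BinaryMask(octamnv:::diskMask(g, c(30, 30), 120), g, "t")
  img <- matrix(0, 60, 60); img[pixels(m)] <- 1
  expect_warning(binarizeVessels(EnFaceImage(img, g), m, windowPx = 59L), "shrinking")
})

test_that("skeletonization yields unit-width centerlines of the right length", {
  g <- ScanGrid(120, 20, pitchX = 12)
  bar <- matrix(FALSE, 20, 120); bar[9:11, 11:110] <- TRUE   # 3 x 100 bar
  sk <- skeletonizeVessels(BinaryMask(bar, g, "t"))
  expect_lte(abs(sum(pixels(sk)) - 98), 2)   # oracle thinning length = 98
  expect_true(all(pixels(sk) <= bar))

  line <- matrix(FALSE, 20, 120); line[10, 11:110] <- TRUE
  expect_identical(pixels(skeletonizeVessels(BinaryMask(line, g, "t"))), line)
  empty <- BinaryMask(matrix(FALSE, 20, 120), g, "t")
  expect_false(any(pixels(skeletonizeVessels(empty))))
})

test_that("VAD/VSD are the pixel-count ratios of the quoted definitions", {
  g <- ScanGrid(100, 100, pitchX = 12)
  mnv <- BinaryMask(matrix(TRUE, 100, 100), g, "t")
  expect_equal(vascularDensity(mnv, mnv, mnv)$vad, 1)

  bar <- matrix(FALSE, 100, 100); bar[50:52, 1:100] <- TRUE
  b <- BinaryMask(bar, g, "t")
  sk <- skeletonizeVessels(b)
  vd <- vascularDensity(b, sk, mnv)
  expect_equal(vd$vad, 0.03)
  expect_equal(vd$vsd, 0.01, tolerance = 0.05)
  expect_error(vascularDensity(b, sk, BinaryMask(matrix(FALSE, 100, 100), g, "t")),
               "empty")
})

test_that("VSD <= VAD for arbitrary vessel maps and both are rotation invariant", {
  g <- ScanGrid(150, 150, pitchX = 12)
  for (s in 1:5) {
    ph <- makeLesionPhantom(g, radiusUm = 450, seed = s, nz = 2)
    vb <- ph$truthVessels
    sk <- skeletonizeVessels(vb)
    vd <- vascularDensity(vb, sk, ph$truthMNV)
    expect_lte(vd$vsd, vd$vad)
  }
  ph <- makeLesionPhantom(g, radiusUm = 450, seed = 6, nz = 2)
  rot <- function(m) t(m)[, nrow(m):1]   # 90-degree rotation
  vb <- pixels(ph$truthVessels); mm <- pixels(ph$truthMNV)
  vd0 <- vascularDensity(ph$truthVessels, skeletonizeVessels(ph$truthVessels), ph$truthMNV)
  vbR <- BinaryMask(rot(vb), g, "t"); mmR <- BinaryMask(rot(mm), g, "t")
  vdR <- vascularDensity(vbR, skeletonizeVessels(vbR), mmR)
  expect_equal(vd0$vad, vdR$vad)   # pixel counts are exactly rotation invariant
  # thinning has a small directional bias, so VSD matches only approximately
  expect_equal(vd0$vsd, vdR$vsd, tolerance = 0.03)
})

test_that("dilating the vessel map moves VAD but the skeleton stays stable", {
  g <- ScanGrid(200, 200, pitchX = 12)
  mnv <- BinaryMask(matrix(TRUE, 200, 200), g, "t")
  # isolated vessel: skeleton length changes only by endpoint extension
  bar <- matrix(FALSE, 200, 200); bar[100:102, 21:180] <- TRUE
  dilBar <- BinaryMask(as.matrix(EBImage::dilate(bar, EBImage::makeBrush(3, "box"))) > 0, g, "t")
  v0 <- vascularDensity(BinaryMask(bar, g, "t"),
                        skeletonizeVessels(BinaryMask(bar, g, "t")), mnv)
  vD <- vascularDensity(dilBar, skeletonizeVessels(dilBar), mnv)
  expect_gt(vD$vad, v0$vad)
  expect_lt(abs(vD$vsd - v0$vsd) / v0$vsd, 0.05)
  # branching trees additionally merge neighboring branches when dilated;
  # the skeleton density still moves far less than the area density
  ph <- makeLesionPhantom(g, radiusUm = 600, seed = 12, nz = 2)
  vb <- pixels(ph$truthVessels)
  dil <- as.matrix(EBImage::dilate(vb, EBImage::makeBrush(3, "box"))) > 0 & pixels(ph$truthMNV)
  t0 <- vascularDensity(ph$truthVessels, skeletonizeVessels(ph$truthVessels), ph$truthMNV)
  tD <- vascularDensity(BinaryMask(dil, g, "t"),
                        skeletonizeVessels(BinaryMask(dil, g, "t")), ph$truthMNV)
  expect_lt(abs(tD$vsd - t0$vsd) / t0$vsd, 0.15)
  expect_lt(abs(tD$vsd - t0$vsd) / t0$vsd, (tD$vad - t0$vad) / t0$vad)
})
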