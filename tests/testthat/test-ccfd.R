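test_that("region partition matches the per-pixel distance oracle (anisotropic)", {
  g <- ScanGrid(60, 45, pitchX = 10, pitchY = 14)
  m <- octamnv:::diskMask(g, c(30, 22), 120)
  reg <- buildRegions(BinaryMask(m, g, "t"))
  d <- bruteForceEdtUm(m, 10, 14)
  lab <- regionLabels(reg)
  expect_true(all(lab[m] == 0))
  expect_true(all((lab == 1) == (d > 0 & d <= 300)))
  expect_true(all((lab == 2) == (d > 300 & d <= 600)))
  expect_true(all((lab == 3) == (d > 600)))
})

test_that("R1 pixel count at 12-um pitch matches the brute-force count", {
  g <- ScanGrid(120, 120, pitchX = 12)
  m <- octamnv:::diskMask(g, c(60, 60), 300)   # 25-px-radius MNV disk
  reg <- buildRegions(BinaryMask(m, g, "t"))
  d <- bruteForceEdtUm(m, 12, 12)
  expect_identical(sum(regionLabels(reg) == 1), sum(d > 0 & d <= 300))
})

test_that("regions always partition the scan, clip at borders, default to R3", {
  g <- ScanGrid(80, 80, pitchX = 12)
  nearBorder <- octamnv:::diskMask(g, c(5, 40), 150)
  lab <- regionLabels(buildRegions(BinaryMask(nearBorder, g, "t")))
  expect_identical(length(lab), sum(lab == 0) + sum(lab == 1) + sum(lab == 2) + sum(lab == 3))
  expect_identical(dim(lab), c(80L, 80L))
  empty <- buildRegions(BinaryMask(matrix(FALSE, 80, 80), g, "t"))
  expect_true(all(regionLabels(empty) == 3))
})

test_that("equivalent-diameter filter removes exactly the sub-24-um components", {
  g <- ScanGrid(40, 40, pitchX = 12)
  m <- matrix(FALSE, 40, 40)
  m[5, 5:7] <- TRUE                      # 3 px = 432 um^2 -> removed
  m[20, 20:23] <- TRUE                   # 4 px = 576 um^2 (d = 27.1) -> kept
  f <- filterSmallFDs(BinaryMask(m, g, "fd"))
  expect_false(any(pixels(f)[5, ]))
  expect_identical(sum(pixels(f)), 4L)
  expect_identical(pixels(filterSmallFDs(f)), pixels(f))       # idempotent
  e <- filterSmallFDs(BinaryMask(matrix(FALSE, 40, 40), g, "fd"))
  expect_false(any(pixels(e)))
})

test_that("filter agrees with an independent labeling + area-rule oracle", {
  set.seed(4)
  g <- ScanGrid(50, 50, pitchX = 12)
  m <- matrix(runif(2500) < 0.12, 50, 50)
  f <- filterSmallFDs(BinaryMask(m, g, "fd"))
  lab <- bfsLabel8(m)
  keepPx <- matrix(FALSE, 50, 50)
  for (k in seq_len(max(lab)))
    if (sum(lab == k) * 144 >= pi * 12^2) keepPx[lab == k] <- TRUE
  expect_identical(pixels(f), keepPx)
  expect_lte(sum(pixels(f)), sum(m))     # never increases FD area
})

test_that("global thresholding recovers noise-free deficits for any k in (0,3)", {
  g <- ScanGrid(100, 100, pitchX = 12)
  disks <- data.frame(x = c(30, 70), y = c(30, 65), diameter_um = c(80, 120))
  cc <- makeCcPhantom(g, disks)
  for (k in c(0.5, 1, 2.5)) {
    fd <- segmentFlowDeficits(cc$ccFlow, "mean_sd", k = k)
    expect_identical(pixels(fd), pixels(cc$truthFD))
  }
  uni <- EnFaceImage(matrix(0.8, 100, 100), g)
  expect_error(segmentFlowDeficits(uni, "mean_sd"), "zero-variance")
  expect_false(any(pixels(segmentFlowDeficits(uni, "fixed", threshold = 0.5))))
})

test_that("lowering a fixed threshold never increases the FD pixel count", {
  g <- ScanGrid(80, 80, pitchX = 12)
  cc <- makeCcPhantom(g, data.frame(x = 40, y = 40, diameter_um = 200),
                      speckleSd = 0.2, seed = 9)
  counts <- sapply(c(0.7, 0.5, 0.3, 0.1), function(th)
    sum(pixels(segmentFlowDeficits(cc$ccFlow, "fixed", threshold = th,
                                   minDiameterUm = 0))))
  expect_true(all(diff(counts) <= 0))
})

test_that("region FD metrics: constructed fractions, clipped mean areas, additivity", {
  g <- ScanGrid(100, 100, pitchX = 12)
  mnv <- octamnv:::diskMask(g, c(50, 50), 240)
  reg <- buildRegions(BinaryMask(mnv, g, "t"))
  lab <- regionLabels(reg)

  # fill exactly 10% of R1 (row-major first tenth of its pixels)
  r1 <- which(lab == 1)
  fd <- matrix(FALSE, 100, 100)
  fd[r1[seq_len(round(0.1 * length(r1)))]] <- TRUE
  met <- regionFdMetrics(BinaryMask(fd, g, "fd"), reg)
  expect_equal(met$fd_pct[met$region == "R1"], 10, tolerance = 0.01)

  # one 20-px component fully inside R2 -> mean FD area 2880 um^2
  run <- NULL
  for (y in 1:100) {
    r <- rle(lab[y, ] == 2)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= 20)[1]
    if (!is.na(i)) { run <- c(y, ends[i] - r$lengths[i] + 1L); break }
  }
  fd2 <- matrix(FALSE, 100, 100)
  fd2[run[1], run[2] + 0:19] <- TRUE
  stopifnot(all(lab[cbind(run[1], run[2] + 0:19)] == 2))
  met2 <- regionFdMetrics(BinaryMask(fd2, g, "fd"), reg)
  expect_equal(met2$mean_fd_area_um2[met2$region == "R2"], 20 * 144)
  expect_identical(met2$n_components[met2$region == "R2"], 1L)

  # union FD% equals the pixel-weighted mean of the regional FD%
  set.seed(2)
  fdr <- matrix(runif(1e4) < 0.15, 100, 100) & lab != 0
  m3 <- regionFdMetrics(BinaryMask(fdr, g, "fd"), reg)
  w <- m3$region_px[1:3]
  expect_equal(m3$fd_pct[4], sum(m3$fd_pct[1:3] * w) / sum(w))
})

test_that("empty regions report missing metrics", {
  g <- ScanGrid(30, 30, pitchX = 12)   # tiny scan: no pixel farther than 600 um
  mnv <- octamnv:::diskMask(g, c(15, 15), 100)
  reg <- buildRegions(BinaryMask(mnv, g, "t"))
  met <- regionFdMetrics(BinaryMask(matrix(FALSE, 30, 30), g, "fd"), reg)
  expect_true(is.na(met$fd_pct[met$region == "R3"]) || met$region_px[met$region == "R3"] > 0)
  expect_true(all(is.na(met$mean_fd_area_um2[met$region_px > 0])))  # no FDs anywhere
})
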