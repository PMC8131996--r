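## Attenuation compensation, choroidal thickness mapping, mean choroidal
## thickness (MCT) and choroidal vascularity index (CVI) in a fovea-centered
## 5-mm circle.

#' Attenuation-compensate a structural OCT volume
#'
#' Single-scatter attenuation compensation per A-scan: each voxel is divided
#' by (twice) the remaining integrated signal beneath it,
#' \code{Ic(z) = I(z)^n / (2 * sum_{z' > z} I(z')^n * dz + eps)}, which
#' removes the shadow cast by strongly reflecting overlying layers and
#' enhances choroidal contrast. The output is scaled so its maximum matches
#' the input maximum (offset-free, preserving intensity ratios); the result
#' is invariant to global scaling of the input (for n = 1 and a relative
#' eps floor). All-zero A-scans are left unchanged and counted in the
#' \code{flaggedAScans} attribute.
#'
#' @param volume an \linkS4class{OctVolume}.
#' @param n signal exponent (default 1).
#' @param epsFrac additive floor for the tail integral, as a fraction of its
#'   maximum (default 1e-6).
#' @return Compensated \linkS4class{OctVolume}.
#' @export
attenuationCompensate <- function(volume, n = 1, epsFrac = 1e-6) {
  g <- scanGrid(volume); v <- voxels(volume)
  nz <- dim(v)[1]; dz <- g@pitchZ
  npx <- dim(v)[2] * dim(v)[3]
  vm <- matrix(aperm(v, c(2, 3, 1)), nrow = npx)      # (pixel, z)
  vn <- vm^n
  # tail integral strictly below each plane
  tailI <- vn[, nz:1, drop = FALSE]
  if (nz > 1) for (k in 2:nz) tailI[, k] <- tailI[, k] + tailI[, k - 1L]
  tailI <- cbind(tailI[, (nz - 1):1, drop = FALSE], 0) * dz   # sum over z' > z
  eps <- epsFrac * max(tailI)
  if (eps == 0) eps <- epsFrac
  comp <- vn / (2 * tailI + eps)
  zeroA <- rowSums(vm) == 0
  comp[zeroA, ] <- vm[zeroA, ]
  # pure scaling (no offset) so intensity ratios survive the rescale
  if (max(comp) > 0) comp <- comp * (max(v) / max(comp))
  out <- aperm(array(comp, c(dim(v)[2], dim(v)[3], nz)), c(3, 1, 2))
  res <- OctVolume(out, g, signalStrength(volume))
  attr(res, "flaggedAScans") <- sum(zeroA)
  res
}

#' Choroidal thickness map and mean choroidal thickness
#'
#' Thickness = CSI depth minus BM depth per (x, y); MCT is its mean over
#' pixels whose centers lie within the fovea-centered circle of the given
#' diameter (default 5 mm, pixel-center membership, no partial-pixel
#' weighting). The full circle must fit inside the scan (12 x 12-mm scans
#' in practice).
#'
#' @param bm,csi \linkS4class{Surface} objects (CSI posterior to BM).
#' @param diameterMm analysis circle diameter (default 5).
#' @return list(ct_map = \linkS4class{EnFaceImage} (um), mct_um).
#' @export
choroidalThickness <- function(bm, csi, diameterMm = 5) {
  g <- scanGrid(bm)
  if (!identical(dim(zUm(bm)), dim(zUm(csi)))) stop("bm/csi grid mismatch")
  ct <- zUm(csi) - zUm(bm)
  if (any(ct < 0)) stop("csi must be posterior to bm everywhere")
  circ <- .checkedCircle(g, diameterMm)
  list(ct_map = EnFaceImage(ct, g), mct_um = mean(ct[circ]))
}

.checkedCircle <- function(g, diameterMm) {
  rUm <- diameterMm * 1000 / 2
  fx <- (g@foveaXY[1] - 0.5) * g@pitchX
  fy <- (g@foveaXY[2] - 0.5) * g@pitchY
  if (fx - rUm < 0 || fy - rUm < 0 ||
      fx + rUm > g@nx * g@pitchX || fy + rUm > g@ny * g@pitchY)
    stop(sprintf("%g-mm analysis circle clipped by the scan edge", diameterMm))
  circleMask(g, diameterMm)
}

#' Segment choroidal vessels by global Otsu thresholding
#'
#' Choroidal vessels appear dark on structural OCT, so slab intensities are
#' inverted (vessels bright) and a single Otsu threshold is computed from
#' the histogram of all voxels between BM and CSI (global thresholding over
#' the whole slab; a per-B-scan mode is available for sensitivity
#' analysis). Vessel voxels are the above-threshold voxels within the slab.
#'
#' @param volume compensated \linkS4class{OctVolume}.
#' @param bm,csi slab boundary \linkS4class{Surface}s.
#' @param perBScan compute a separate threshold per B-scan (default FALSE).
#' @return Logical (nz, ny, nx) array: vessel voxels; attribute
#'   \code{slab} holds the slab-membership array.
#' @export
segmentChoroidVessels <- function(volume, bm, csi, perBScan = FALSE) {
  g <- scanGrid(volume); v <- voxels(volume)
  slab <- .slabVoxels(g, dim(v)[1], bm, csi)
  if (!any(slab)) stop("empty choroidal slab")
  inv <- max(v[slab]) - v
  vessel <- array(FALSE, dim(v))
  if (perBScan) {
    for (y in seq_len(dim(v)[2])) {
      sy <- slab[, y, , drop = FALSE]
      if (!any(sy)) next
      vy <- inv[, y, , drop = FALSE]
      th <- otsuThreshold(vy[sy])
      vessel[, y, ][sy[, 1, ]] <- vy[sy] > th
    }
  } else {
    th <- otsuThreshold(inv[slab])
    vessel[slab] <- inv[slab] > th
  }
  attr(vessel, "slab") <- slab
  vessel
}

# Voxel-center slab membership: (k - 0.5) * pitchZ in [bm, csi).
.slabVoxels <- function(g, nz, bm, csi) {
  zc <- (seq_len(nz) - 0.5) * g@pitchZ
  b <- zUm(bm); c <- zUm(csi)
  out <- array(FALSE, c(nz, g@ny, g@nx))
  for (k in seq_len(nz)) out[k, , ] <- zc[k] >= b & zc[k] < c
  out
}

#' Choroidal vascularity index
#'
#' Per A-scan, the fraction of choroidal-slab voxels classified as vessel
#' (\code{cvi_map}; \code{NA} where the slab is empty); the scalar CVI is
#' the ratio of total vessel voxels to total slab voxels over the A-scans
#' inside the fovea-centered circle, i.e. the slab-voxel-weighted mean of
#' the map.
#'
#' @param vessel logical voxel array from
#'   \code{\link{segmentChoroidVessels}} (carrying its \code{slab}
#'   attribute, or supply \code{slab}).
#' @param grid the \linkS4class{ScanGrid}.
#' @param slab optional logical slab-membership array.
#' @param diameterMm analysis circle diameter (default 5).
#' @return list(cvi_map = \linkS4class{EnFaceImage}-like matrix with NAs,
#'   cvi).
#' @export
cviMetrics <- function(vessel, grid, slab = attr(vessel, "slab"), diameterMm = 5) {
  if (is.null(slab)) stop("slab membership array required")
  nslab <- colSums(slab)                 # (ny, nx)
  nves <- colSums(vessel & slab)
  cviMap <- ifelse(nslab > 0, nves / nslab, NA_real_)
  circ <- .checkedCircle(grid, diameterMm)
  tot <- sum(nslab[circ])
  if (tot == 0) stop("empty slab within the analysis circle")
  list(cvi_map = cviMap, cvi = sum(nves[circ]) / tot)
}
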