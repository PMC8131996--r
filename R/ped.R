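## PED height-map volumetry between the RPE and Bruch's membrane surfaces,
## MNV-masked PED metrics, and variance-stabilizing transforms.

#' PED height map from RPE and BM surfaces
#'
#' Elevation of the RPE above Bruch's membrane at every (x, y):
#' \code{height = max(0, bm_z - rpe_z)} um (z grows posteriorly, so an RPE
#' anterior to BM has smaller z and positive elevation). Negative values
#' (RPE posterior to BM, segmentation jitter) are floored at zero.
#'
#' @param rpe,bm \linkS4class{Surface} objects on the same grid.
#' @return An \linkS4class{EnFaceImage} of heights (um).
#' @export
pedHeightMap <- function(rpe, bm) {
  if (!identical(dim(zUm(rpe)), dim(zUm(bm)))) stop("rpe/bm grid mismatch")
  EnFaceImage(pmax(zUm(bm) - zUm(rpe), 0), scanGrid(bm))
}

#' PED area and volume from a height map
#'
#' Area counts pixels with elevation above \code{minHeightUm} (default 0:
#' any positive elevation) times the pixel area; volume integrates the
#' height over those pixels. Conversions um -> mm are exact
#' (\code{1 mm^3 = 1e9 um^3}).
#'
#' @param heights height-map \linkS4class{EnFaceImage} (um).
#' @param minHeightUm elevation floor for the area/volume support
#'   (default 0).
#' @return list(area_mm2, volume_mm3).
#' @export
pedMetrics <- function(heights, minHeightUm = 0) {
  g <- scanGrid(heights); h <- pixels(heights)
  if (minHeightUm < 0) stop("minHeightUm must be >= 0")
  sel <- h > minHeightUm
  pxUm2 <- g@pitchX * g@pitchY
  list(area_mm2 = sum(sel) * pxUm2 / 1e6,
       volume_mm3 = sum(h[sel]) * pxUm2 / 1e9)
}

#' MNV-specific PED metrics
#'
#' Restricts the height map to the MNV footprint before integrating, so
#' drusen elevations outside the lesion are excluded; this isolates the
#' MNV-PED area and volume.
#'
#' @param heights height-map \linkS4class{EnFaceImage} (um).
#' @param mnvMask MNV \linkS4class{BinaryMask} on the same grid.
#' @param minHeightUm elevation floor (default 0).
#' @return list(area_mm2, volume_mm3).
#' @export
mnvPedMetrics <- function(heights, mnvMask, minHeightUm = 0) {
  if (!all(dim(pixels(heights)) == dim(pixels(mnvMask)))) stop("grid mismatch")
  h <- pixels(heights) * pixels(mnvMask)
  pedMetrics(EnFaceImage(h, scanGrid(heights)), minHeightUm)
}

#' Variance-stabilizing transforms for lesion size
#'
#' Square-root of areas and cube-root of volumes remove the dependence of
#' test-retest variability on lesion size.
#'
#' @param areaMm2 area, mm^2 (>= 0).
#' @param volumeMm3 volume, mm^3 (>= 0).
#' @return list(sqrt_area_mm, cubert_volume_mm).
#' @export
stabilizeMetrics <- function(areaMm2, volumeMm3) {
  if (any(areaMm2 < 0) || any(volumeMm3 < 0)) stop("inputs must be non-negative")
  list(sqrt_area_mm = sqrt(areaMm2), cubert_volume_mm = volumeMm3^(1 / 3))
}
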