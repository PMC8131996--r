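## MNV lesion segmentation from the ORCC en face flow image, lesion area /
## growth metrics, eligibility gates, and focus counting.

#' Segment the MNV lesion from an ORCC en face flow image
#'
#' Transparent threshold-and-clean segmentation of angiographic flow in the
#' outer retina-to-CC slab: background statistics are estimated from pixels
#' farther than \code{backgroundBufferUm} from a provisional (Otsu) lesion,
#' the image is thresholded at background mean + k SD, closed with a small
#' disc, hole-filled, and components below \code{minComponentMm2} are
#' dropped. Deterministic.
#'
#' @param orccEnface artifact-removed ORCC flow \linkS4class{EnFaceImage}.
#' @param k threshold multiplier on the background SD (default 2).
#' @param closeRadiusPx radius of the morphological closing disc (default 2).
#' @param minComponentMm2 minimum surviving component area (default 0.01).
#' @param backgroundBufferUm exclusion buffer around the provisional lesion
#'   when estimating background statistics (default 600).
#' @return A \linkS4class{BinaryMask} (empty, with a warning, if nothing
#'   survives).
#' @export
segmentMNV <- function(orccEnface, k = 2, closeRadiusPx = 2,
                       minComponentMm2 = 0.01, backgroundBufferUm = 600) {
  g <- scanGrid(orccEnface); img <- pixels(orccEnface)
  if (diff(range(img)) == 0) {
    return(BinaryMask(matrix(FALSE, g@ny, g@nx), g, "segmentMNV"))
  }
  prov <- img > otsuThreshold(as.vector(img))
  bg <- if (any(prov)) edtUm(prov, g@pitchX, g@pitchY) > backgroundBufferUm
        else matrix(TRUE, g@ny, g@nx)
  if (sum(bg) < 100) bg <- !prov       # tiny background: fall back
  mu <- mean(img[bg]); sdev <- stats::sd(img[bg])
  if (is.na(sdev)) sdev <- 0
  m <- img > mu + k * sdev
  if (any(m)) {
    brush <- EBImage::makeBrush(2L * closeRadiusPx + 1L, shape = "disc")
    m <- as.matrix(EBImage::closing(m, brush)) > 0
    m <- as.matrix(EBImage::fillHull(m)) > 0
    lab <- label8(m)
    if (max(lab) > 0) {
      keep <- which(componentSizes(lab) * pixelAreaMM2(g) >= minComponentMm2)
      m <- matrix(lab %in% keep, g@ny, g@nx)
    }
  }
  if (!any(m)) warning("segmentMNV: empty segmentation")
  BinaryMask(m, g, "segmentMNV")
}

#' Lesion area metrics
#'
#' Area as pixel count times pixel area, its square-root transform
#' (variance-stabilizing for growth analysis), and the greatest linear
#' dimension (GLD) as the maximum pairwise distance between lesion boundary
#' pixel centers (um).
#'
#' @param mask lesion \linkS4class{BinaryMask}.
#' @return list(area_mm2, sqrt_area_mm, gld_um); \code{gld_um} is \code{NA}
#'   for an empty mask.
#' @export
lesionMetrics <- function(mask) {
  g <- scanGrid(mask); m <- pixels(mask)
  area <- sum(m) * pixelAreaMM2(g)
  gld <- if (!any(m)) NA_real_ else maxBoundaryDistanceUm(m, g)
  list(area_mm2 = area, sqrt_area_mm = sqrt(area), gld_um = gld)
}

# Greatest pairwise distance (um) between boundary pixel centers, via the
# convex hull of the boundary point set.
maxBoundaryDistanceUm <- function(m, g) {
  b <- boundaryPixels(m)
  pts <- which(b, arr.ind = TRUE)
  xy <- cbind((pts[, 2] - 0.5) * g@pitchX, (pts[, 1] - 0.5) * g@pitchY)
  if (nrow(xy) == 1L) return(0)
  h <- grDevices::chull(xy)
  hx <- xy[h, , drop = FALSE]
  d2 <- outer(hx[, 1], hx[, 1], "-")^2 + outer(hx[, 2], hx[, 2], "-")^2
  sqrt(max(d2))
}

# Mask pixels with at least one non-mask 4-neighbor (or on the image edge).
boundaryPixels <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L); pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  inner <- pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
           pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  m & !inner
}

#' Lesion eligibility gates
#'
#' A lesion is ineligible if its greatest linear dimension is below 250 um,
#' its area is below 0.2 mm^2, or it touches the scan border (lesions must
#' be fully contained in the 6 x 6-mm scan for reproducible measurement).
#'
#' @param mask lesion \linkS4class{BinaryMask} on a 6 x 6-mm grid.
#' @param minGldUm,minAreaMm2 gate thresholds (defaults 250 um, 0.2 mm^2).
#' @return list(eligible = logical, reasons = character vector).
#' @export
lesionEligibility <- function(mask, minGldUm = 250, minAreaMm2 = 0.2) {
  m <- pixels(mask)
  met <- lesionMetrics(mask)
  reasons <- character()
  if (!any(m)) reasons <- c(reasons, "empty_mask")
  else {
    if (met$gld_um < minGldUm) reasons <- c(reasons, sprintf("gld<%gum", minGldUm))
    if (met$area_mm2 < minAreaMm2) reasons <- c(reasons, sprintf("area<%gmm2", minAreaMm2))
    if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
      reasons <- c(reasons, "touches_border")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Count discrete MNV foci
#'
#' 8-connected components whose boundary-to-boundary separation is below
#' \code{minSeparationUm} are merged into a single focus (lesions count as
#' discrete only when separated by at least 600 um, i.e. non-overlapping
#' 300-um rims).
#'
#' @param mask lesion \linkS4class{BinaryMask}.
#' @param minSeparationUm merge distance (default 600).
#' @return Integer number of merged foci (0 for an empty mask).
#' @export
countFoci <- function(mask, minSeparationUm = 600) {
  g <- scanGrid(mask); m <- pixels(mask)
  lab <- label8(m)
  n <- max(lab)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  pts <- lapply(seq_len(n), function(i) {
    w <- which(lab == i & boundaryPixels(m), arr.ind = TRUE)
    cbind((w[, 2] - 0.5) * g@pitchX, (w[, 1] - 0.5) * g@pitchY)
  })
  adj <- diag(TRUE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d2 <- outer(pts[[i]][, 1], pts[[j]][, 1], "-")^2 +
          outer(pts[[i]][, 2], pts[[j]][, 2], "-")^2
    if (min(d2) < minSeparationUm^2) adj[i, j] <- adj[j, i] <- TRUE
  }
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(gph)$no)
}

#' Lesion enlargement rate
#'
#' Monthly growth rate between two visits on the raw (mm^2/month) and
#' square-root (mm/month) area scales; one month is fixed at 30.44 days
#' (365.25 / 12).
#'
#' @param area1Mm2,area2Mm2 lesion area at visit 1 / visit 2, mm^2.
#' @param days inter-visit interval in days (> 0).
#' @param monthDays days per month (default 30.44).
#' @return list(rate_mm2_per_month, sqrt_rate_mm_per_month).
#' @export
enlargementRate <- function(area1Mm2, area2Mm2, days, monthDays = 30.44) {
  if (any(days <= 0)) stop("days must be > 0")
  months <- days / monthDays
  list(rate_mm2_per_month = (area2Mm2 - area1Mm2) / months,
       sqrt_rate_mm_per_month = (sqrt(area2Mm2) - sqrt(area1Mm2)) / months)
}
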