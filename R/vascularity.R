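## Binary vessel map, skeleton, and VAD/VSD ratios inside the MNV mask.

#' Mask the ORCC flow image to the lesion
#'
#' Elementwise product of the en face flow image with the MNV binary mask:
#' removes the noise surrounding the lesion before vessel extraction.
#' Outside-lesion pixels are exactly zero.
#'
#' @param orccEnface ORCC flow \linkS4class{EnFaceImage}.
#' @param mnvMask MNV \linkS4class{BinaryMask} on the same grid.
#' @return Masked \linkS4class{EnFaceImage}.
#' @export
maskLesionFlow <- function(orccEnface, mnvMask) {
  if (!all(dim(pixels(orccEnface)) == dim(pixels(mnvMask)))) stop("grid mismatch")
  EnFaceImage(pixels(orccEnface) * pixels(mnvMask), scanGrid(orccEnface))
}

# Multiscale Hessian tubularity (Frangi-style, bright vessels on dark
# background): max response over Gaussian scales.
vesselnessResponse <- function(img, scalesPx = c(1, 2, 3), beta = 0.5, cFrac = 0.5) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scalesPx) {
    sm <- gaussianSmooth(img, s)
    # second differences, scale-normalized (gamma = 2)
    shift <- function(m, dy, dx) {
      ny <- nrow(m); nx <- ncol(m)
      yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      m[yi, xi]
    }
    dyy <- shift(sm, 1, 0) + shift(sm, -1, 0) - 2 * sm
    dxx <- shift(sm, 0, 1) + shift(sm, 0, -1) - 2 * sm
    dxy <- (shift(sm, 1, 1) + shift(sm, -1, -1) - shift(sm, 1, -1) - shift(sm, -1, 1)) / 4
    dyy <- dyy * s^2; dxx <- dxx * s^2; dxy <- dxy * s^2
    tmp <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
    l1 <- (dxx + dyy + tmp) / 2
    l2 <- (dxx + dyy - tmp) / 2
    # order by |lambda|: lam1 = smaller magnitude, lam2 = larger
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1); lam2 <- ifelse(swap, l1, l2)
    S <- sqrt(lam1^2 + lam2^2)
    c2 <- (cFrac * max(S))^2
    if (c2 == 0) next
    rb2 <- (lam1 / pmin(lam2, -1e-12))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * c2)))
    v[lam2 >= 0] <- 0                 # bright tubes need lambda2 < 0
    best <- pmax(best, v)
  }
  best
}

#' Extract a binary vessel map inside the lesion
#'
#' Combined Hessian-filter + adaptive-threshold detector: the multiscale
#' Hessian tubularity response captures thin vessels, a local-mean adaptive
#' threshold captures large trunks; the default combination is the union of
#' the two detections (intersection available), restricted to the MNV mask
#' and despeckled.
#'
#' @param maskedFlow \linkS4class{EnFaceImage} from
#'   \code{\link{maskLesionFlow}} (zero outside the lesion).
#' @param mnvMask MNV \linkS4class{BinaryMask}.
#' @param scalesPx Hessian scales in pixels (default c(1, 2, 3)).
#' @param windowPx adaptive-threshold window (odd, default 33; auto-shrunk
#'   with a warning if larger than the lesion bounding box).
#' @param offset adaptive-threshold offset subtracted from the local mean,
#'   as a fraction of the in-lesion dynamic range. The default (-0.1) is
#'   negative, i.e. the threshold sits slightly above the local mean, so
#'   locally flat avascular regions are rejected.
#' @param vesselnessCut threshold on the tubularity response, as a fraction
#'   of its maximum (default 0.25).
#' @param combine "union" or "intersection" of the two detectors.
#' @param minComponentPx despeckle size (default 3 px).
#' @return Vessel \linkS4class{BinaryMask} (subset of \code{mnvMask}).
#' @export
binarizeVessels <- function(maskedFlow, mnvMask, scalesPx = c(1, 2, 3),
                            windowPx = 33L, offset = -0.1, vesselnessCut = 0.25,
                            combine = c("union", "intersection"),
                            minComponentPx = 3L) {
  combine <- match.arg(combine)
  g <- scanGrid(maskedFlow); img <- pixels(maskedFlow); m <- pixels(mnvMask)
  if (any(img[!m] != 0)) stop("masked flow must be zero outside the lesion")
  if (!any(m) || all(img == 0))
    return(BinaryMask(matrix(FALSE, g@ny, g@nx), g, "binarizeVessels"))
  bb <- range(which(m, arr.ind = TRUE)[, 1])
  bbx <- range(which(m, arr.ind = TRUE)[, 2])
  maxWin <- min(diff(bb), diff(bbx)) + 1L
  if (windowPx > maxWin) {
    warning("adaptive window larger than lesion bounding box; shrinking")
    windowPx <- max(3L, maxWin - (1L - maxWin %% 2L))
  }
  vr <- vesselnessResponse(img, scalesPx)
  hess <- vr > vesselnessCut * max(vr)
  rng <- diff(range(img[m]))
  adap <- img > localMean(img, windowPx) - offset * rng
  vm <- if (combine == "union") (hess | adap) else (hess & adap)
  vm <- vm & m
  if (any(vm) && minComponentPx > 1L) {
    lab <- label8(vm)
    keep <- which(componentSizes(lab) >= minComponentPx)
    vm <- matrix(lab %in% keep, g@ny, g@nx)
  }
  BinaryMask(vm, g, "binarizeVessels")
}

#' Skeletonize a binary vessel map
#'
#' Topology-preserving thinning (Guo-Hall) to 8-connected single-pixel
#' centerlines: every vessel, regardless of caliber, contributes a 1-px
#' line. The skeleton is a subset of the input map.
#'
#' @param binary vessel \linkS4class{BinaryMask}.
#' @return Skeleton \linkS4class{BinaryMask}.
#' @export
skeletonizeVessels <- function(binary) {
  BinaryMask(thinMask(pixels(binary)), scanGrid(binary), "skeleton")
}

#' Vessel area density and vessel skeleton density
#'
#' VAD = vessel pixels / MNV pixels; VSD = skeleton pixels / MNV pixels.
#' Unitless pixel-count ratios with the lesion area as denominator.
#'
#' @param binary vessel \linkS4class{BinaryMask}.
#' @param skeleton skeleton \linkS4class{BinaryMask}.
#' @param mnvMask MNV \linkS4class{BinaryMask} (non-empty).
#' @return list(vad, vsd).
#' @export
vascularDensity <- function(binary, skeleton, mnvMask) {
  n <- sum(pixels(mnvMask))
  if (n == 0L) stop("empty MNV mask")
  list(vad = sum(pixels(binary)) / n, vsd = sum(pixels(skeleton)) / n)
}
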