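## Slab extraction and en face conditioning: surface-following projection,
## retinal projection-artifact removal, structural compensation of CC flow.

#' Define a depth slab between layer surfaces
#'
#' A slab is bounded above by a named surface plus an offset and below
#' either by another surface plus offset or by a fixed thickness. Named
#' presets carry the study's slab geometry: \code{"orcc"} runs from the
#' outer retinal boundary down to the innermost choriocapillaris (resolved
#' as Bruch's membrane + 4 um, so it abuts the CC slab with no gap), and
#' \code{"cc_16um"} is the 16-um-thick choriocapillaris slab whose anterior
#' boundary sits 4 um beneath Bruch's membrane.
#'
#' @param topSurface,topOffsetUm anterior boundary: surface name + um offset.
#' @param bottomSurface,bottomOffsetUm posterior boundary surface + offset
#'   (ignored when \code{thicknessUm} given).
#' @param thicknessUm fixed slab thickness below the top boundary, um.
#' @param projection "mean" or "max" axial projection.
#' @return A \code{SlabDefinition} (classed list).
#' @examples
#' slabPreset("cc_16um")
#' @export
slabDefinition <- function(topSurface, topOffsetUm = 0,
                           bottomSurface = NULL, bottomOffsetUm = 0,
                           thicknessUm = NULL,
                           projection = c("mean", "max")) {
  projection <- match.arg(projection)
  if (is.null(bottomSurface) && is.null(thicknessUm))
    stop("either bottomSurface or thicknessUm must be given")
  structure(list(topSurface = topSurface, topOffsetUm = topOffsetUm,
                 bottomSurface = bottomSurface, bottomOffsetUm = bottomOffsetUm,
                 thicknessUm = thicknessUm, projection = projection),
            class = "SlabDefinition")
}

#' @param name preset name: "orcc" or "cc_16um".
#' @rdname slabDefinition
#' @export
slabPreset <- function(name = c("orcc", "cc_16um")) {
  switch(match.arg(name),
    orcc = slabDefinition("outer_retina", 0, "bm", 4),
    cc_16um = slabDefinition("bm", 4, thicknessUm = 16))
}

#' Extract an en face projection of a depth slab
#'
#' Projects voxels with z in [top, bottom) per (x, y). Sub-voxel boundary
#' positions are honoured: for the mean projection the axial profile is
#' treated as piecewise constant over voxel planes and integrated exactly
#' over the slab, so fractional plane overlaps get fractional weight; the
#' max projection uses every plane overlapping the slab.
#'
#' @param volume an \linkS4class{OctVolume} or \linkS4class{FlowVolume}.
#' @param surfaces named list of \linkS4class{Surface} objects (names as in
#'   \linkS4class{Surface}).
#' @param slab a \code{\link{slabDefinition}}.
#' @param maxClippedFraction error if more than this fraction of A-scans has
#'   a slab extending outside the volume (default 0.01).
#' @return An \linkS4class{EnFaceImage}; attribute \code{clippedFraction}
#'   reports the fraction of clipped A-scans.
#' @export
extractEnface <- function(volume, surfaces, slab, maxClippedFraction = 0.01) {
  g <- scanGrid(volume); v <- voxels(volume)
  nz <- dim(v)[1]; p <- g@pitchZ
  getS <- function(nm) {
    if (is.null(surfaces[[nm]])) stop("required surface missing: ", nm)
    s <- surfaces[[nm]]
    if (!isTRUE(all.equal(dim(zUm(s)), c(g@ny, g@nx)))) stop("surface grid mismatch: ", nm)
    zUm(s)
  }
  top <- getS(slab$topSurface) + slab$topOffsetUm
  bot <- if (!is.null(slab$thicknessUm)) top + slab$thicknessUm
         else getS(slab$bottomSurface) + slab$bottomOffsetUm
  if (any(bot <= top)) stop("slab bottom must be posterior to top everywhere")
  zmax <- nz * p
  clipped <- top < 0 | bot > zmax
  cf <- mean(clipped)
  if (cf > maxClippedFraction)
    stop(sprintf("slab exits volume for %.1f%% of A-scans (limit %.1f%%)",
                 100 * cf, 100 * maxClippedFraction))
  top <- pmin(pmax(top, 0), zmax)
  bot <- pmin(pmax(bot, 0), zmax)
  bot <- pmax(bot, top + 1e-9)
  npx <- g@ny * g@nx
  vm <- matrix(aperm(v, c(2, 3, 1)), nrow = npx)   # (pixel, z)
  if (slab$projection == "mean") {
    cumm <- vm
    if (nz > 1) for (k in 2:nz) cumm[, k] <- cumm[, k] + cumm[, k - 1L]
    cum <- cbind(0, cumm * p)                      # integral at plane bounds
    intAt <- function(z) {
      k <- pmin(pmax(floor(z / p), 0), nz)
      frac <- z - k * p
      base <- cum[cbind(seq_len(npx), k + 1L)]
      inner <- k < nz
      add <- numeric(npx)
      add[inner] <- vm[cbind(which(inner), k[inner] + 1L)] * frac[inner]
      base + add
    }
    val <- (intAt(as.vector(bot)) - intAt(as.vector(top))) / (as.vector(bot) - as.vector(top))
  } else {
    tv <- as.vector(top); bv <- as.vector(bot)
    val <- rep(-Inf, npx)
    for (k in seq_len(nz)) {
      lo <- (k - 1) * p; hi <- k * p
      sel <- tv < hi & bv > lo
      if (any(sel)) val[sel] <- pmax(val[sel], vm[sel, k])
    }
    val[!is.finite(val)] <- 0
  }
  out <- matrix(val, g@ny, g@nx)
  img <- EnFaceImage(out, g)
  attr(img, "clippedFraction") <- cf
  img
}

#' Remove retinal-vessel projection artifacts from an en face image
#'
#' Pixels under the retinal-vessel mask are replaced by inpainting from the
#' surrounding unmasked pixels: an initial iterative mean fill from the ring
#' of available neighbors, then Jacobi relaxation (discrete Laplace
#' interpolation over the masked region) until convergence. Unmasked pixels
#' are untouched, and the operation is idempotent on its own output.
#'
#' @param enface an \linkS4class{EnFaceImage}.
#' @param vesselMask a \linkS4class{BinaryMask} of retinal vessels on the
#'   same grid.
#' @param tol relative convergence tolerance (default 1e-9).
#' @param maxIter relaxation iteration cap.
#' @return The artifact-removed \linkS4class{EnFaceImage}.
#' @export
removeProjectionArtifacts <- function(enface, vesselMask, tol = 1e-9, maxIter = 10000L) {
  m <- pixels(vesselMask)
  if (!all(dim(m) == dim(pixels(enface)))) stop("mask grid mismatch")
  if (mean(m) > 0.5) stop("vessel mask covers more than 50% of the image")
  if (!any(m)) return(enface)
  z <- pixels(enface)
  scale <- diff(range(z[!m]))
  if (scale == 0) scale <- max(abs(z[!m]), 1)
  z <- fillHoles(z, m)
  idx <- which(m)
  for (it in seq_len(maxIter)) {
    zp <- rbind(NA, cbind(NA, z, NA), NA)
    acc <- matrix(0, nrow(z), ncol(z)); cnt <- matrix(0, nrow(z), ncol(z))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- zp[(2 + dy):(nrow(z) + 1 + dy), (2 + dx):(ncol(z) + 1 + dx)]
      okn <- !is.na(nb)
      acc[okn] <- acc[okn] + nb[okn]
      cnt <- cnt + okn
    }
    newv <- acc[idx] / cnt[idx]
    delta <- max(abs(newv - z[idx]))
    z[idx] <- newv
    if (delta <= tol * scale) break
  }
  EnFaceImage(z, scanGrid(enface))
}

#' Compensate CC flow for signal loss under overlying anatomy
#'
#' Divides the flow image by a smoothed, floored version of the
#' corresponding structural en face slab, so regions shadowed by overlying
#' tissue (visible as low structural signal) are boosted proportionally:
#' \code{out = flow * mean(S) / S_smoothed}, rescaled to preserve the global
#' mean flow. Scale-equivariant in the structure image.
#'
#' @param ccFlow flow \linkS4class{EnFaceImage}.
#' @param ccStructure structural \linkS4class{EnFaceImage}, same grid.
#' @param sigmaPx Gaussian smoothing sigma for the structure image (default
#'   3 px).
#' @param floorQuantile structure values are floored at this quantile
#'   (default 0.01) so near-zero structure cannot blow up the ratio.
#' @return Compensated flow \linkS4class{EnFaceImage}.
#' @export
compensateCC <- function(ccFlow, ccStructure, sigmaPx = 3, floorQuantile = 0.01) {
  f <- pixels(ccFlow); s <- pixels(ccStructure)
  if (!all(dim(f) == dim(s))) stop("flow/structure grid mismatch")
  if (all(s == 0)) stop("structure image is all zero")
  fl <- stats::quantile(s[s > 0], floorQuantile)
  s <- pmax(s, fl)
  ssm <- gaussianSmooth(s, sigmaPx)
  ssm <- pmax(ssm, fl)
  out <- f * (mean(s) / ssm)
  mo <- mean(out)
  if (mo > 0) out <- out * (mean(f) / mo)
  EnFaceImage(out, scanGrid(ccFlow))
}
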