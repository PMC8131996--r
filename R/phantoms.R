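## Seeded synthetic phantoms with known ground truth for every pipeline
## input: lesions with flow vasculature, CC slabs with inserted deficits,
## RPE elevations of analytic volume, choroid slabs of known vessel
## fraction, and two-group visit-pair cohorts. Ground truths come from
## constructions or brute-force counting, never from the measurement code.

#' Lesion phantom: ORCC-band flow volume with a vessel tree
#'
#' A disk lesion containing a random branching vessel tree (L-system-like
#' polylines rasterized at a given stroke width). Flow signal is high on
#' vessels, low elsewhere inside the lesion, background outside, with
#' optional additive Gaussian noise (clipped at 0). The en face truth masks
#' are produced by direct rasterization, independent of the measurement
#' modules.
#'
#' @param grid a \linkS4class{ScanGrid} with finite pitchZ (any small nz
#'   band works; the flow is constant along z).
#' @param centerXY lesion center, pixel coordinates (default fovea).
#' @param radiusUm lesion disk radius, um (0 or NULL = no lesion; must be
#'   >= 2 pixels otherwise).
#' @param nBranches number of primary vessel branches (default 10).
#' @param branchWidthPx vessel stroke width in pixels (default 3).
#' @param tortuosity direction-diffusion SD per step, radians (default 0.15; steps are 4 px, so curvature stays resolved at the pixel scale).
#' @param vesselLevel,lesionLevel,backgroundLevel flow levels (defaults 1,
#'   0.1, 0.05).
#' @param noiseSd additive Gaussian noise SD (default 0).
#' @param nz axial planes in the band (default 4).
#' @param seed integer seed; fixed seed gives identical output.
#' @return list(flow = \linkS4class{FlowVolume}, truthMNV, truthVessels,
#'   truthCenterlines = \linkS4class{BinaryMask}s); the centerlines are the
#'   width-1 rasterized branch polylines (true skeleton length).
#' @export
makeLesionPhantom <- function(grid, centerXY = grid@foveaXY, radiusUm = 1000,
                              nBranches = 10, branchWidthPx = 3,
                              tortuosity = 0.15, vesselLevel = 1,
                              lesionLevel = 0.1, backgroundLevel = 0.05,
                              noiseSd = 0, nz = 4, seed = NULL) {
  empty <- is.null(radiusUm) || radiusUm <= 0
  if (!empty && radiusUm < 2 * min(grid@pitchX, grid@pitchY))
    stop("lesion radius below 2 pixels")
  if (is.na(grid@pitchZ))   # band needs an axial pitch; 4 um is the CC-slab scale
    grid <- ScanGrid(grid@nx, grid@ny, grid@pitchX, grid@pitchY, 4, grid@foveaXY)
  withSeed(seed, {
    if (empty) {
      mnv <- matrix(FALSE, grid@ny, grid@nx)
      ves <- mnv; cl <- mnv
    } else {
      mnv <- diskMask(grid, centerXY, radiusUm)
      ves <- matrix(FALSE, grid@ny, grid@nx)
      cl <- matrix(FALSE, grid@ny, grid@nx)
      rPx <- radiusUm / mean(c(grid@pitchX, grid@pitchY))
      # radial spokes with mean-reverting direction: branches spread apart
      # instead of co-running, so the union of width-1 centerlines is the
      # skeleton-length ground truth of the rasterized map
      walk <- function(start, baseAng, nStep) {
        ang <- baseAng
        pos <- start
        pts <- matrix(pos, 1, 2)
        for (st in seq_len(nStep)) {
          ang <- ang + stats::rnorm(1, 0, tortuosity) - 0.3 * (ang - baseAng)
          pos <- pos + 4 * c(cos(ang), sin(ang))
          pts <- rbind(pts, pos)
          dUm <- sqrt(sum(((pos - centerXY) * c(grid@pitchX, grid@pitchY))^2))
          if (dUm > radiusUm - branchWidthPx * grid@pitchX) break
        }
        pts
      }
      # wide strokes get extended caps (half a width past each end) so the
      # tube's medial axis spans the full centerline, not a round-cap-short
      # version of it
      extend <- function(pts, ext) {
        if (nrow(pts) < 2L) return(pts)
        d1 <- pts[1, ] - pts[2, ]; d1 <- d1 / sqrt(sum(d1^2))
        d2 <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]; d2 <- d2 / sqrt(sum(d2^2))
        rbind(pts[1, ] + ext * d1, pts, pts[nrow(pts), ] + ext * d2)
      }
      cap <- branchWidthPx / 2
      nStep <- max(3L, ceiling(rPx / 4))
      for (b in seq_len(nBranches)) {
        base <- 2 * pi * (b - 1) / nBranches + stats::runif(1, -0.15, 0.15)
        pts <- walk(centerXY + 6 * c(cos(base), sin(base)), base, nStep)
        ves <- ves | rasterizePolyline(grid, extend(pts, cap), branchWidthPx)
        cl <- cl | rasterizePolyline(grid, pts, 1)
        if (nrow(pts) > 6 && stats::runif(1) < 0.5) {
          mid <- pts[ceiling(nrow(pts) / 2), ]
          side <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9)
          childAng <- base + side
          # step clear of the parent stroke so the child's centerline is
          # not double-covered at the junction
          pts2 <- walk(mid + 2 * c(cos(childAng), sin(childAng)), childAng,
                       ceiling(nStep / 2))
          ves <- ves | rasterizePolyline(grid, extend(pts2, cap), branchWidthPx)
          cl <- cl | rasterizePolyline(grid, pts2, 1)
        }
      }
      ves <- ves & mnv
      cl <- cl & mnv
    }
    en <- matrix(backgroundLevel, grid@ny, grid@nx)
    en[mnv] <- lesionLevel
    en[ves] <- vesselLevel
    if (noiseSd > 0) en <- pmax(en + matrix(stats::rnorm(length(en), 0, noiseSd),
                                            nrow(en), ncol(en)), 0)
    arr <- aperm(array(en, c(grid@ny, grid@nx, nz)), c(3, 1, 2))
    list(flow = FlowVolume(arr, grid, 10L),
         truthMNV = BinaryMask(mnv, grid, "phantom_truth"),
         truthVessels = BinaryMask(ves, grid, "phantom_truth"),
         truthCenterlines = BinaryMask(cl, grid, "phantom_truth"))
  })
}

#' CC phantom: en face flow/structure pair with inserted flow deficits
#'
#' Flow = (background - depth on deficit disks) x optional shading field,
#' with optional multiplicative speckle (clipped at 0); structure =
#' structure level x the same shading field, so structural compensation can
#' undo the shading. Truth FD mask is the union of the rasterized disks.
#'
#' @param grid a \linkS4class{ScanGrid}.
#' @param fdDisks data.frame(x, y, diameter_um) of deficit disks (pixel
#'   center coords); disks extending beyond the grid are an error.
#' @param background background flow level (default 0.8).
#' @param deficitDepth flow drop on deficits (default 0.6).
#' @param speckleSd multiplicative speckle SD (default 0).
#' @param shading optional (ny, nx) multiplier field (default uniform 1).
#' @param structureLevel structural slab level (default 1).
#' @param seed integer seed.
#' @return list(ccFlow, ccStructure = \linkS4class{EnFaceImage}, truthFD =
#'   \linkS4class{BinaryMask}).
#' @export
makeCcPhantom <- function(grid, fdDisks = NULL, background = 0.8,
                          deficitDepth = 0.6, speckleSd = 0, shading = NULL,
                          structureLevel = 1, seed = NULL) {
  withSeed(seed, {
    fd <- matrix(FALSE, grid@ny, grid@nx)
    if (!is.null(fdDisks) && nrow(fdDisks)) {
      for (i in seq_len(nrow(fdDisks))) {
        r <- fdDisks$diameter_um[i] / 2
        cx <- (fdDisks$x[i] - 0.5) * grid@pitchX
        cy <- (fdDisks$y[i] - 0.5) * grid@pitchY
        if (cx - r < 0 || cy - r < 0 || cx + r > grid@nx * grid@pitchX ||
            cy + r > grid@ny * grid@pitchY)
          stop("deficit disk ", i, " extends beyond the grid")
        fd <- fd | diskMask(grid, c(fdDisks$x[i], fdDisks$y[i]), r)
      }
    }
    if (is.null(shading)) shading <- matrix(1, grid@ny, grid@nx)
    flow <- (background - deficitDepth * fd) * shading
    if (speckleSd > 0)
      flow <- pmax(flow * (1 + matrix(stats::rnorm(length(flow), 0, speckleSd),
                                      nrow(flow), ncol(flow))), 0)
    list(ccFlow = EnFaceImage(flow, grid),
         ccStructure = EnFaceImage(structureLevel * shading, grid),
         truthFD = BinaryMask(fd, grid, "phantom_truth"))
  })
}

#' Sample pairwise-disjoint flow-deficit disks
#'
#' Rejection-samples disk centers/diameters so that disks are pairwise
#' separated by at least \code{minGapUm}, keep \code{marginUm} clear of the
#' grid border, and optionally avoid a mask (e.g. stay outside the lesion).
#'
#' @param grid a \linkS4class{ScanGrid}.
#' @param n number of disks.
#' @param diameterRangeUm min/max disk diameter, um (default c(30, 120)).
#' @param avoidMask optional \linkS4class{BinaryMask} the disks must not
#'   touch.
#' @param avoidBufferUm clearance around \code{avoidMask}, um (default 0).
#' @param marginUm clearance from the grid border (default 100).
#' @param minGapUm minimum edge-to-edge disk separation (default 24).
#' @param seed integer seed.
#' @return data.frame(x, y, diameter_um).
#' @export
sampleFdDisks <- function(grid, n, diameterRangeUm = c(30, 120),
                          avoidMask = NULL, avoidBufferUm = 0, marginUm = 100,
                          minGapUm = 24, seed = NULL) {
  withSeed(seed, {
    avoid <- if (is.null(avoidMask)) NULL
             else edtUm(pixels(avoidMask), grid@pitchX, grid@pitchY)
    out <- data.frame(x = numeric(0), y = numeric(0), diameter_um = numeric(0))
    tries <- 0L
    while (nrow(out) < n && tries < 20000L) {
      tries <- tries + 1L
      dUm <- stats::runif(1, diameterRangeUm[1], diameterRangeUm[2])
      r <- dUm / 2
      x <- stats::runif(1, (marginUm + r) / grid@pitchX + 0.5,
                        grid@nx - (marginUm + r) / grid@pitchX - 0.5)
      y <- stats::runif(1, (marginUm + r) / grid@pitchY + 0.5,
                        grid@ny - (marginUm + r) / grid@pitchY - 0.5)
      if (!is.null(avoid)) {
        d <- avoid[round(y), round(x)]
        if (is.infinite(d)) d <- .Machine$double.xmax
        if (d < r + avoidBufferUm) next
      }
      if (nrow(out)) {
        cc <- sqrt(((out$x - x) * grid@pitchX)^2 + ((out$y - y) * grid@pitchY)^2)
        if (any(cc < r + out$diameter_um / 2 + minGapUm)) next
      }
      out <- rbind(out, data.frame(x = x, y = y, diameter_um = dUm))
    }
    if (nrow(out) < n) stop("could not place ", n, " disjoint disks")
    out
  })
}

#' PED phantom: Gaussian RPE elevations over a flat Bruch's membrane
#'
#' BM is flat at \code{bmZUm}; the RPE is elevated anteriorly by a sum of
#' Gaussian bumps \code{h exp(-r^2 / (2 sigma^2))}. Each bump's analytic
#' volume is \code{2 pi sigma^2 h} (um^3), returned in mm^3 as ground
#' truth.
#'
#' @param grid a \linkS4class{ScanGrid}.
#' @param bumps data.frame(x, y, h_um, sigma_um), pixel-center coords.
#' @param bmZUm BM depth (default 300).
#' @return list(rpe, bm = \linkS4class{Surface}, truthVolumesMm3,
#'   truthTotalVolumeMm3).
#' @export
makePedPhantom <- function(grid, bumps = NULL, bmZUm = 300) {
  elev <- matrix(0, grid@ny, grid@nx)
  vols <- numeric(0)
  if (!is.null(bumps) && nrow(bumps)) {
    if (any(bumps$sigma_um < min(grid@pitchX, grid@pitchY)))
      stop("bump sigma below one pixel pitch")
    xs <- (seq_len(grid@nx) - 0.5) * grid@pitchX
    ys <- (seq_len(grid@ny) - 0.5) * grid@pitchY
    for (i in seq_len(nrow(bumps))) {
      cx <- (bumps$x[i] - 0.5) * grid@pitchX
      cy <- (bumps$y[i] - 0.5) * grid@pitchY
      r2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      elev <- elev + bumps$h_um[i] * exp(-r2 / (2 * bumps$sigma_um[i]^2))
      vols <- c(vols, 2 * pi * bumps$sigma_um[i]^2 * bumps$h_um[i] / 1e9)
    }
  }
  list(rpe = Surface("rpe", bmZUm - elev, grid),
       bm = Surface("bm", bmZUm, grid),
       truthVolumesMm3 = vols,
       truthTotalVolumeMm3 = sum(vols))
}

#' Choroid phantom: bright stroma, dark vessels, known MCT and CVI
#'
#' Builds a structural volume in which the choroidal slab (BM to CSI,
#' thickness field in um) takes a bright stroma value except inside vessel
#' structures, which are dark. Vessels are either whole voxel planes
#' ("planes": an exact fraction of each A-scan's slab, giving CVI = f by
#' construction) or random cylinders along x ("cylinders": truth CVI by
#' brute-force voxel counting of the construction). Truth MCT is the
#' brute-force mean of the thickness field inside the fovea-centered
#' circle.
#'
#' @param grid a \linkS4class{ScanGrid} with finite pitchZ.
#' @param thicknessUm scalar or (ny, nx) matrix choroid thickness field.
#' @param vesselFraction target vessel volume fraction f in [0, 0.95].
#' @param mode "planes" (exact f) or "cylinders".
#' @param nCylinders number of cylinders for mode "cylinders" (default 40).
#' @param bmZUm BM depth (default 40).
#' @param stromaLevel,vesselLevel tissue reflectivity (defaults 200, 50).
#' @param attenuation simulate Beer-Lambert depth attenuation
#'   (default TRUE): the recorded signal is reflectivity x
#'   exp(-2 integral of mu), with the attenuation coefficient mu
#'   proportional to reflectivity and an absorbing sclera below the CSI.
#'   Attenuation compensation inverts exactly this model, so the
#'   compensated slab returns to two clean tissue classes. FALSE gives the
#'   plain two-valued volume (for raw-intensity thresholding tests).
#' @param circleDiameterMm truth-MCT/CVI circle (default 5).
#' @param seed integer seed.
#' @return list(volume = \linkS4class{OctVolume}, bm, csi =
#'   \linkS4class{Surface}, truth = list(mct_um, cvi), vesselTruth =
#'   logical voxel array).
#' @export
makeChoroidPhantom <- function(grid, thicknessUm = 200, vesselFraction = 0.3,
                               mode = c("planes", "cylinders"), nCylinders = 40,
                               bmZUm = 40, stromaLevel = 200, vesselLevel = 50,
                               attenuation = TRUE, circleDiameterMm = 5,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (vesselFraction > 0.95) stop("vessel fraction above 0.95")
  th <- if (length(thicknessUm) == 1L) matrix(thicknessUm, grid@ny, grid@nx)
        else thicknessUm
  if (any(th <= 0)) stop("thickness field must be positive")
  withSeed(seed, {
    csiZ <- bmZUm + th
    scleraUm <- if (attenuation) 200 else 0   # absorbing backing layer
    nz <- ceiling((bmZUm + max(th) + scleraUm) / grid@pitchZ) + 2L
    zc <- (seq_len(nz) - 0.5) * grid@pitchZ
    slab <- array(FALSE, c(nz, grid@ny, grid@nx))
    for (k in seq_len(nz)) slab[k, , ] <- zc[k] >= bmZUm & zc[k] < csiZ
    vessel <- array(FALSE, c(nz, grid@ny, grid@nx))
    if (mode == "planes") {
      # bottom fraction f of each A-scan's slab voxels, rounded per A-scan
      nsl <- colSums(slab)
      nv <- round(vesselFraction * nsl)
      cum <- slab[nz:1, , , drop = FALSE] * 1L   # cumulative slab count from bottom
      if (nz > 1) for (k in 2:nz) cum[k, , ] <- cum[k, , ] + cum[k - 1L, , ]
      for (k in seq_len(nz))
        vessel[nz - k + 1L, , ] <- slab[nz - k + 1L, , ] & (cum[k, , ] <= nv)
    } else if (nCylinders > 0) {
      ys <- (seq_len(grid@ny) - 0.5) * grid@pitchY
      tmin <- min(th)
      for (i in seq_len(nCylinders)) {
        r <- stats::runif(1, 15, max(20, tmin / 4))
        cy <- stats::runif(1, r, grid@ny * grid@pitchY - r)
        cz <- stats::runif(1, bmZUm + r, bmZUm + tmin - r)
        dy2 <- (ys - cy)^2
        for (k in which(abs(zc - cz) <= r)) {
          hit <- dy2 <= r^2 - (zc[k] - cz)^2
          if (any(hit)) vessel[k, hit, ] <- TRUE
        }
      }
      vessel <- vessel & slab
    }
    refl <- array(stromaLevel * 0.25, c(nz, grid@ny, grid@nx))  # retina/sclera
    refl[slab] <- stromaLevel
    refl[vessel] <- vesselLevel
    if (attenuation) {
      # bright, strongly attenuating sclera soaks up the remaining signal
      below <- array(FALSE, dim(refl))
      for (k in seq_len(nz)) below[k, , ] <- zc[k] >= csiZ
      refl[below] <- stromaLevel * 2
      # mu proportional to reflectivity (0.01 / um for stroma), the coupling
      # the single-scatter compensation model inverts
      mu <- refl * (0.01 / stromaLevel)
      od <- mu * grid@pitchZ                 # optical depth per voxel
      cum <- od
      if (nz > 1) for (k in 2:nz) cum[k, , ] <- cum[k, , ] + cum[k - 1L, , ]
      vox <- refl * exp(-2 * (cum - od))     # attenuation above each voxel
    } else {
      vox <- refl
    }
    circ <- circleMask(grid, circleDiameterMm)
    circA <- aperm(array(circ, c(grid@ny, grid@nx, nz)), c(3, 1, 2))
    truthCvi <- if (sum(slab & circA) > 0) sum(vessel & slab & circA) / sum(slab & circA) else NA_real_
    list(volume = OctVolume(vox, grid, 10L),
         bm = Surface("bm", bmZUm, grid),
         csi = Surface("csi", csiZ, grid),
         truth = list(mct_um = mean(th[circ]), cvi = truthCvi),
         vesselTruth = vessel)
  })
}

#' Published cohort summary moments
#'
#' Visit-2 and rate-per-month group means/SDs (no-exudation n = 12,
#' exudation n = 9) for the eight reported biomarkers, as printed in the
#' study's summary table. Used to parameterize synthetic cohorts.
#'
#' @return data.frame(metric, group, n, mean_visit2, sd_visit2, mean_rate,
#'   sd_rate).
#' @export
referenceCohortMoments <- function() {
  rbind(
    data.frame(metric = "mnv_size_mm2", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(3.59, 2.09), sd_visit2 = c(2.89, 2.13),
               mean_rate = c(0.023, 0.038), sd_rate = c(0.102, 0.110)),
    data.frame(metric = "sqrt_mnv_size_mm", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(1.74, 1.28), sd_visit2 = c(0.79, 0.71),
               mean_rate = c(0.01, 0.01), sd_rate = c(0.03, 0.04)),
    data.frame(metric = "cc_r1_fd_pct", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(26.4, 27.2), sd_visit2 = c(14.1, 13.6),
               mean_rate = c(-0.6, 2.0), sd_rate = c(2.6, 3.5)),
    data.frame(metric = "vad", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(0.515, 0.390), sd_visit2 = c(0.054, 0.104),
               mean_rate = c(0.005, -0.006), sd_rate = c(0.014, 0.022)),
    data.frame(metric = "vsd", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(0.189, 0.149), sd_visit2 = c(0.024, 0.030),
               mean_rate = c(0.002, -0.003), sd_rate = c(0.003, 0.005)),
    data.frame(metric = "cubert_mnv_ped_volume_mm", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(0.403, 0.268), sd_visit2 = c(0.143, 0.133),
               mean_rate = c(0.008, 0.010), sd_rate = c(0.010, 0.019)),
    data.frame(metric = "mct_um", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(192.8, 244.7), sd_visit2 = c(83.9, 95.3),
               mean_rate = c(0.72, -1.64), sd_rate = c(3.19, 10.5)),
    data.frame(metric = "cvi", group = c("no_exudation", "exudation"), n = c(12L, 9L),
               mean_visit2 = c(0.614, 0.627), sd_visit2 = c(0.037, 0.042),
               mean_rate = c(-0.002, -0.001), sd_rate = c(0.006, 0.007))
  )
}

#' Synthetic two-group visit-pair cohort
#'
#' Draws, per eye and metric, the visit-2 value and the monthly rate from
#' the stated group distribution (normal, or a right-skewed shifted
#' lognormal standardized to the requested mean/SD), plus an inter-visit
#' interval (normal in months, floored at 0.5), and back-computes visit 1 =
#' visit 2 - rate x months. Deterministic under a fixed seed.
#'
#' @param moments data.frame as \code{\link{referenceCohortMoments}}.
#' @param nPerGroup named vector c(no_exudation = , exudation = ) overriding
#'   the \code{n} column (NULL = use the column).
#' @param distribution "normal" or "lognormal_shifted".
#' @param intervalMo named list of c(mean, sd) month intervals per group
#'   (defaults: no-exudation 3.6 +/- 2.1, exudation 2.7 +/- 1.7).
#' @param monthDays days per month (default 30.44).
#' @param seed integer seed.
#' @return data.frame: eye_id, group, days_between, and <metric>_v1/_v2
#'   columns.
#' @export
makeCohort <- function(moments = referenceCohortMoments(), nPerGroup = NULL,
                       distribution = c("normal", "lognormal_shifted"),
                       intervalMo = list(no_exudation = c(3.6, 2.1),
                                         exudation = c(2.7, 1.7)),
                       monthDays = 30.44, seed = NULL) {
  distribution <- match.arg(distribution)
  if (any(moments$sd_visit2 < 0) || any(moments$sd_rate < 0)) stop("SDs must be >= 0")
  rdraw <- function(n, m, s) {
    if (s == 0) return(rep(m, n))
    if (distribution == "normal") stats::rnorm(n, m, s)
    else {
      L <- stats::rlnorm(n, 0, 1)
      m + s * (L - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
    }
  }
  withSeed(seed, {
    out <- NULL
    for (gname in unique(moments$group)) {
      mg <- moments[moments$group == gname, ]
      n <- if (!is.null(nPerGroup)) nPerGroup[[gname]] else mg$n[1]
      if (n < 2) stop("need n >= 2 per group")
      iv <- intervalMo[[gname]]
      months <- pmax(0.5, stats::rnorm(n, iv[1], iv[2]))
      df <- data.frame(eye_id = paste0(substr(gname, 1, 2), seq_len(n)),
                       group = gname, days_between = months * monthDays)
      for (i in seq_len(nrow(mg))) {
        v2 <- rdraw(n, mg$mean_visit2[i], mg$sd_visit2[i])
        rate <- rdraw(n, mg$mean_rate[i], mg$sd_rate[i])
        df[[paste0(mg$metric[i], "_v2")]] <- v2
        df[[paste0(mg$metric[i], "_v1")]] <- v2 - rate * months
      }
      out <- rbind(out, df)
    }
    out
  })
}
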