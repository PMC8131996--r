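## Orchestration: study configuration, per-eye end-to-end quantification,
## visit-pair selection, and report tables.

#' Study configuration
#'
#' Collects every named analysis constant in one provenance-friendly
#' object: slab presets, segmentation thresholds, the 24-um flow-deficit
#' filter, the 300/600-um ring radii, the 5-mm analysis circle, the month
#' length, QC and statistics options. Serialize with
#' \code{\link{writeStudyConfig}} / \code{\link{readStudyConfig}} (YAML).
#'
#' @param ... overrides of the defaults (see the function body / YAML dump
#'   for the full key list).
#' @return A classed list (\code{StudyConfig}).
#' @export
studyConfig <- function(...) {
  cfg <- list(
    regionRadiiUm = c(300, 600),
    minFdDiameterUm = 24,
    ccSlabOffsetUm = 4,
    ccSlabThicknessUm = 16,
    circleDiameterMm = 5,
    monthDays = 30.44,
    minGldUm = 250,
    minAreaMm2 = 0.2,
    fociSeparationUm = 600,
    minSignalStrength = 7,
    segK = 2,
    segCloseRadiusPx = 2,
    segMinComponentMm2 = 0.01,
    fdStrategy = "mean_sd",
    fdK = 1,
    fdFixedThreshold = NULL,
    vesselScalesPx = c(1, 2, 3),
    vesselWindowPx = 33L,
    pedMinHeightUm = 0,
    bootB = 2000,
    alpha = 0.05,
    bufferDays = 183,
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(all(cfg$regionRadiiUm > 0), cfg$minFdDiameterUm >= 0,
            cfg$circleDiameterMm > 0, cfg$monthDays > 0)
  structure(cfg, class = "StudyConfig")
}

#' @param cfg a \code{StudyConfig}.
#' @param path YAML file path.
#' @rdname studyConfig
#' @export
writeStudyConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname studyConfig
#' @export
readStudyConfig <- function(path) {
  do.call(studyConfig, yaml::read_yaml(path))
}

# Stable short hash of the configuration for provenance stamps.
configHash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Quantify one eye at one visit, end to end
#'
#' Runs every enabled metric family over the supplied inputs: ORCC en face
#' conditioning and MNV segmentation, CC flow-deficit quantification in the
#' ring regions, intralesional VAD/VSD, PED volumetry, and choroidal
#' MCT/CVI. Families whose inputs are missing yield \code{NA} metrics, not
#' failure. Volumes failing the signal-strength gate are a hard QC error.
#'
#' @param inputs named list; recognized elements: \code{orccEnface}
#'   (\linkS4class{EnFaceImage}) or \code{orccVolume} + \code{surfaces}
#'   (named list with outer_retina and bm); \code{retinalVesselMask};
#'   \code{mnvMask} (precomputed mask bypasses segmentation);
#'   \code{ccFlowEnface}, \code{ccStructureEnface}; \code{rpe}, \code{bm}
#'   (6 x 6-mm surfaces); \code{choroid} = list(volume, bm, csi).
#' @param config a \code{\link{studyConfig}}.
#' @param eye_id,visit,visit_date record identifiers.
#' @return One-row metrics data.frame (see \code{\link{metricColumns}});
#'   attributes \code{flags} (eligibility etc.) and \code{provenance}.
#' @export
runEyeVisit <- function(inputs, config = studyConfig(), eye_id = "eye",
                        visit = 1L, visit_date = NA) {
  flags <- list()
  vals <- list()
  qcVols <- list(orccVolume = inputs$orccVolume, choroidVolume = inputs$choroid$volume)
  for (nm in names(qcVols)) {
    v <- qcVols[[nm]]
    if (!is.null(v) && !is.na(signalStrength(v)) &&
        signalStrength(v) < config$minSignalStrength)
      stop(sprintf("QC rejection (%s): signal strength %d below minimum %d",
                   nm, signalStrength(v), config$minSignalStrength))
  }
  orcc <- inputs$orccEnface
  if (is.null(orcc) && !is.null(inputs$orccVolume))
    orcc <- extractEnface(inputs$orccVolume, inputs$surfaces, slabPreset("orcc"))
  if (!is.null(orcc) && !is.null(inputs$retinalVesselMask))
    orcc <- removeProjectionArtifacts(orcc, inputs$retinalVesselMask)
  mnv <- inputs$mnvMask
  if (is.null(mnv) && !is.null(orcc))
    mnv <- segmentMNV(orcc, k = config$segK, closeRadiusPx = config$segCloseRadiusPx,
                      minComponentMm2 = config$segMinComponentMm2)
  if (!is.null(mnv)) {
    lm <- lesionMetrics(mnv)
    vals$mnv_area_mm2 <- lm$area_mm2
    vals$sqrt_mnv_area_mm <- lm$sqrt_area_mm
    flags$eligibility <- lesionEligibility(mnv, config$minGldUm, config$minAreaMm2)
    flags$n_foci <- countFoci(mnv, config$fociSeparationUm)
    flags$gld_um <- lm$gld_um
  }
  if (!is.null(inputs$ccFlowEnface) && !is.null(mnv)) {
    cc <- inputs$ccFlowEnface
    if (!is.null(inputs$ccStructureEnface))
      cc <- compensateCC(cc, inputs$ccStructureEnface)
    if (!is.null(inputs$retinalVesselMask))
      cc <- removeProjectionArtifacts(cc, inputs$retinalVesselMask)
    regions <- buildRegions(mnv, config$regionRadiiUm)
    fd <- segmentFlowDeficits(cc, strategy = config$fdStrategy, k = config$fdK,
                              threshold = config$fdFixedThreshold,
                              excludeMask = mnv,
                              minDiameterUm = config$minFdDiameterUm)
    met <- regionFdMetrics(fd, regions)
    pick <- function(r, col) met[met$region == r, col]
    vals$fd_pct_r1 <- pick("R1", "fd_pct")
    vals$fd_pct_r2 <- pick("R2", "fd_pct")
    vals$fd_pct_r3 <- pick("R3", "fd_pct")
    vals$fd_pct_excl_mnv <- pick("excl_mnv", "fd_pct")
    vals$mean_fd_area_um2_r1 <- pick("R1", "mean_fd_area_um2")
    vals$mean_fd_area_um2_r2 <- pick("R2", "mean_fd_area_um2")
    vals$mean_fd_area_um2_r3 <- pick("R3", "mean_fd_area_um2")
    vals$mean_fd_area_um2_excl_mnv <- pick("excl_mnv", "mean_fd_area_um2")
  }
  if (!is.null(orcc) && !is.null(mnv) && any(pixels(mnv))) {
    mf <- maskLesionFlow(orcc, mnv)
    vb <- binarizeVessels(mf, mnv, scalesPx = config$vesselScalesPx,
                          windowPx = config$vesselWindowPx)
    sk <- skeletonizeVessels(vb)
    vd <- vascularDensity(vb, sk, mnv)
    vals$vad <- vd$vad
    vals$vsd <- vd$vsd
  }
  if (!is.null(inputs$rpe) && !is.null(inputs$bm)) {
    hm <- pedHeightMap(inputs$rpe, inputs$bm)
    pm <- pedMetrics(hm, config$pedMinHeightUm)
    vals$ped_area_mm2 <- pm$area_mm2
    vals$ped_volume_mm3 <- pm$volume_mm3
    if (!is.null(mnv)) {
      mm <- mnvPedMetrics(hm, mnv, config$pedMinHeightUm)
      st <- stabilizeMetrics(mm$area_mm2, mm$volume_mm3)
      vals$mnv_ped_area_mm2 <- mm$area_mm2
      vals$mnv_ped_volume_mm3 <- mm$volume_mm3
      vals$sqrt_mnv_ped_area_mm <- st$sqrt_area_mm
      vals$cubert_mnv_ped_volume_mm <- st$cubert_volume_mm
    }
  }
  if (!is.null(inputs$choroid)) {
    ch <- inputs$choroid
    comp <- attenuationCompensate(ch$volume)
    ct <- choroidalThickness(ch$bm, ch$csi, config$circleDiameterMm)
    vals$mct_um <- ct$mct_um
    ves <- segmentChoroidVessels(comp, ch$bm, ch$csi)
    cv <- cviMetrics(ves, scanGrid(ch$volume), diameterMm = config$circleDiameterMm)
    vals$cvi <- cv$cvi
  }
  row <- do.call(eyeVisitMetrics,
                 c(list(eye_id = eye_id, visit = visit, visit_date = visit_date), vals))
  attr(row, "flags") <- flags
  attr(row, "provenance") <- list(config_hash = configHash(config),
                                  package_version = as.character(utils::packageVersion("octamnv")))
  row
}

#' Select the analysis visit pair per eye
#'
#' Eyes that progressed to exudation contribute the last two visits
#' strictly before the exudation date. Eyes that stayed dry contribute the
#' latest consecutive visit pair whose second visit precedes the last
#' follow-up by at least \code{bufferDays} (183 days = the 6-month buffer).
#' Eyes with no qualifying pair are excluded with a reason.
#'
#' @param visits data.frame: eye_id, visit_date (numeric days or Date),
#'   optional exudation_date (NA = never exudated), optional last_followup
#'   (default: the eye's latest visit).
#' @param bufferDays dry-eye buffer (default 183).
#' @return list(pairs = data.frame(eye_id, group, visit1_date, visit2_date),
#'   exclusions = data.frame(eye_id, reason)).
#' @export
selectVisitPairs <- function(visits, bufferDays = 183) {
  pairs <- NULL; excl <- NULL
  for (id in unique(visits$eye_id)) {
    v <- visits[visits$eye_id == id, ]
    dates <- sort(as.numeric(v$visit_date))
    ex <- if ("exudation_date" %in% names(v)) as.numeric(v$exudation_date[1]) else NA
    lf <- if ("last_followup" %in% names(v) && !all(is.na(v$last_followup)))
            as.numeric(v$last_followup[1]) else max(dates)
    if (!is.na(ex)) {
      pre <- dates[dates < ex]
      if (length(pre) < 2) {
        excl <- rbind(excl, data.frame(eye_id = id, reason = "exudation_without_two_prior_visits"))
        next
      }
      p <- utils::tail(pre, 2)
      pairs <- rbind(pairs, data.frame(eye_id = id, group = "exudation",
                                       visit1_date = p[1], visit2_date = p[2]))
    } else {
      if (length(dates) < 2) {
        excl <- rbind(excl, data.frame(eye_id = id, reason = "inadequate_follow_up"))
        next
      }
      ok <- which(lf - dates[-1] >= bufferDays)   # index of qualifying visit-2
      if (!length(ok)) {
        excl <- rbind(excl, data.frame(eye_id = id, reason = "no_pair_before_6_month_buffer"))
        next
      }
      i2 <- max(ok) + 1L
      pairs <- rbind(pairs, data.frame(eye_id = id, group = "no_exudation",
                                       visit1_date = dates[i2 - 1L], visit2_date = dates[i2]))
    }
  }
  list(pairs = pairs, exclusions = excl)
}

#' Cohort report: group summaries and confidence intervals
#'
#' From a wide visit-pair cohort table (columns \code{<metric>_v1},
#' \code{<metric>_v2}, \code{days_between}, \code{group}), computes per-eye
#' differences and monthly rates, group summaries (mean, SD, median, IQR)
#' for visit 1 / visit 2 / difference / rate, and 95\% CIs on the
#' between-group difference (no-exudation minus exudation) at visit 2 and
#' for the rate, choosing pooled-t or percentile bootstrap per metric by
#' Shapiro-Wilk gating.
#'
#' @param cohort wide data.frame (see \code{\link{makeCohort}}).
#' @param metrics character vector of metric stems (default: inferred from
#'   \code{_v2} columns).
#' @param config a \code{\link{studyConfig}} (bootstrap B, alpha, month
#'   length, seed).
#' @return list(summaries, ci, provenance); \code{ci} has one row per
#'   metric x (visit2, rate) with the method flag.
#' @export
buildReport <- function(cohort, metrics = NULL, config = studyConfig()) {
  if (is.null(metrics))
    metrics <- sub("_v2$", "", grep("_v2$", names(cohort), value = TRUE))
  groups <- unique(cohort$group)
  summ <- NULL; cis <- NULL
  for (m in metrics) {
    v1 <- cohort[[paste0(m, "_v1")]]; v2 <- cohort[[paste0(m, "_v2")]]
    ch <- visitChange(v1, v2, cohort$days_between, config$monthDays)
    per <- data.frame(group = cohort$group, v1 = v1, v2 = v2,
                      diff = ch$difference, rate = ch$rate_per_month)
    for (g in groups) for (ty in c("v1", "v2", "diff", "rate")) {
      x <- per[per$group == g, ty]
      summ <- rbind(summ, data.frame(
        metric = m, group = g, type = ty, n = length(x), mean = mean(x),
        sd = stats::sd(x), median = stats::median(x), iqr = stats::IQR(x)))
    }
    if (all(c("no_exudation", "exudation") %in% groups)) {
      for (ty in c("v2", "rate")) {
        a <- per[per$group == "no_exudation", ty]
        b <- per[per$group == "exudation", ty]
        if (length(a) < 2 || length(b) < 2) next
        method <- if (length(a) >= 3 && length(b) >= 3)
          normalityGate(a, b, config$alpha)$method else "pooled_t"
        ci <- if (method == "pooled_t")
          pooledTCI(mean(a), stats::sd(a), length(a), mean(b), stats::sd(b), length(b))
        else
          bootstrapCI(a, b, B = config$bootB, seed = config$seed)
        cis <- rbind(cis, data.frame(
          metric = m, type = if (ty == "v2") "visit2" else "rate_per_month",
          diff = ci$diff, lo = ci$lo, hi = ci$hi, method = ci$method,
          n1 = length(a), n2 = length(b)))
      }
    }
  }
  list(summaries = summ, ci = cis,
       provenance = list(config_hash = configHash(config),
                         package_version = as.character(utils::packageVersion("octamnv"))))
}
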