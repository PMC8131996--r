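## Readers/writers for volumes (multi-page TIFF / NIfTI + JSON sidecar),
## surfaces (CSV/JSON), masks (PNG/TIFF) and metric tables (CSV).

#' @importFrom jsonlite read_json write_json
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom png readPNG writePNG
#' @importFrom RNifti readNifti writeNifti
NULL

#' Canonical per-eye, per-visit metric columns
#'
#' Column order and units of the biomarker table written by
#' \code{\link{writeMetrics}} and produced by \code{\link{runEyeVisit}}.
#'
#' @return Named character vector: column name -> unit.
#' @export
metricColumns <- function() c(
  mnv_area_mm2 = "mm2", sqrt_mnv_area_mm = "mm",
  fd_pct_r1 = "%", fd_pct_r2 = "%", fd_pct_r3 = "%", fd_pct_excl_mnv = "%",
  mean_fd_area_um2_r1 = "um2", mean_fd_area_um2_r2 = "um2",
  mean_fd_area_um2_r3 = "um2", mean_fd_area_um2_excl_mnv = "um2",
  vad = "ratio", vsd = "ratio",
  ped_area_mm2 = "mm2", ped_volume_mm3 = "mm3",
  mnv_ped_area_mm2 = "mm2", mnv_ped_volume_mm3 = "mm3",
  sqrt_mnv_ped_area_mm = "mm", cubert_mnv_ped_volume_mm = "mm",
  mct_um = "um", cvi = "ratio"
)

#' One eye-visit biomarker record
#'
#' Builds a one-row data frame holding every scalar biomarker for one eye at
#' one visit, with the canonical column order of \code{\link{metricColumns}}.
#' Missing metric families stay \code{NA}. Invariants (FD\% in [0, 100],
#' 0 <= VSD <= VAD <= 1, CVI in [0, 1], areas/volumes >= 0) are checked on
#' the non-missing values.
#'
#' @param eye_id character eye identifier.
#' @param visit visit index (1 or 2).
#' @param visit_date visit date (Date or numeric day offset).
#' @param ... named metric values from \code{\link{metricColumns}}.
#' @return A one-row data.frame.
#' @export
eyeVisitMetrics <- function(eye_id = NA_character_, visit = NA_integer_,
                            visit_date = NA, ...) {
  vals <- list(...)
  cols <- names(metricColumns())
  bad <- setdiff(names(vals), cols)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  row <- as.list(stats::setNames(rep(NA_real_, length(cols)), cols))
  row[names(vals)] <- lapply(vals, as.numeric)
  ok <- function(v) !is.na(v)
  for (p in c("fd_pct_r1", "fd_pct_r2", "fd_pct_r3", "fd_pct_excl_mnv")) {
    v <- row[[p]]
    if (ok(v) && (v < 0 || v > 100)) stop(p, " must be in [0, 100]")
  }
  if (ok(row$vad) && (row$vad < 0 || row$vad > 1)) stop("vad must be in [0, 1]")
  if (ok(row$vsd) && (row$vsd < 0 || row$vsd > 1)) stop("vsd must be in [0, 1]")
  if (ok(row$vad) && ok(row$vsd) && row$vsd > row$vad + 1e-12)
    stop("vsd must not exceed vad")
  if (ok(row$cvi) && (row$cvi < 0 || row$cvi > 1)) stop("cvi must be in [0, 1]")
  for (p in grep("_(mm2|mm3|um2|um|mm)$", cols, value = TRUE)) {
    v <- row[[p]]
    if (ok(v) && v < 0) stop(p, " must be >= 0")
  }
  cbind(data.frame(eye_id = eye_id, visit = as.integer(visit),
                   visit_date = visit_date, stringsAsFactors = FALSE),
        as.data.frame(row))
}

.sidecarPath <- function(path) paste0(path, ".json")

.readSidecar <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read a structural or flow OCT volume
#'
#' Reads a multi-page TIFF (one page per B-scan, each page nz x nx) or a
#' NIfTI-1 stack (dims nz, ny, nx), together with a JSON sidecar
#' \code{<path>.json} holding \code{nx, ny, nz, pitch_x_um, pitch_y_um,
#' pitch_z_um, fovea_x, fovea_y, signal_strength}. Scans whose signal
#' strength falls below \code{minSignalStrength} are rejected, mirroring the
#' acquisition-quality exclusion gate.
#'
#' @param path file path (.tif/.tiff or .nii/.nii.gz).
#' @param kind "flow" (OCTA) or "oct" (structural).
#' @param minSignalStrength minimum acceptable quality score (default 7).
#' @return An \linkS4class{OctVolume} / \linkS4class{FlowVolume}.
#' @export
readVolume <- function(path, kind = c("flow", "oct"), minSignalStrength = 7) {
  kind <- match.arg(kind)
  meta <- .readSidecar(path)
  need <- c("nx", "ny", "nz", "pitch_x_um", "pitch_y_um", "pitch_z_um")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sidecar missing fields: ", paste(miss, collapse = ", "))
  ss <- if (!is.null(meta$signal_strength)) as.integer(meta$signal_strength) else NA_integer_
  if (!is.na(ss) && ss < minSignalStrength)
    stop(sprintf("QC rejection: signal strength %d below required minimum %d",
                 ss, as.integer(minSignalStrength)))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::readNifti(path)
    if (length(dim(im)) != 3L) stop("NIfTI stack must be 3-D")
    arr <- array(as.vector(im), dim = dim(im))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(d[1], length(pages), d[2]))
    for (y in seq_along(pages)) {
      if (!all(dim(pages[[y]]) == d)) stop("TIFF pages differ in size")
      arr[, y, ] <- pages[[y]]
    }
  }
  d <- dim(arr)
  if (d[3] != meta$nx || d[2] != meta$ny || d[1] != meta$nz)
    stop(sprintf("grid/shape mismatch: sidecar (nz=%d, ny=%d, nx=%d) vs stack (%d, %d, %d)",
                 meta$nz, meta$ny, meta$nx, d[1], d[2], d[3]))
  if (any(arr < 0)) stop("negative intensities in volume")
  fx <- if (!is.null(meta$fovea_x)) meta$fovea_x else (meta$nx + 1) / 2
  fy <- if (!is.null(meta$fovea_y)) meta$fovea_y else (meta$ny + 1) / 2
  grid <- ScanGrid(meta$nx, meta$ny, meta$pitch_x_um, meta$pitch_y_um,
                   meta$pitch_z_um, c(fx, fy))
  OctVolume(arr, grid, ss, kind = kind)
}

#' Write a volume plus JSON sidecar
#'
#' TIFF output stores 32-bit float pages (one page per B-scan; values are
#' rounded to float32). NIfTI output (chosen by a .nii path) stores
#' float64 and round-trips losslessly. The sidecar records the grid
#' geometry and signal strength so that \code{\link{readVolume}}
#' round-trips.
#'
#' @param vol an \linkS4class{OctVolume}.
#' @param path output path (.tif/.tiff or .nii/.nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  g <- scanGrid(vol); v <- voxels(vol)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(v, path, datatype = "double")
  } else {
    pages <- lapply(seq_len(g@ny), function(y) v[, y, , drop = TRUE])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(list(
    nx = g@nx, ny = g@ny, nz = dim(v)[1],
    pitch_x_um = g@pitchX, pitch_y_um = g@pitchY, pitch_z_um = g@pitchZ,
    fovea_x = g@foveaXY[1], fovea_y = g@foveaXY[2],
    signal_strength = signalStrength(vol)
  ), .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layer surface from CSV or JSON
#'
#' CSV: ny rows x nx columns of axial positions in um, no header. JSON: an
#' object \code{{"z_um": [[...]]}} (row-major, ny rows). Non-finite cells
#' are an error unless \code{inpaint = TRUE}, in which case they are filled
#' iteratively from the mean of finite neighbors.
#'
#' @param path file path (.csv or .json).
#' @param grid the \linkS4class{ScanGrid} the surface must match.
#' @param name boundary name (see \linkS4class{Surface}).
#' @param inpaint fill non-finite cells instead of failing (default FALSE).
#' @return A \linkS4class{Surface}.
#' @export
readSurface <- function(path, grid, name, inpaint = FALSE) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    z <- if (is.list(obj) && !is.null(obj$z_um)) obj$z_um else obj
    z <- as.matrix(z)
  } else {
    z <- as.matrix(read.csv(path, header = FALSE))
  }
  dimnames(z) <- NULL
  if (!all(dim(z) == c(grid@ny, grid@nx)))
    stop(sprintf("surface shape (%d, %d) does not match grid (ny=%d, nx=%d)",
                 nrow(z), ncol(z), grid@ny, grid@nx))
  bad <- !is.finite(z)
  if (any(bad)) {
    if (!inpaint) {
      cell <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite surface value at (y=%d, x=%d); inpainting disabled",
                   cell[1], cell[2]))
    }
    z <- fillHoles(z, bad)
  }
  Surface(name, z, grid)
}

# Iteratively replace flagged cells by the mean of their finite 8-neighbors.
fillHoles <- function(z, bad) {
  z[bad] <- NA_real_
  while (anyNA(z)) {
    zp <- rbind(NA, cbind(NA, z, NA), NA)
    acc <- matrix(0, nrow(z), ncol(z)); cnt <- matrix(0, nrow(z), ncol(z))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- zp[(2 + dy):(nrow(z) + 1 + dy), (2 + dx):(ncol(z) + 1 + dx)]
      okn <- !is.na(nb)
      acc[okn] <- acc[okn] + nb[okn]
      cnt <- cnt + okn
    }
    fill <- is.na(z) & cnt > 0
    if (!any(fill)) stop("cannot inpaint: no finite neighbors anywhere")
    z[fill] <- acc[fill] / cnt[fill]
  }
  z
}

#' Write a surface as CSV (ny rows x nx cols, um)
#'
#' Values are written with 17 significant digits, so a write/read cycle
#' reproduces the doubles bit-identically.
#'
#' @param surface a \linkS4class{Surface}.
#' @param path output .csv path.
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(surface, path) {
  z <- zUm(surface)
  lines <- apply(z, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary mask from PNG or single-page TIFF (nonzero = TRUE)
#' @param path image path.
#' @param grid expected \linkS4class{ScanGrid}.
#' @param provenance free-text origin label.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, grid, provenance = basename(path)) {
  img <- if (grepl("\\.png$", path)) png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!all(dim(img) == c(grid@ny, grid@nx)))
    stop("mask shape does not match grid")
  BinaryMask(img > 0, grid, provenance)
}

#' Write a binary mask as PNG
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(pixels(mask) * 1.0, path)
  invisible(path)
}

#' Write / read the eye-visit metrics table
#'
#' CSV with one row per eye-visit, the canonical column order of
#' \code{\link{metricColumns}}, and a leading comment line documenting
#' units. \code{readMetrics} inverts it.
#'
#' @param records data.frame of \code{\link{eyeVisitMetrics}} rows (possibly
#'   zero rows).
#' @param path output .csv path.
#' @return \code{path} (write) / data.frame (read).
#' @export
writeMetrics <- function(records, path) {
  cols <- c("eye_id", "visit", "visit_date", names(metricColumns()))
  if (nrow(records)) {
    miss <- setdiff(cols, names(records))
    for (m in miss) records[[m]] <- NA
    records <- records[, c(cols, setdiff(names(records), cols)), drop = FALSE]
  } else {
    records <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(names(metricColumns()),
                                       metricColumns(), sep = "=", collapse = " ")), con)
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
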