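#' @import methods
#' @importFrom stats median quantile rnorm runif sd shapiro.test qt fisher.test
#'   dhyper setNames approx
#' @importFrom utils read.csv write.csv head tail
NULL

## Coordinate conventions used throughout the package
## ---------------------------------------------------
## x = fast axis (A-scans within a B-scan), y = B-scan index, z = depth
## increasing posteriorly. En face rasters are (ny, nx) matrices indexed
## [y, x]; volumes are (nz, ny, nx) arrays indexed [z, y, x]. Surfaces hold
## axial positions in micrometres measured from the anterior face of the
## first voxel plane, so voxel plane k spans [(k-1)*pitchZ, k*pitchZ).
## Pixel (y, x) has its centre at ((x-0.5)*pitchX, (y-0.5)*pitchY) um.
## Depths/pitches/thicknesses are um; areas mm^2; volumes mm^3 (conversion
## happens only when metrics are emitted).

#' ScanGrid: geometry of a raster scan
#'
#' Describes the sampling geometry of an OCT/OCTA raster scan: pixel counts,
#' pixel pitch in micrometres, and the pixel coordinates of the foveal
#' center. The physical extent is derived (\code{nx * pitchX / 1000} mm wide)
#' so geometry is consistent by construction.
#'
#' @slot nx,ny integer pixel counts along the fast (x) and slow (y) axes.
#' @slot pitchX,pitchY lateral pixel pitch, um/pixel.
#' @slot pitchZ axial voxel pitch, um/voxel (may be \code{NA} for purely
#'   en face grids; required to attach a volume).
#' @slot foveaXY numeric length-2, (x, y) pixel coordinates of the foveal
#'   center (1-based pixel index space).
#' @export
setClass("ScanGrid", representation(
  nx = "integer", ny = "integer",
  pitchX = "numeric", pitchY = "numeric", pitchZ = "numeric",
  foveaXY = "numeric"
))

setValidity("ScanGrid", function(object) {
  msg <- character()
  if (length(object@nx) != 1L || object@nx < 1L) msg <- c(msg, "nx must be a positive integer")
  if (length(object@ny) != 1L || object@ny < 1L) msg <- c(msg, "ny must be a positive integer")
  if (!is.finite(object@pitchX) || object@pitchX <= 0) msg <- c(msg, "pitchX must be > 0")
  if (!is.finite(object@pitchY) || object@pitchY <= 0) msg <- c(msg, "pitchY must be > 0")
  if (!is.na(object@pitchZ) && object@pitchZ <= 0) msg <- c(msg, "pitchZ must be > 0 (or NA)")
  if (length(object@foveaXY) != 2L || any(!is.finite(object@foveaXY)))
    msg <- c(msg, "foveaXY must be two finite numbers")
  else if (object@foveaXY[1] < 0.5 || object@foveaXY[1] > object@nx + 0.5 ||
           object@foveaXY[2] < 0.5 || object@foveaXY[2] > object@ny + 0.5)
    msg <- c(msg, "foveaXY must lie inside the grid")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanGrid
#'
#' @param nx,ny pixel counts (fast, slow axis).
#' @param pitchX,pitchY lateral pitch in um/pixel (default 12, the scan
#'   density used for choriocapillaris quantification).
#' @param pitchZ axial pitch in um/voxel; \code{NA} for en face-only grids.
#' @param foveaXY (x, y) pixel coordinates of the foveal center; defaults to
#'   the grid center.
#' @return A \linkS4class{ScanGrid}.
#' @examples
#' g <- ScanGrid(500, 500, pitchX = 12)   # 6 x 6 mm
#' extentMM(g)
#' @export
ScanGrid <- function(nx, ny, pitchX = 12, pitchY = pitchX, pitchZ = NA_real_,
                     foveaXY = c((nx + 1) / 2, (ny + 1) / 2)) {
  new("ScanGrid", nx = as.integer(nx), ny = as.integer(ny),
      pitchX = as.numeric(pitchX), pitchY = as.numeric(pitchY),
      pitchZ = as.numeric(pitchZ), foveaXY = as.numeric(foveaXY))
}

#' Structural and flow OCT volumes
#'
#' \code{OctVolume} holds non-negative scalar intensities on a
#' \linkS4class{ScanGrid}; \code{FlowVolume} is the same container for OCTA
#' decorrelation (flow) signal. \code{signalStrength} carries the
#' instrument's scan-quality score used as an exclusion gate.
#'
#' @slot voxels numeric array, dim (nz, ny, nx), finite and non-negative.
#' @slot grid a \linkS4class{ScanGrid} with a finite \code{pitchZ}.
#' @slot signalStrength integer quality score (NA when unknown).
#' @aliases FlowVolume-class
#' @export
setClass("OctVolume", representation(
  voxels = "array", grid = "ScanGrid", signalStrength = "integer"
))

#' @export
setClass("FlowVolume", contains = "OctVolume")

.validVolume <- function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 3L) msg <- c(msg, "voxels must be a 3-D (nz, ny, nx) array")
  else if (d[2] != object@grid@ny || d[3] != object@grid@nx)
    msg <- c(msg, sprintf("voxel dims (%d, %d, %d) inconsistent with grid (ny=%d, nx=%d)",
                          d[1], d[2], d[3], object@grid@ny, object@grid@nx))
  if (is.na(object@grid@pitchZ)) msg <- c(msg, "grid must carry a pitchZ to hold a volume")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msg <- c(msg, "voxels must be finite")
  else if (any(object@voxels < 0)) msg <- c(msg, "voxels must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("OctVolume", .validVolume)

#' Construct an OCT / OCTA volume
#'
#' @param voxels (nz, ny, nx) array of non-negative intensities.
#' @param grid a \linkS4class{ScanGrid} with finite \code{pitchZ}.
#' @param signalStrength integer instrument quality score (default NA).
#' @param kind "oct" for structural, "flow" for angiographic signal.
#' @return An \linkS4class{OctVolume} or \linkS4class{FlowVolume}.
#' @export
OctVolume <- function(voxels, grid, signalStrength = NA_integer_, kind = c("oct", "flow")) {
  kind <- match.arg(kind)
  cl <- if (kind == "flow") "FlowVolume" else "OctVolume"
  new(cl, voxels = voxels, grid = grid, signalStrength = as.integer(signalStrength))
}

#' @rdname OctVolume
#' @export
FlowVolume <- function(voxels, grid, signalStrength = NA_integer_)
  OctVolume(voxels, grid, signalStrength, kind = "flow")

#' Layer surface: per-(x, y) axial boundary position
#'
#' Axial position (um from the anterior face of the volume) of a named
#' retinal/choroidal boundary at every (x, y). RPE anterior to Bruch's
#' membrane (smaller z) encodes a pigment epithelial detachment, so
#' \code{rpe <= bm} is not assumed.
#'
#' @slot name one of outer_retina, rpe, bm, csi, cc_inner.
#' @slot zUm (ny, nx) matrix of finite axial positions, um.
#' @slot grid the \linkS4class{ScanGrid}.
#' @export
setClass("Surface", representation(name = "character", zUm = "matrix", grid = "ScanGrid"))

.surfaceNames <- c("outer_retina", "rpe", "bm", "csi", "cc_inner")

setValidity("Surface", function(object) {
  msg <- character()
  if (!(object@name %in% .surfaceNames))
    msg <- c(msg, paste("name must be one of:", paste(.surfaceNames, collapse = ", ")))
  if (!all(dim(object@zUm) == c(object@grid@ny, object@grid@nx)))
    msg <- c(msg, "zUm must be (ny, nx)")
  if (any(!is.finite(object@zUm))) msg <- c(msg, "zUm must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Surface
#' @param name boundary name (outer_retina, rpe, bm, csi, cc_inner).
#' @param zUm (ny, nx) matrix of axial positions in um, or a scalar for a
#'   flat surface.
#' @param grid the \linkS4class{ScanGrid}.
#' @return A \linkS4class{Surface}.
#' @export
Surface <- function(name, zUm, grid) {
  if (length(zUm) == 1L) zUm <- matrix(as.numeric(zUm), grid@ny, grid@nx)
  new("Surface", name = name, zUm = zUm, grid = grid)
}

#' En face image on a scan grid
#'
#' @slot pixels (ny, nx) matrix of finite values.
#' @slot grid the \linkS4class{ScanGrid}.
#' @export
setClass("EnFaceImage", representation(pixels = "matrix", grid = "ScanGrid"))

setValidity("EnFaceImage", function(object) {
  if (!all(dim(object@pixels) == c(object@grid@ny, object@grid@nx)))
    return("pixels must be (ny, nx)")
  if (any(!is.finite(object@pixels))) return("pixels must be finite")
  TRUE
})

#' @param pixels (ny, nx) matrix.
#' @param grid a \linkS4class{ScanGrid}.
#' @rdname EnFaceImage-class
#' @export
EnFaceImage <- function(pixels, grid) new("EnFaceImage", pixels = pixels, grid = grid)

#' Binary mask on a scan grid
#'
#' @slot pixels (ny, nx) logical matrix.
#' @slot grid the \linkS4class{ScanGrid}.
#' @slot provenance free-text label recording how the mask was produced.
#' @export
setClass("BinaryMask", representation(pixels = "matrix", grid = "ScanGrid",
                                      provenance = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be logical")
  if (!all(dim(object@pixels) == c(object@grid@ny, object@grid@nx)))
    return("pixels must be (ny, nx)")
  TRUE
})

#' @param pixels (ny, nx) logical matrix.
#' @param grid a \linkS4class{ScanGrid}.
#' @param provenance free-text origin label.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(pixels, grid, provenance = "unspecified") {
  storage.mode(pixels) <- "logical"
  new("BinaryMask", pixels = pixels, grid = grid, provenance = provenance)
}

#' Region partition around the MNV lesion
#'
#' Label image assigning every scan pixel to MNV, R1 (0-300 um from the
#' lesion margin), R2 (300-600 um) or R3 (remainder).
#'
#' @slot labels (ny, nx) character-coded factor matrix stored as integer
#'   codes 0 = MNV, 1 = R1, 2 = R2, 3 = R3.
#' @slot grid the \linkS4class{ScanGrid}.
#' @export
setClass("RegionPartition", representation(labels = "matrix", grid = "ScanGrid"))

setValidity("RegionPartition", function(object) {
  if (!all(dim(object@labels) == c(object@grid@ny, object@grid@nx)))
    return("labels must be (ny, nx)")
  if (!all(object@labels %in% 0:3)) return("labels must be codes 0..3 (MNV, R1, R2, R3)")
  TRUE
})

.regionCodes <- c(MNV = 0L, R1 = 1L, R2 = 2L, R3 = 3L)

## ---- accessors -----------------------------------------------------------

#' Accessors for the core data containers
#'
#' \code{scanGrid} returns the \linkS4class{ScanGrid}; \code{pixels} the
#' (ny, nx) raster; \code{voxels} the (nz, ny, nx) array; \code{zUm} a
#' surface's axial positions; \code{extentMM} the physical (width, height)
#' in mm; \code{pixelAreaMM2} one pixel's area in mm^2.
#'
#' @param x an octamnv data object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanGrid", function(x) standardGeneric("scanGrid"))
#' @rdname accessors
#' @export
setMethod("scanGrid", "OctVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("scanGrid", "Surface", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("scanGrid", "EnFaceImage", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("scanGrid", "BinaryMask", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("scanGrid", "RegionPartition", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "EnFaceImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "OctVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("zUm", function(x) standardGeneric("zUm"))
#' @rdname accessors
#' @export
setMethod("zUm", "Surface", function(x) x@zUm)

#' @rdname accessors
#' @export
setGeneric("signalStrength", function(x) standardGeneric("signalStrength"))
#' @rdname accessors
#' @export
setMethod("signalStrength", "OctVolume", function(x) x@signalStrength)

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionPartition", function(x) x@labels)

#' @rdname accessors
#' @export
extentMM <- function(x) {
  g <- if (is(x, "ScanGrid")) x else scanGrid(x)
  c(width = g@nx * g@pitchX / 1000, height = g@ny * g@pitchY / 1000)
}

#' @rdname accessors
#' @export
pixelAreaMM2 <- function(x) {
  g <- if (is(x, "ScanGrid")) x else scanGrid(x)
  g@pitchX * g@pitchY / 1e6
}

## ---- show methods --------------------------------------------------------

setMethod("show", "ScanGrid", function(object) {
  e <- extentMM(object)
  cat(sprintf("ScanGrid: %d x %d px, pitch (%g, %g, %s) um, %.2f x %.2f mm, fovea (%.1f, %.1f)\n",
              object@nx, object@ny, object@pitchX, object@pitchY,
              ifelse(is.na(object@pitchZ), "NA", format(object@pitchZ)),
              e[1], e[2], object@foveaXY[1], object@foveaXY[2]))
})

setMethod("show", "OctVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s: %d x %d x %d voxels (z, y, x), signal strength %s\n",
              class(object), d[1], d[2], d[3],
              ifelse(is.na(object@signalStrength), "NA", object@signalStrength)))
  show(object@grid)
})

setMethod("show", "Surface", function(object) {
  cat(sprintf("Surface '%s': z in [%.1f, %.1f] um\n", object@name,
              min(object@zUm), max(object@zUm)))
})

setMethod("show", "EnFaceImage", function(object) {
  cat(sprintf("EnFaceImage: %d x %d px, range [%.4g, %.4g]\n",
              object@grid@ny, object@grid@nx, min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask (%s): %d / %d px true\n", object@provenance,
              sum(object@pixels), length(object@pixels)))
})

setMethod("show", "RegionPartition", function(object) {
  tab <- table(factor(object@labels, levels = 0:3, labels = names(.regionCodes)))
  cat("RegionPartition:", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})
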