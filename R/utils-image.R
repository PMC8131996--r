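## Internal image-processing utilities shared by the measurement modules.
## All operate on plain (ny, nx) matrices in the package's [y, x] convention.

#' @importFrom EBImage filter2 makeBrush dilate erode fillHull closing otsu Image
#' @importFrom igraph graph_from_edgelist components make_empty_graph
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 8-connected component labeling of a logical matrix.
# Returns an integer matrix: 0 = background, 1..k component ids.
label8 <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  ny <- nrow(mask); nx <- ncol(mask)
  r <- ((idx - 1L) %% ny) + 1L
  c <- ((idx - 1L) %/% ny) + 1L
  # map full-image linear index -> foreground vertex id
  vid <- integer(ny * nx); vid[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * ny + r2[ok]
    hit <- mask[nb]
    if (!any(hit)) next
    edges <- rbind(edges, cbind(vid[idx[ok]][hit], vid[nb[hit]]))
  }
  g <- if (is.null(edges)) igraph::make_empty_graph(n = length(idx), directed = FALSE)
       else igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Exact Euclidean distance transform: for every pixel, distance (um) from its
# center to the nearest TRUE pixel center, honouring anisotropic pitch.
# Two-pass separable algorithm (1-D squared-distance lower envelopes along
# columns, then rows). Empty mask -> all Inf.
edtUm <- function(mask, pitchX, pitchY) {
  ny <- nrow(mask); nx <- ncol(mask)
  if (!any(mask)) return(matrix(Inf, ny, nx))
  INF <- .Machine$double.xmax / 4
  # pass 1: linear distance along y within each column (forward + backward
  # sweep, vectorized across columns)
  dcur <- matrix(INF, ny, nx)
  lin <- rep(INF, nx)
  for (i in seq_len(ny)) {
    lin <- pmin(ifelse(mask[i, ], 0, lin + pitchY), INF)
    dcur[i, ] <- lin
  }
  lin <- rep(INF, nx)
  for (i in rev(seq_len(ny))) {
    lin <- pmin(dcur[i, ], pmin(lin + pitchY, INF))
    dcur[i, ] <- lin
  }
  g2 <- dcur^2                      # squared distance restricted to columns
  g2[dcur >= INF] <- INF
  # pass 2: per row, lower envelope of parabolas j -> g2[i,j] + ((x-j)*pitchX)^2
  out <- matrix(0, ny, nx)
  px2 <- pitchX^2
  xs <- seq_len(nx)
  for (i in seq_len(ny)) {
    f <- g2[i, ]
    if (all(f >= INF)) { out[i, ] <- INF; next }
    v <- integer(nx); zl <- numeric(nx + 1L)
    k <- 1L; v[1] <- 1L; zl[1] <- -Inf; zl[2] <- Inf
    for (q in 2:nx) {
      fq <- f[q]
      if (fq >= INF) next
      repeat {
        p <- v[k]
        s <- ((fq + (q * q) * px2) - (f[p] + (p * p) * px2)) / (2 * px2 * (q - p))
        if (s <= zl[k] && k > 1L) { k <- k - 1L } else break
      }
      k <- k + 1L; v[k] <- q; zl[k] <- s; zl[k + 1L] <- Inf
    }
    k2 <- 1L
    for (q in xs) {
      while (zl[k2 + 1L] < q) k2 <- k2 + 1L
      p <- v[k2]
      out[i, q] <- f[p] + ((q - p) * (q - p)) * px2
    }
  }
  res <- sqrt(out)
  res[out >= INF] <- Inf
  res
}

# Gaussian low-pass on a matrix with replicate boundary handling.
gaussianSmooth <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  r <- max(1L, ceiling(3 * sigmaPx))
  k1 <- exp(-((-r:r)^2) / (2 * sigmaPx^2)); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
}

# Local (moving-window) mean with replicate boundary; window must be odd.
localMean <- function(m, windowPx) {
  w <- as.integer(windowPx)
  if (w %% 2L == 0L) w <- w + 1L
  kern <- matrix(1 / (w * w), w, w)
  as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
}

# Otsu threshold of a numeric vector (EBImage's histogram Otsu on the
# values rescaled to [0, 1]).
otsuThreshold <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  im <- EBImage::Image(matrix((v - r[1]) / diff(r), ncol = 1L))
  th <- EBImage::otsu(im, range = c(0, 1), levels = levels)
  r[1] + th * diff(r)
}

# Guo-Hall two-subiteration thinning to 8-connected unit-width centerlines.
# Endpoint-preserving, so skeleton length tracks true centerline length.
thinMask <- function(mask) {
  p <- mask
  ny <- nrow(p); nx <- ncol(p)
  pad <- function(m) { out <- matrix(FALSE, ny + 2L, nx + 2L); out[2:(ny + 1L), 2:(nx + 1L)] <- m; out }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      q <- pad(p)
      ci <- 2:(ny + 1L); cj <- 2:(nx + 1L)
      p2 <- q[ci - 1L, cj];     p3 <- q[ci - 1L, cj + 1L]
      p4 <- q[ci, cj + 1L];     p5 <- q[ci + 1L, cj + 1L]
      p6 <- q[ci + 1L, cj];     p7 <- q[ci + 1L, cj - 1L]
      p8 <- q[ci, cj - 1L];     p9 <- q[ci - 1L, cj - 1L]
      C  <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) + (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      Nm <- pmin(N1, N2)
      m  <- if (step == 1L) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      cond <- p & C == 1 & Nm >= 2 & Nm <= 3 & !m
      if (any(cond)) { p[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  p
}

# Rasterize a disk of given center (x, y in pixel coords) and radius (um)
# onto a grid: pixel centers within radius.
diskMask <- function(grid, centerXY, radiusUm) {
  xs <- (seq_len(grid@nx) - 0.5) * grid@pitchX
  ys <- (seq_len(grid@ny) - 0.5) * grid@pitchY
  cx <- (centerXY[1] - 0.5) * grid@pitchX
  cy <- (centerXY[2] - 0.5) * grid@pitchY
  outer(ys - cy, xs - cx, function(dy, dx) dy * dy + dx * dx) <= radiusUm^2
}

# Pixel-center membership of the fovea-centered circle of given diameter (mm).
circleMask <- function(grid, diameterMm, centerXY = grid@foveaXY) {
  diskMask(grid, centerXY, diameterMm * 1000 / 2)
}

# Rasterize a polyline (n x 2 matrix of (x, y) pixel coordinates) with a
# given stroke width in pixels. Segments are stepped at one sample per
# dominant-axis pixel, giving 8-connected unit-width lines (so the width-1
# raster's pixel count matches the skeleton-length convention).
rasterizePolyline <- function(grid, xy, widthPx = 1) {
  m <- matrix(FALSE, grid@ny, grid@nx)
  if (nrow(xy) < 2L) return(m)
  for (s in seq_len(nrow(xy) - 1L)) {
    a <- xy[s, ]; b <- xy[s + 1L, ]
    n <- max(2L, ceiling(max(abs(b - a))) + 1L)
    t <- seq(0, 1, length.out = n)
    px <- round(a[1] + t * (b[1] - a[1]))
    py <- round(a[2] + t * (b[2] - a[2]))
    ok <- px >= 1 & px <= grid@nx & py >= 1 & py <= grid@ny
    m[cbind(py[ok], px[ok])] <- TRUE
  }
  if (widthPx > 1) {
    brush <- EBImage::makeBrush(2L * floor(widthPx / 2) + 1L, shape = "disc")
    m <- EBImage::dilate(m, brush) > 0
  }
  m
}

# Component pixel counts of a label matrix (named integer vector).
componentSizes <- function(lab) {
  t <- tabulate(lab[lab > 0L])
  stats::setNames(t, seq_along(t))
}
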