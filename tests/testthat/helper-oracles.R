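# Independent oracles and small fixtures, kept free of the package's own
# computational paths wherever they are used as ground truth.

dice <- function(a, b) {
  pa <- if (is(a, "BinaryMask")) pixels(a) else a
  pb <- if (is(b, "BinaryMask")) pixels(b) else b
  2 * sum(pa & pb) / (sum(pa) + sum(pb))
}

# Brute-force anisotropic Euclidean distance (um) to the nearest TRUE pixel.
bruteForceEdtUm <- function(mask, px, py) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (!nrow(idx)) return(out)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    out[i, j] <- sqrt(min(((i - idx[, 1]) * py)^2 + ((j - idx[, 2]) * px)^2))
  out
}

# Breadth-first 8-connected labeling (independent of the package's igraph
# route). Returns integer label matrix.
bfsLabel8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextLab <- 0L
  ny <- nrow(mask); nx <- ncol(mask)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% ny + 1L; c <- (cur - 1L) %/% ny + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > ny || c2 < 1 || c2 > nx) next
        k <- (c2 - 1L) * ny + r2
        if (mask[k] && lab[k] == 0L) { lab[k] <- nextLab; queue <- c(queue, k) }
      }
    }
  }
  lab
}

# Two-sided Fisher exact p by direct enumeration of all tables with the
# observed margins (hypergeometric probabilities <= observed, with the
# usual relative tolerance).
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  pobs <- pr[xs == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Fine-grid numeric integral of a Gaussian bump h * exp(-r^2 / (2 sigma^2))
# over the plane (mm^3), independent of the phantom's closed form.
numericBumpVolumeMm3 <- function(hUm, sigmaUm, stepUm = 5, extentSigmas = 8) {
  xs <- seq(-extentSigmas * sigmaUm, extentSigmas * sigmaUm, by = stepUm)
  z <- hUm * exp(-outer(xs^2, xs^2, "+") / (2 * sigmaUm^2))
  sum(z) * stepUm^2 / 1e9
}
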