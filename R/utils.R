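# Internal numerical helpers: array resampling, connected components,
# intensity clustering, spline bases.

# Translate a volume by `shift` voxels (possibly fractional) with trilinear
# interpolation: out[v] = vol[v - shift]; voxels sampled outside the grid
# get `fill`.
#' @noRd
shiftVolume <- function(vol, shift, fill = 0) {
  if (all(shift == 0)) return(vol)
  d <- dim(vol)
  xs <- seq_len(d[1]) - shift[1]
  ys <- seq_len(d[2]) - shift[2]
  zs <- seq_len(d[3]) - shift[3]
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0;   fy <- ys - y0;   fz <- zs - z0
  clampIdx <- function(i, n) pmin(pmax(i, 1L), n)
  inRange <- function(i, n) i >= 1 & i <= n
  out <- array(fill, d)
  # accumulate the 8 trilinear corners via outer products of 1-D weights
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fx else fx
    wy <- if (dy == 0) 1 - fy else fy
    wz <- if (dz == 0) 1 - fz else fz
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    okx <- inRange(ix, d[1]); oky <- inRange(iy, d[2]); okz <- inRange(iz, d[3])
    vals <- vol[clampIdx(ix, d[1]), clampIdx(iy, d[2]), clampIdx(iz, d[3]),
                drop = FALSE]
    vals <- vals * (wx * okx)
    vals <- sweep(vals, 2, wy * oky, "*")
    vals <- sweep(vals, 3, wz * okz, "*")
    if (dx + dy + dz == 0) out[] <- 0
    out <- out + vals
  }
  # renormalise by total in-bounds weight so border voxels are not dimmed,
  # then put `fill` where no corner was in bounds
  wtot <- outer(outer(ifelse(inRange(x0, d[1]), 1 - fx, 0) +
                        ifelse(inRange(x0 + 1L, d[1]), fx, 0),
                      ifelse(inRange(y0, d[2]), 1 - fy, 0) +
                        ifelse(inRange(y0 + 1L, d[2]), fy, 0)),
                ifelse(inRange(z0, d[3]), 1 - fz, 0) +
                  ifelse(inRange(z0 + 1L, d[3]), fz, 0))
  zero <- wtot <= 1e-12
  out[!zero] <- out[!zero] / wtot[!zero]
  out[zero] <- fill
  out
}

# Normalised cross-correlation between two volumes over a voxel subset.
#' @noRd
nccOverlap <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

# 6-connected components of a logical 3-D array via frontier flood fill.
# Returns an integer array of labels (0 = background).
#' @noRd
labelComponents <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  maskv <- as.logical(mask)
  offsets <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  # precompute coordinates to reject wrap-around neighbours
  xcoord <- rep_len(seq_len(d[1]), n)
  ycoord <- rep_len(rep(seq_len(d[2]), each = d[1]), n)
  zcoord <- rep(seq_len(d[3]), each = d[1] * d[2])
  remaining <- which(maskv)
  current <- 0L
  while (length(remaining)) {
    current <- current + 1L
    frontier <- remaining[1]
    lab[frontier] <- current
    while (length(frontier)) {
      cand <- rep(frontier, each = 6L) + rep(offsets, length(frontier))
      # reject out-of-grid and wrap-around steps
      src <- rep(frontier, each = 6L)
      ok <- cand >= 1L & cand <= n
      cand <- cand[ok]; src <- src[ok]
      ok <- (abs(xcoord[cand] - xcoord[src]) +
             abs(ycoord[cand] - ycoord[src]) +
             abs(zcoord[cand] - zcoord[src])) == 1L
    cand <- cand[ok]
      cand <- unique(cand[maskv[cand] & lab[cand] == 0L])
      lab[cand] <- current
      frontier <- cand
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  array(lab, d)
}

# Two-class 1-D intensity clustering; returns the midpoint between the two
# class means (k-means with deterministic quantile initialisation).
#' @noRd
twoClassThreshold <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(q) < .Machine$double.eps^0.5 * max(1, abs(q[2])))
    return(NA_real_)
  km <- stats::kmeans(x, centers = matrix(q, ncol = 1), iter.max = 50)
  mean(sort(km$centers))
}

# Restricted cubic spline basis with 3 knots (10th/50th/90th percentiles by
# default): natural cubic spline, linear beyond the boundary knots.
#' @noRd
rcsBasis <- function(x, knots = NULL, probs = c(0.1, 0.5, 0.9)) {
  if (is.null(knots)) knots <- stats::quantile(x, probs, names = FALSE)
  if (length(unique(knots)) < 3)
    stop("degenerate spline knots: covariate has too few distinct values")
  splines::ns(x, knots = knots[2], Boundary.knots = knots[c(1, 3)])
}

# Standardised mean difference of a numeric covariate between one group and
# the rest, optionally weighted (used in balance diagnostics and tests).
#' @noRd
smd <- function(x, inGroup, w = rep(1, length(x))) {
  m1 <- stats::weighted.mean(x[inGroup], w[inGroup])
  m0 <- stats::weighted.mean(x[!inGroup], w[!inGroup])
  v1 <- stats::weighted.mean((x[inGroup] - m1)^2, w[inGroup])
  v0 <- stats::weighted.mean((x[!inGroup] - m0)^2, w[!inGroup])
  (m1 - m0) / sqrt((v1 + v0) / 2)
}
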