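#' Correct multiplicative bias-field inhomogeneity
#'
#' Estimates a smooth multiplicative field from a single volume and divides
#' it out. The estimator alternates two steps in the log domain: (1)
#' classify foreground voxels into a small number of tissue classes by
#' one-dimensional k-means on the bias-corrected log intensity, (2) fit a
#' low-order polynomial in the voxel coordinates to the residual of the
#' log intensity around the class means. The converged polynomial,
#' exponentiated and normalised to mean 1 over the foreground, is the
#' estimated field. On a volume with piecewise-constant tissue classes and
#' no bias, the residuals vanish and the estimated field is exactly 1.
#'
#' @param volume 3-D array; must be strictly positive over tissue.
#' @param config list of options: \code{degree} polynomial degree (default
#'   2), \code{nClasses} tissue classes (default 3), \code{maxIter}
#'   (default 8), \code{fgFraction} foreground threshold as a fraction of
#'   the 99th intensity percentile (default 0.05).
#' @return list with \code{corrected} (volume divided by the field) and
#'   \code{field} (estimated field, mean 1 over the foreground).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(32, 32, 8), noiseSd = 0,
#'                                   biasFieldAmplitude = 0, seed = 1))
#' bf <- correctBiasField(ph$series@nonFatSat)
#' range(bf$field)
#' @export
correctBiasField <- function(volume, config = list()) {
  cfg <- utils::modifyList(list(degree = 2, nClasses = 3, maxIter = 8,
                                fgFraction = 0.05), config)
  if (max(volume) <= 0)
    stop("bias correction requires a volume with positive tissue signal")
  d <- dim(volume)
  thr <- cfg$fgFraction * stats::quantile(volume, 0.99, names = FALSE)
  fg <- which(volume > thr)
  if (any(volume[fg] <= 0))
    stop("bias correction requires strictly positive intensities over tissue")

  # polynomial design in scaled coordinates, evaluated on foreground voxels
  coords <- arrayInd(fg, d)
  sc <- sweep(sweep(coords, 2, d / 2), 2, d / 2, "/")
  P <- stats::poly(sc, degree = cfg$degree, raw = TRUE)
  P <- cbind(1, P)
  logI <- log(volume[fg])

  lf <- rep(0, length(fg))  # log field estimate
  if (stats::sd(logI) > 1e-8) {
    for (it in seq_len(cfg$maxIter)) {
      lc <- logI - lf
      k <- min(cfg$nClasses, length(unique(round(lc, 10))))
      if (k < 2) break
      centres <- stats::quantile(lc, seq(0.1, 0.9, length.out = k),
                                 names = FALSE)
      if (length(unique(centres)) < k) break
      km <- stats::kmeans(lc, centers = matrix(centres, ncol = 1),
                          iter.max = 50)
      resid <- logI - km$centers[km$cluster]
      fit <- stats::lm.fit(P, resid)
      newLf <- as.vector(P %*% fit$coefficients)
      if (max(abs(newLf - lf)) < 1e-6) { lf <- newLf; break }
      lf <- newLf
    }
  }

  # evaluate the fitted polynomial over the whole grid
  allCoords <- arrayInd(seq_len(prod(d)), d)
  scAll <- sweep(sweep(allCoords, 2, d / 2), 2, d / 2, "/")
  coef <- tryCatch(stats::lm.fit(P, lf)$coefficients,
                   error = function(e) c(0, rep(0, ncol(P) - 1)))
  coef[is.na(coef)] <- 0
  Pall <- cbind(1, stats::poly(scAll, degree = cfg$degree, raw = TRUE))
  field <- array(exp(as.vector(Pall %*% coef)), d)
  field <- field / mean(field[fg])
  list(corrected = volume / field, field = field)
}

#' Segment the two breasts on the non-fat-suppressed volume
#'
#' Thresholds the non-fat-suppressed T1 volume by two-class intensity
#' clustering (tissue vs air), removes the chest-wall slab by cutting at
#' the most anterior posterior-axis row whose cross-section is almost
#' fully covered by foreground, labels 6-connected components, and returns
#' the two largest as left and right breast masks (side assigned by
#' centroid along the left-right axis). If the breasts touch across the
#' midline the single component is split at the mid-sagittal plane.
#'
#' @param series a \code{\linkS4class{DceSeries}}.
#' @param volume optional replacement for the non-fat-suppressed volume
#'   (e.g. its bias-corrected version).
#' @param config list: \code{slabCoverage} cross-section coverage above
#'   which a row is treated as chest wall (default 0.9).
#' @return named list with \code{left} and \code{right}
#'   \code{\linkS4class{VoxelMask}} objects (tissue \code{"breast"}).
#' @export
segmentBreast <- function(series, volume = NULL, config = list()) {
  stopifnot(is(series, "DceSeries"))
  cfg <- utils::modifyList(list(slabCoverage = 0.9), config)
  vol <- if (is.null(volume)) series@nonFatSat else volume
  d <- dim(vol)
  thr <- twoClassThreshold(as.vector(vol))
  if (is.na(thr) || !any(vol > thr))
    stop("breast segmentation failed: no foreground found")
  fg <- vol > thr

  # chest-wall cut: posterior rows whose (x,z) cross-section is (almost)
  # fully foreground belong to the chest-wall slab
  coverage <- apply(fg, 2, mean)
  slabRows <- which(coverage > cfg$slabCoverage)
  slabRows <- slabRows[slabRows > dim(fg)[2] / 2]  # only posterior half
  if (length(slabRows)) fg[, min(slabRows):d[2], ] <- FALSE
  if (!any(fg))
    stop("breast segmentation failed: no tissue anterior to the chest wall")

  # the dark fibroglandular interior falls below the air/fat threshold;
  # restore it by filling in-plane holes
  fg <- EBImage::fillHull(array(as.numeric(fg), d)) > 0.5
  fg <- array(fg, d)

  lab <- labelComponents(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
  xmid <- (d[1] + 1) / 2
  masks <- list()
  if (length(keep) == 2) {
    for (k in keep) {
      m <- lab == k
      cx <- mean(arrayInd(which(m), d)[, 1])
      side <- if (cx > xmid) "left" else "right"
      masks[[side]] <- m
    }
  }
  if (length(masks) != 2) {  # single component: split at the midline
    m <- lab == keep[1]
    left <- m; left[seq_len(floor(xmid)), , ] <- FALSE
    right <- m & !left
    masks <- list(left = left, right = right)
  }
  list(
    left = new("VoxelMask", mask = masks$left, side = "left",
               tissue = "breast", eroded = FALSE,
               voxelSize = series@voxelSize),
    right = new("VoxelMask", mask = masks$right, side = "right",
                tissue = "breast", eroded = FALSE,
                voxelSize = series@voxelSize))
}

#' Segment parenchyma in the contralateral breast
#'
#' Two-class intensity clustering of the voxels inside the contralateral
#' breast mask on the non-fat-suppressed T1 volume: fat is bright,
#' fibroglandular (parenchymal) tissue dark. The darker class becomes the
#' parenchyma mask (before erosion).
#'
#' @param series a \code{\linkS4class{DceSeries}}; its
#'   \code{laterality} defines which side is contralateral.
#' @param breastMask a breast \code{\linkS4class{VoxelMask}} for the side
#'   opposite \code{series@laterality}.
#' @param volume optional replacement for the non-fat-suppressed volume
#'   (e.g. bias-corrected).
#' @return a \code{\linkS4class{VoxelMask}} with tissue
#'   \code{"parenchyma"}, not yet eroded.
#' @export
segmentParenchyma <- function(series, breastMask, volume = NULL) {
  stopifnot(is(series, "DceSeries"), is(breastMask, "VoxelMask"))
  if (breastMask@side == series@laterality)
    stop("parenchyma is segmented in the contralateral breast; the ",
         "supplied mask is on the cancer side (", series@laterality, ")")
  if (!any(breastMask@mask))
    stop("parenchyma segmentation failed: breast mask is empty")
  vol <- if (is.null(volume)) series@nonFatSat else volume
  vals <- vol[breastMask@mask]
  thr <- twoClassThreshold(vals)
  if (is.na(thr))
    stop("parenchyma segmentation failed: breast intensities are constant")
  m <- array(FALSE, dim(vol))
  m[breastMask@mask] <- vals < thr  # parenchyma is the dark class
  new("VoxelMask", mask = m, side = breastMask@side,
      tissue = "parenchyma", eroded = FALSE, voxelSize = series@voxelSize)
}

#' In-plane morphological erosion of a mask
#'
#' Erodes the mask with a 3 x 3 structuring element applied slice-wise
#' (in-plane only, never through-slice, matching the anisotropic voxels).
#'
#' @param mask a \code{\linkS4class{VoxelMask}}.
#' @return the eroded \code{\linkS4class{VoxelMask}} (\code{eroded} flag
#'   set).
#' @export
erodeInplane <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  kern <- EBImage::makeBrush(3, shape = "box")
  eroded <- EBImage::erode(array(as.numeric(mask@mask), dim(mask@mask)),
                           kern) > 0.5
  initialize(mask, mask = array(eroded, dim(mask@mask)), eroded = TRUE)
}

# Phase-correlation translation estimate: the subvoxel shift to apply to
# `mov` (via shiftVolume) so it aligns with `ref`. A Hann window suppresses
# wrap-around edge effects; the correlation peak is refined per axis by a
# three-point parabolic fit.
#' @noRd
phaseCorrelation <- function(ref, mov) {
  d <- dim(ref)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  W <- array(outer(outer(hann(d[1]), hann(d[2])), hann(d[3])), d)
  Fr <- stats::fft(ref * W)
  Fm <- stats::fft(mov * W)
  R <- Fr * Conj(Fm)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  p <- arrayInd(which.max(r), d)
  s <- as.numeric(p - 1)
  s <- ifelse(s > d / 2, s - d, s)
  sub <- numeric(3)
  for (ax in 1:3) {
    at <- function(off) {
      q <- p
      q[ax] <- ((q[ax] - 1 + off) %% d[ax]) + 1
      r[q[1], q[2], q[3]]
    }
    den <- at(-1) - 2 * at(0) + at(1)
    sub[ax] <- if (abs(den) > 1e-12) 0.5 * (at(-1) - at(1)) / den else 0
  }
  s + sub
}

#' Register the fat-suppressed series to the pre-contrast frame
#'
#' Estimates, for each post-contrast volume, the translation that aligns
#' it with the pre-contrast fat-suppressed volume by 3-D phase correlation
#' (Hann-windowed cross-power spectrum; subvoxel peak by parabolic fit)
#' and resamples the volume into the pre-contrast frame with trilinear
#' interpolation. With \code{method = "identity"} the series is passed
#' through unchanged (for data known to be aligned).
#'
#' @param series a \code{\linkS4class{DceSeries}}.
#' @param config list: \code{method} \code{"translation"} (default) or
#'   \code{"identity"}; \code{maxShiftVox} sanity bound on the recovered
#'   shift per axis (default \code{c(8, 8, 3)}); larger estimates raise a
#'   registration error. \code{minShiftVox} (default 0.2): estimates below
#'   this on every axis are treated as no motion and the volume is left
#'   unresampled (the estimator's accuracy floor; avoids interpolation
#'   blur), which also makes registration idempotent.
#' @return the registered \code{\linkS4class{DceSeries}}
#'   (\code{registered = TRUE}); recovered translations in mm are stored
#'   in the \code{transforms} slot.
#' @export
registerSeries <- function(series, config = list()) {
  stopifnot(is(series, "DceSeries"))
  cfg <- utils::modifyList(list(method = "translation",
                                maxShiftVox = c(8, 8, 3),
                                minShiftVox = 0.2), config)
  if (cfg$method == "identity") {
    series@registered <- TRUE
    series@transforms <- rep(list(c(x = 0, y = 0, z = 0)), 4)
    return(series)
  }
  ref <- series@fatSat[[1]]
  if (max(ref) <= 0) stop("registration failed: reference volume is empty")

  transforms <- list(c(x = 0, y = 0, z = 0))
  for (k in 2:4) {
    s <- phaseCorrelation(ref, series@fatSat[[k]])
    if (any(abs(s) > cfg$maxShiftVox))
      stop("registration failed: recovered shift (",
           paste(sprintf("%.2f", s), collapse = ", "),
           " voxels) exceeds the plausible range; check the input series")
    if (all(abs(s) < cfg$minShiftVox)) s <- c(0, 0, 0)
    if (any(s != 0))
      series@fatSat[[k]] <- shiftVolume(series@fatSat[[k]], s)
    transforms[[k]] <- stats::setNames(s * series@voxelSize,
                                       c("x", "y", "z"))
  }
  message(sprintf(
    "registration: recovered translations (mm): post1 %.2f, post2 %.2f, post3 %.2f",
    sqrt(sum(transforms[[2]]^2)), sqrt(sum(transforms[[3]]^2)),
    sqrt(sum(transforms[[4]]^2))))
  series@registered <- TRUE
  series@transforms <- transforms
  series
}
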