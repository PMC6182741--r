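#' Compute the per-voxel late-enhancement map
#'
#' Late enhancement at each voxel of the (eroded) parenchyma mask is the
#' relative signal increase between the first and the last post-contrast
#' fat-suppressed volumes: E(v) = (S_last(v) - S_first(v)) / S_first(v).
#' The map is unitless, so any common positive rescaling of the volumes
#' leaves it unchanged.
#'
#' @param series a registered \code{\linkS4class{DceSeries}}.
#' @param mask an eroded parenchyma \code{\linkS4class{VoxelMask}}.
#' @param onNonPositive what to do when S_first <= 0 on a mask voxel:
#'   \code{"error"} (default) or \code{"exclude"} the voxel.
#' @return an \code{\linkS4class{EnhancementMap}}.
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(32, 32, 8), noiseSd = 0,
#'                                   seed = 1))
#' m <- new("VoxelMask", mask = ph$truth@parenchymaMask, side = "right",
#'          tissue = "parenchyma", eroded = TRUE, voxelSize = c(0.7, 0.7, 3))
#' em <- computeEnhancementMap(ph$series, m)
#' range(em@values)  # 0.4 everywhere for the noise-free phantom
#' @export
computeEnhancementMap <- function(series, mask,
                                  onNonPositive = c("error", "exclude")) {
  stopifnot(is(series, "DceSeries"), is(mask, "VoxelMask"))
  onNonPositive <- match.arg(onNonPositive)
  if (!series@registered)
    stop("series must be registered before computing enhancement")
  if (!mask@eroded)
    warning("enhancement computed on a non-eroded mask")
  idx <- which(mask@mask)
  sFirst <- series@fatSat[[2]][idx]
  sLast <- series@fatSat[[4]][idx]
  bad <- sFirst <= 0
  if (any(bad)) {
    if (onNonPositive == "error")
      stop(sum(bad), " mask voxel(s) have non-positive first post-contrast",
           " signal; register/segment upstream or set onNonPositive='exclude'")
    idx <- idx[!bad]; sFirst <- sFirst[!bad]; sLast <- sLast[!bad]
  }
  new("EnhancementMap", values = (sLast - sFirst) / sFirst,
      voxels = as.integer(idx), dim = dim(mask@mask))
}

#' Compute contralateral parenchymal enhancement (CPE)
#'
#' Sorts the enhancement values ascending and averages the top 10\%: the
#' \code{ceiling(0.1 * N)} largest values. The 90th percentile (linear
#' interpolation) is reported alongside for reference. Negative
#' enhancement values are retained in the distribution; they simply never
#' reach the top decile.
#'
#' @param map an \code{\linkS4class{EnhancementMap}} with at least 10
#'   voxels.
#' @return a \code{\linkS4class{CpeResult}} (tertile unset).
#' @examples
#' m <- new("EnhancementMap", values = as.numeric(1:100),
#'          voxels = 1:100, dim = c(100L, 1L, 1L))
#' cpeValue(computeCpe(m))  # mean of 91..100 = 95.5
#' @export
computeCpe <- function(map) {
  stopifnot(is(map, "EnhancementMap"))
  n <- length(map@values)
  if (n < 10L)
    stop("CPE requires at least 10 parenchyma voxels (got ", n, ")")
  k <- ceiling(0.1 * n)
  vals <- sort(map@values)
  top <- vals[(n - k + 1L):n]
  new("CpeResult",
      p90 = stats::quantile(map@values, 0.9, names = FALSE),
      cpe = mean(top), nVoxels = as.integer(n))
}

#' Trichotomise a cohort's CPE values into tertiles
#'
#' Ranks patients by CPE and assigns equal-size low / intermediate / high
#' groups by increasing CPE. When n is not divisible by 3 the remainder
#' goes to the outer groups first (the low group receives a remainder
#' patient before the high group), so n = 302 yields 101/100/101. Ties
#' spanning a boundary are broken by stable original-order rank.
#'
#' @param cpeValues numeric vector of per-patient CPE values (n >= 3).
#' @return factor with ordered levels \code{low}, \code{intermediate},
#'   \code{high}, same length/order as the input.
#' @examples
#' table(assignTertiles(rnorm(302)))
#' assignTertiles(c(3, 1, 2))
#' @export
assignTertiles <- function(cpeValues) {
  n <- length(cpeValues)
  if (n < 3L) stop("tertile assignment requires at least 3 patients")
  if (any(!is.finite(cpeValues))) stop("CPE values must be finite")
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- c(low = base + (r >= 1L), intermediate = base,
             high = base + (r >= 2L))
  ranks <- order(cpeValues)  # stable: ties keep original order
  lab <- character(n)
  lab[ranks] <- rep(c("low", "intermediate", "high"), times = sizes)
  factor(lab, levels = c("low", "intermediate", "high"))
}
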