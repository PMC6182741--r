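#' @import methods
NULL

#' Dynamic contrast-enhanced breast MRI series
#'
#' Container for one patient's DCE-MRI acquisition: a non-fat-suppressed
#' T1-weighted volume plus four fat-suppressed T1-weighted volumes (one
#' pre-contrast and three post-contrast, nominally 120 s apart). All volumes
#' share one voxel grid; the first array axis runs towards the patient's
#' left, the second from anterior to posterior, the third across slices.
#'
#' @slot nonFatSat 3-D array, non-fat-suppressed T1-weighted volume.
#' @slot fatSat list of four 3-D arrays: pre-contrast, then three
#'   post-contrast fat-suppressed volumes, in acquisition order.
#' @slot voxelSize numeric(3), voxel edge lengths in mm
#'   (in-plane, in-plane, slice).
#' @slot laterality side of the known cancer, \code{"left"} or
#'   \code{"right"}; the contralateral (disease-free) breast is the other
#'   side.
#' @slot registered logical flag: \code{TRUE} once the fat-suppressed
#'   volumes are in the frame of the pre-contrast volume.
#' @slot transforms list of per-volume translation estimates (mm) recorded
#'   by \code{\link{registerSeries}}.
#'
#' @seealso \code{\link{generatePhantom}}, \code{\link{registerSeries}}
#' @export
setClass("DceSeries",
  representation(
    nonFatSat  = "array",
    fatSat     = "list",
    voxelSize  = "numeric",
    laterality = "character",
    registered = "logical",
    transforms = "list"
  ),
  prototype(registered = FALSE, transforms = list())
)

setValidity("DceSeries", function(object) {
  msg <- character()
  if (length(object@fatSat) != 4L)
    msg <- c(msg, "fatSat must hold 4 volumes (pre + 3 post-contrast)")
  dims <- lapply(c(list(object@nonFatSat), object@fatSat), dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    msg <- c(msg, "all volumes must share the same dimensions")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (!object@laterality %in% c("left", "right"))
    msg <- c(msg, "laterality must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Binary voxel mask
#'
#' A binary mask over the voxel grid of a \code{\linkS4class{DceSeries}},
#' labelled with the breast side it covers and the tissue it delineates.
#' Parenchyma masks are nested inside the breast mask of the same side, and
#' an eroded mask is nested inside its pre-erosion parent.
#'
#' @slot mask logical 3-D array.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot tissue \code{"breast"} or \code{"parenchyma"}.
#' @slot eroded logical; \code{TRUE} after in-plane morphological erosion.
#' @slot voxelSize numeric(3), mm.
#' @export
setClass("VoxelMask",
  representation(
    mask      = "array",
    side      = "character",
    tissue    = "character",
    eroded    = "logical",
    voxelSize = "numeric"
  ),
  prototype(eroded = FALSE)
)

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical array")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (!object@tissue %in% c("breast", "parenchyma"))
    msg <- c(msg, "tissue must be 'breast' or 'parenchyma'")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic phantom
#'
#' Records everything the generator knows about a phantom so downstream
#' stages can be scored: tissue compartment masks, the true late
#' enhancement of the parenchyma, the multiplicative bias field, and the
#' translation applied to each post-contrast volume.
#'
#' @slot breastMask,fatMask,parenchymaMask logical 3-D arrays; fat and
#'   parenchyma are disjoint and partition the breast mask.
#' @slot trueEnhancement true relative signal increase of parenchyma
#'   between first and last post-contrast volumes (unitless).
#' @slot trueBiasField strictly positive 3-D array.
#' @slot motionMm 4 x 3 matrix of applied translations (mm) for the four
#'   fat-suppressed volumes (pre-contrast row is zero).
#' @export
setClass("GroundTruth",
  representation(
    breastMask      = "array",
    fatMask         = "array",
    parenchymaMask  = "array",
    trueEnhancement = "numeric",
    trueBiasField   = "array",
    motionMm        = "matrix"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(object@fatMask & object@parenchymaMask))
    msg <- c(msg, "fat and parenchyma masks must be disjoint")
  if (any(object@trueBiasField <= 0))
    msg <- c(msg, "trueBiasField must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Late-enhancement map over a parenchyma mask
#'
#' Per-voxel relative signal increase between the first and last
#' post-contrast volumes, (S_last - S_first) / S_first, restricted to the
#' voxels of an (eroded) parenchyma mask.
#'
#' @slot values numeric vector of enhancement values (unitless).
#' @slot voxels integer vector of linear voxel indices into the volume.
#' @slot dim integer(3), dimensions of the parent volume.
#' @export
setClass("EnhancementMap",
  representation(values = "numeric", voxels = "integer", dim = "integer")
)

setValidity("EnhancementMap", function(object) {
  msg <- character()
  if (length(object@values) != length(object@voxels))
    msg <- c(msg, "values and voxels must have equal length")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "enhancement values must be finite")
  if (length(msg)) msg else TRUE
})

#' Contralateral parenchymal enhancement summary
#'
#' The CPE biomarker for one patient: the 90th-percentile threshold of the
#' enhancement distribution, the mean of the top decile (the CPE value
#' itself), the mask size, and (once a cohort has been trichotomised) the
#' tertile label.
#'
#' @slot p90 90th percentile of the enhancement values (unitless).
#' @slot cpe mean of the top 10\% of enhancement values (unitless).
#' @slot nVoxels number of mask voxels summarised.
#' @slot tertile \code{"low"}, \code{"intermediate"}, \code{"high"}, or
#'   \code{NA} before cohort-level assignment.
#' @export
setClass("CpeResult",
  representation(p90 = "numeric", cpe = "numeric", nVoxels = "integer",
                 tertile = "character"),
  prototype(tertile = NA_character_)
)

setValidity("CpeResult", function(object) {
  msg <- character()
  if (object@nVoxels <= 0L) msg <- c(msg, "nVoxels must be positive")
  if (!is.na(object@tertile) &&
      !object@tertile %in% c("low", "intermediate", "high"))
    msg <- c(msg, "tertile must be low/intermediate/high or NA")
  if (length(msg)) msg else TRUE
})

#' Propensity model for CPE tertile membership
#'
#' A three-category multinomial logistic model of tertile membership given
#' the confounders (age and tumour diameter through restricted cubic
#' splines; grade, PR status, nodal category and systemic therapy as
#' factors), with the fitted per-patient probability triples.
#'
#' @slot model the fitted \code{nnet::multinom} object.
#' @slot probabilities n x 3 matrix of membership probabilities
#'   (columns low/intermediate/high; rows sum to 1).
#' @slot levels tertile level names.
#' @slot knots list describing the spline knots used for age and diameter.
#' @export
setClass("PropensityFit",
  representation(model = "ANY", probabilities = "matrix",
                 levels = "character", knots = "list")
)

setValidity("PropensityFit", function(object) {
  p <- object@probabilities
  if (ncol(p) != 3L) return("probabilities must have 3 columns")
  if (any(p <= 0) || any(p >= 1))
    return("each probability must lie strictly in (0,1)")
  if (max(abs(rowSums(p) - 1)) > 1e-6)
    return("per-patient probabilities must sum to 1")
  TRUE
})

#' Weighted Cox model of survival on CPE tertiles
#'
#' Hazard ratios of the intermediate and high tertiles versus the low
#' (reference) tertile from an inverse-probability-weighted Cox
#' proportional hazards fit with robust (sandwich) variance, plus a trend
#' test on the ordinally coded tertile. May be a single fit or the
#' Rubin-pooled combination across multiply imputed datasets.
#'
#' @slot endpoint \code{"idfs"} or \code{"os"}.
#' @slot table data.frame with one row per non-reference tertile:
#'   \code{tertile, logHr, se, hr, lo, hi, p, nEvents, nAtRisk}.
#' @slot reference data.frame with the reference group's
#'   \code{nEvents, nAtRisk}.
#' @slot trend list with \code{coef}, \code{se}, \code{p} for the ordinal
#'   (0/1/2) tertile term.
#' @slot pooled logical; \code{TRUE} for a Rubin-pooled fit.
#' @slot m number of imputations pooled (1 for a single fit).
#' @export
setClass("WeightedCoxFit",
  representation(endpoint = "character", table = "data.frame",
                 reference = "data.frame", trend = "list",
                 pooled = "logical", m = "integer"),
  prototype(pooled = FALSE, m = 1L)
)

setValidity("WeightedCoxFit", function(object) {
  tab <- object@table
  msg <- character()
  if (any(tab$hr <= 0)) msg <- c(msg, "hazard ratios must be positive")
  if (any(tab$lo > tab$hr | tab$hr > tab$hi))
    msg <- c(msg, "confidence limits must bracket the hazard ratio")
  if (length(msg)) msg else TRUE
})

#' Weighted Kaplan-Meier curves with bootstrap bands
#'
#' Per-tertile inverse-probability-weighted Kaplan-Meier step functions
#' with pointwise percentile bootstrap confidence bands, and the cumulative
#' survival at 120 months per group.
#'
#' @slot endpoint \code{"idfs"} or \code{"os"}.
#' @slot curves named list (one per tertile) of data.frames with columns
#'   \code{time, surv, lo, hi}.
#' @slot survAtHorizon data.frame: \code{group, time, surv, lo, hi}.
#' @slot nBoot number of bootstrap resamples.
#' @slot seed RNG seed used for the bootstrap.
#' @export
setClass("WeightedKmFit",
  representation(endpoint = "character", curves = "list",
                 survAtHorizon = "data.frame", nBoot = "integer",
                 seed = "integer")
)

# ---- show methods ---------------------------------------------------------

setMethod("show", "DceSeries", function(object) {
  d <- dim(object@nonFatSat)
  cat(sprintf("DceSeries: %d x %d x %d voxels (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
  cat(sprintf("  cancer laterality: %s; fat-sat time points: %d; %s\n",
              object@laterality, length(object@fatSat),
              if (object@registered) "registered" else "not registered"))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask: %s %s mask, %d voxels%s\n", object@side,
              object@tissue, sum(object@mask),
              if (object@eroded) " (eroded)" else ""))
})

setMethod("show", "CpeResult", function(object) {
  cat(sprintf("CpeResult: CPE = %.3f (p90 = %.3f, n = %d voxels)%s\n",
              object@cpe, object@p90, object@nVoxels,
              if (is.na(object@tertile)) ""
              else sprintf(", tertile = %s", object@tertile)))
})

setMethod("show", "WeightedCoxFit", function(object) {
  cat(sprintf("WeightedCoxFit (%s)%s\n", toupper(object@endpoint),
              if (object@pooled)
                sprintf(", pooled over %d imputations", object@m) else ""))
  ref <- object@reference
  cat(sprintf("  low (reference): %d/%d events\n", ref$nEvents, ref$nAtRisk))
  for (i in seq_len(nrow(object@table))) {
    r <- object@table[i, ]
    cat(sprintf("  %s: HR %.2f (%.2f-%.2f), p = %.3g [%d/%d events]\n",
                r$tertile, r$hr, r$lo, r$hi, r$p, r$nEvents, r$nAtRisk))
  }
  cat(sprintf("  trend test: p = %.3g\n", object@trend$p))
})

setMethod("show", "WeightedKmFit", function(object) {
  cat(sprintf("WeightedKmFit (%s), %d bootstrap resamples\n",
              toupper(object@endpoint), object@nBoot))
  s <- object@survAtHorizon
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: S(%g mo) = %.2f (%.2f-%.2f)\n", s$group[i],
                s$time[i], s$surv[i], s$lo[i], s$hi[i]))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for pipeline objects
#'
#' Small accessor generics for the central classes: \code{cpeValue} returns
#' the CPE statistic of a \code{\linkS4class{CpeResult}}; \code{maskArray}
#' the logical array of a \code{\linkS4class{VoxelMask}};
#' \code{hazardRatios} the per-tertile table of a
#' \code{\linkS4class{WeightedCoxFit}}; \code{trendTest} its trend-test
#' summary; \code{voxelSizeMm} the voxel spacing of series or masks.
#'
#' @param object an object of the documented class.
#' @return See each generic's description.
#' @name accessors
#' @aliases cpeValue maskArray hazardRatios trendTest voxelSizeMm
#' @export cpeValue maskArray hazardRatios trendTest voxelSizeMm
NULL

setGeneric("cpeValue", function(object) standardGeneric("cpeValue"))
#' @rdname accessors
setMethod("cpeValue", "CpeResult", function(object) object@cpe)

setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
setMethod("maskArray", "VoxelMask", function(object) object@mask)

setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))
#' @rdname accessors
setMethod("hazardRatios", "WeightedCoxFit", function(object) object@table)

setGeneric("trendTest", function(object) standardGeneric("trendTest"))
#' @rdname accessors
setMethod("trendTest", "WeightedCoxFit", function(object) object@trend)

setGeneric("voxelSizeMm", function(object) standardGeneric("voxelSizeMm"))
#' @rdname accessors
setMethod("voxelSizeMm", "DceSeries", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSizeMm", "VoxelMask", function(object) object@voxelSize)
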