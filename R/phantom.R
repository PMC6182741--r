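#' Specification of a synthetic bilateral-breast DCE-MRI phantom
#'
#' Parameters of the digital phantom: two half-ellipsoid breasts resting on
#' a flat chest-wall slab, with a fibroglandular (parenchymal) compartment
#' of configurable volume fraction embedded in fat. Signal over the five
#' acquisitions (one non-fat-suppressed T1 plus fat-suppressed pre-contrast
#' and three post-contrast volumes) follows a piecewise-linear kinetic
#' curve in the parenchyma, while fat is bright on the non-fat-suppressed
#' volume and non-enhancing. A smooth multiplicative bias field, additive
#' Gaussian noise and inter-timepoint translation can be switched on.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSizeMm numeric(3), mm; default 0.7 x 0.7 x 3.0 (anisotropic
#'   in-plane/slice spacing typical of clinical breast protocols).
#' @slot nTimepoints must be 5 (1 non-fat-sat + 1 pre + 3 post).
#' @slot parenchymaFraction fraction of breast volume that is parenchyma,
#'   in (0,1).
#' @slot kineticParams list with \code{uptake} (relative signal increase
#'   from pre-contrast to first post-contrast in parenchyma) and
#'   \code{late} (relative increase from first to last post-contrast, the
#'   quantity the CPE biomarker measures).
#' @slot biasFieldAmplitude peak deviation of the multiplicative bias
#'   field from 1 (0 disables it).
#' @slot noiseSd additive Gaussian noise SD in signal units (fat signal on
#'   the non-fat-suppressed volume is 1000).
#' @slot motionMm translation magnitude (mm) applied independently to each
#'   post-contrast volume (0 = no motion).
#' @slot laterality side of the (virtual) cancer; the contralateral breast
#'   is analysed.
#' @slot seed RNG seed; identical specs produce bit-identical phantoms.
#' @seealso \code{\link{generatePhantom}}
#' @export
setClass("PhantomSpec",
  representation(
    gridShape          = "integer",
    voxelSizeMm        = "numeric",
    nTimepoints        = "integer",
    parenchymaFraction = "numeric",
    kineticParams      = "list",
    biasFieldAmplitude = "numeric",
    noiseSd            = "numeric",
    motionMm           = "numeric",
    laterality         = "character",
    seed               = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 integers, each >= 8")
  if (any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxel sizes must be positive")
  if (object@nTimepoints != 5L)
    msg <- c(msg, "nTimepoints must be 5 (non-fat-sat + pre + 3 post)")
  if (object@parenchymaFraction <= 0 || object@parenchymaFraction >= 1)
    msg <- c(msg, "parenchymaFraction must lie in (0,1)")
  kp <- object@kineticParams
  if (!all(c("uptake", "late") %in% names(kp)))
    msg <- c(msg, "kineticParams must contain 'uptake' and 'late'")
  else if (kp$uptake < 0)
    msg <- c(msg, "kinetic uptake amplitude must be >= 0")
  if (object@biasFieldAmplitude < 0 || object@noiseSd < 0 ||
      object@motionMm < 0)
    msg <- c(msg, "bias amplitude, noise SD and motion must be >= 0")
  if (!object@laterality %in% c("left", "right"))
    msg <- c(msg, "laterality must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' Constructor with defaults matching the acquisition geometry the pipeline
#' targets: 0.7 x 0.7 x 3.0 mm voxels and five acquisitions. The default
#' kinetic curve gives the parenchyma a 60\% early uptake and a 40\% late
#' enhancement (first to last post-contrast), in the range of the reported
#' cohort median CPE.
#'
#' @param gridShape voxels per axis (default \code{c(64, 64, 20)}).
#' @param voxelSizeMm voxel spacing in mm.
#' @param parenchymaFraction fraction of breast volume that is parenchyma.
#' @param kineticParams list(uptake, late); see
#'   \code{\linkS4class{PhantomSpec}}.
#' @param biasFieldAmplitude peak multiplicative bias deviation.
#' @param noiseSd additive noise SD (signal units).
#' @param motionMm inter-timepoint translation magnitude in mm.
#' @param laterality side of the virtual cancer.
#' @param seed integer RNG seed.
#' @return A validated \code{\linkS4class{PhantomSpec}}.
#' @examples
#' spec <- phantomSpec(gridShape = c(40, 40, 12), noiseSd = 0, seed = 1)
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 20L),
                        voxelSizeMm = c(0.7, 0.7, 3.0),
                        parenchymaFraction = 0.25,
                        kineticParams = list(uptake = 0.6, late = 0.4),
                        biasFieldAmplitude = 0.15,
                        noiseSd = 10,
                        motionMm = 0,
                        laterality = "left",
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      nTimepoints = 5L, parenchymaFraction = parenchymaFraction,
      kineticParams = kineticParams,
      biasFieldAmplitude = biasFieldAmplitude, noiseSd = noiseSd,
      motionMm = motionMm, laterality = laterality,
      seed = as.integer(seed))
}

# reference signal levels (arbitrary units) for the phantom compartments
.phantomSignal <- list(
  nonFatSat = c(fat = 1000, parenchyma = 300, chestWall = 400, bg = 0),
  fatSat    = c(fat = 80,  parenchyma = 300, chestWall = 350, bg = 0)
)

#' Generate a synthetic bilateral DCE-MRI phantom
#'
#' Builds the five volumes of a \code{\linkS4class{DceSeries}} together
#' with the ground truth needed to score every downstream stage. Geometry:
#' a posterior chest-wall slab spanning the full field of view, two
#' anterior half-ellipsoid breasts, and in each breast a central
#' parenchymal blob whose boundary is roughened with smooth random bumps;
#' the parenchyma voxel count is exactly
#' \code{round(parenchymaFraction * breast voxels)} per breast. In the
#' parenchyma, fat-suppressed signal rises by \code{uptake} from
#' pre-contrast to the first post-contrast volume and by \code{late}
#' between the first and last post-contrast volumes (linear in between);
#' fat and chest wall do not enhance. The bias field is a broad Gaussian
#' bump multiplying all volumes; motion translates each post-contrast
#' volume by \code{motionMm} in an in-plane random direction; noise is
#' additive Gaussian.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return list with elements \code{series}
#'   (\code{\linkS4class{DceSeries}}) and \code{truth}
#'   (\code{\linkS4class{GroundTruth}}).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(40, 40, 12), seed = 7))
#' ph$series
#' sum(ph$truth@parenchymaMask)
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  d <- spec@gridShape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)

  # chest-wall slab occupies the posterior 18% of the anterior-posterior axis
  slabFront <- ny - max(2L, round(0.18 * ny)) + 1L
  slab <- array(FALSE, d); slab[, slabFront:ny, ] <- TRUE

  # two half-ellipsoid breasts attached to the slab's anterior face
  centres <- rbind(c(0.27 * nx, slabFront, nz / 2 + 0.5),
                   c(0.73 * nx, slabFront, nz / 2 + 0.5))
  radii <- c(0.21 * nx, 0.80 * (slabFront - 1), 0.42 * nz)
  X <- array(rep(x, times = ny * nz), d)
  Y <- array(rep(rep(y, each = nx), times = nz), d)
  Z <- array(rep(z, each = nx * ny), d)
  inEllipsoid <- function(c0) {
    ((X - c0[1]) / radii[1])^2 + ((Y - c0[2]) / radii[2])^2 +
      ((Z - c0[3]) / radii[3])^2 <= 1 & Y <= c0[2]
  }
  breastL <- inEllipsoid(centres[2, ])  # larger x = patient left
  breastR <- inEllipsoid(centres[1, ])
  breast <- (breastL | breastR) & !slab

  # parenchyma: per breast, rank voxels by ellipsoidal distance from the
  # breast centre plus smooth random bumps, keep exactly round(f * n)
  roughScore <- function(c0, mask) {
    r2 <- ((X - c0[1]) / radii[1])^2 + ((Y - (c0[2] - 0.35 * radii[2])) /
            (0.6 * radii[2]))^2 + ((Z - c0[3]) / radii[3])^2
    bump <- array(0, d)
    for (k in 1:6) {
      bc <- c0 + stats::rnorm(3) * radii * 0.25
      bw <- radii * stats::runif(1, 0.15, 0.3)
      bump <- bump + stats::runif(1, -1, 1) *
        exp(-(((X - bc[1]) / bw[1])^2 + ((Y - bc[2]) / bw[2])^2 +
                ((Z - bc[3]) / bw[3])^2) / 2)
    }
    s <- r2 + 0.15 * bump
    s[!mask] <- Inf
    s
  }
  pickParenchyma <- function(c0, mask) {
    n <- round(spec@parenchymaFraction * sum(mask))
    s <- roughScore(c0, mask)
    keep <- order(as.vector(s))[seq_len(n)]
    out <- array(FALSE, d); out[keep] <- TRUE
    out
  }
  parenchyma <- pickParenchyma(centres[2, ], breastL & breast) |
                pickParenchyma(centres[1, ], breastR & breast)
  fat <- breast & !parenchyma

  # bias field: broad Gaussian bump, strictly positive
  amp <- spec@biasFieldAmplitude
  bc <- c(0.35 * nx, 0.4 * ny, 0.5 * nz)
  bw <- c(0.7 * nx, 0.7 * ny, 0.9 * nz)
  bias <- 1 + amp * exp(-(((X - bc[1]) / bw[1])^2 + ((Y - bc[2]) / bw[2])^2 +
                            ((Z - bc[3]) / bw[3])^2) / 2)

  # compartment signal over time: fat-sat series index 1 = pre, 4 = post3
  sig <- .phantomSignal
  uptake <- spec@kineticParams$uptake
  late <- spec@kineticParams$late
  parTime <- sig$fatSat["parenchyma"] *
    c(1, (1 + uptake) * c(1, 1 + late / 2, 1 + late))
  paint <- function(fatSig, parSig, slabSig) {
    v <- array(0, d)
    v[fat] <- fatSig; v[parenchyma] <- parSig; v[slab] <- slabSig
    v
  }
  nfs <- paint(sig$nonFatSat["fat"], sig$nonFatSat["parenchyma"],
               sig$nonFatSat["chestWall"]) * bias
  fatSat <- lapply(parTime, function(p)
    paint(sig$fatSat["fat"], p, sig$fatSat["chestWall"]) * bias)

  # rigid inter-timepoint motion of the post-contrast volumes (in-plane)
  motion <- matrix(0, 4, 3, dimnames = list(
    c("pre", "post1", "post2", "post3"), c("x", "y", "z")))
  if (spec@motionMm > 0) {
    for (k in 2:4) {
      theta <- stats::runif(1, 0, 2 * pi)
      motion[k, ] <- spec@motionMm * c(cos(theta), sin(theta), 0)
      fatSat[[k]] <- shiftVolume(fatSat[[k]], motion[k, ] / spec@voxelSizeMm)
    }
  }

  if (spec@noiseSd > 0) {
    nfs <- nfs + array(stats::rnorm(prod(d), 0, spec@noiseSd), d)
    fatSat <- lapply(fatSat, function(v)
      v + array(stats::rnorm(prod(d), 0, spec@noiseSd), d))
  }

  series <- new("DceSeries", nonFatSat = nfs, fatSat = fatSat,
                voxelSize = spec@voxelSizeMm, laterality = spec@laterality,
                registered = spec@motionMm == 0, transforms = list())
  truth <- new("GroundTruth", breastMask = breast, fatMask = fat,
               parenchymaMask = parenchyma, trueEnhancement = late,
               trueBiasField = bias, motionMm = motion)
  list(series = series, truth = truth)
}
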