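#' Write a DCE series to NIfTI files
#'
#' Writes the five volumes as compressed NIfTI (.nii.gz) with the voxel
#' spacing in the header: \code{<prefix>_nonfatsat.nii.gz},
#' \code{<prefix>_fatsat_pre.nii.gz} and
#' \code{<prefix>_fatsat_post1..3.nii.gz}.
#'
#' @param series a \code{\linkS4class{DceSeries}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"series"}).
#' @return invisibly, the vector of written paths.
#' @export
writeDceSeries <- function(series, dir, prefix = "series") {
  stopifnot(is(series, "DceSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- c(list(series@nonFatSat), series@fatSat)
  names(vols) <- c("nonfatsat", "fatsat_pre", "fatsat_post1",
                   "fatsat_post2", "fatsat_post3")
  paths <- file.path(dir, paste0(prefix, "_", names(vols), ".nii.gz"))
  for (i in seq_along(vols)) {
    im <- RNifti::asNifti(vols[[i]])
    RNifti::pixdim(im) <- series@voxelSize
    RNifti::writeNifti(im, paths[i])
  }
  invisible(paths)
}

#' Read a DCE series from NIfTI files
#'
#' @param nonFatSatPath path to the non-fat-suppressed T1 volume.
#' @param fatSatPaths character(4): pre-contrast then three post-contrast
#'   fat-suppressed volumes, in acquisition order.
#' @param laterality side of the known cancer (\code{"left"}/\code{"right"}).
#' @param registered whether the volumes are already co-registered.
#' @return a \code{\linkS4class{DceSeries}}; voxel spacing is read from
#'   the NIfTI header of the non-fat-suppressed volume.
#' @export
readDceSeries <- function(nonFatSatPath, fatSatPaths, laterality,
                          registered = FALSE) {
  stopifnot(length(fatSatPaths) == 4L)
  nfs <- RNifti::readNifti(nonFatSatPath)
  vox <- RNifti::pixdim(nfs)[1:3]
  fatSat <- lapply(fatSatPaths, function(p)
    array(as.numeric(RNifti::readNifti(p)), dim(nfs)))
  new("DceSeries", nonFatSat = array(as.numeric(nfs), dim(nfs)),
      fatSat = fatSat, voxelSize = as.numeric(vox),
      laterality = laterality, registered = registered,
      transforms = list())
}

#' Write / read a binary mask as NIfTI (uint8)
#'
#' @param mask a \code{\linkS4class{VoxelMask}}.
#' @param path output path (.nii.gz).
#' @return \code{writeMask}: invisibly, the path. \code{readMask}: a
#'   \code{\linkS4class{VoxelMask}}.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VoxelMask"))
  im <- RNifti::asNifti(array(as.integer(mask@mask), dim(mask@mask)))
  RNifti::pixdim(im) <- mask@voxelSize
  RNifti::writeNifti(im, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @param side,tissue,eroded mask metadata (not stored in NIfTI).
#' @export
readMask <- function(path, side, tissue = "parenchyma", eroded = FALSE) {
  im <- RNifti::readNifti(path)
  new("VoxelMask", mask = array(as.integer(im) > 0, dim(im)), side = side,
      tissue = tissue, eroded = eroded,
      voxelSize = as.numeric(RNifti::pixdim(im)[1:3]))
}

#' Write / read a cohort table as CSV
#'
#' Plain-text round trip of the patient-level table; \code{readCohort}
#' restores the documented factor columns (\code{pr_status},
#' \code{nodes_cat}, \code{therapy}, \code{menopausal_status},
#' \code{tertile}) with their canonical level order.
#'
#' @param records cohort data.frame (columns as documented in
#'   \code{\link{generateCohort}}).
#' @param path CSV path.
#' @return \code{writeCohort}: invisibly, the path. \code{readCohort}: the
#'   cohort data.frame.
#' @export
writeCohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lv <- list(pr_status = c("neg", "pos"), nodes_cat = c("0", "1-3", "4+"),
             therapy = c("none", "endocrine", "chemo", "both"),
             menopausal_status = c("pre", "peri", "post"),
             tertile = c("low", "intermediate", "high"))
  for (v in names(lv))
    if (v %in% names(d)) d[[v]] <- factor(d[[v]], levels = lv[[v]])
  d
}
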