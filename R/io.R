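#' @importFrom RNifti readNifti writeNifti asNifti pixdim xform
NULL

grid_from_nifti <- function(img) {
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), " dimensions")
  aff <- RNifti::xform(img)
  image_grid(shape = d,
             spacing = abs(RNifti::pixdim(img))[1:3],
             origin = aff[1:3, 4])
}

nifti_from_grid <- function(values, grid, datatype = "double") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::`qform<-`(img, structure(aff, code = 2L))
}

#' Read an SUV volume from a NIfTI file
#'
#' Grid spacing and origin are taken from the file header. Negative values are
#' rejected (SUV is non-negative by definition) with a count of offending
#' voxels.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [suv_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  suv_volume(array(as.numeric(img), dim = dim(img)), grid_from_nifti(img))
}

#' Read an ROI mask from a NIfTI file
#'
#' The file must contain only values 0 and 1 (stored as any numeric type).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param label label to attach to the mask.
#' @return An [roi_mask].
#' @export
read_mask <- function(path, label = "ROI") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  if (!all(v %in% c(0, 1)))
    stop("mask file contains values other than 0/1: ", path)
  roi_mask(v == 1, grid_from_nifti(img), label = label)
}

#' Write a volume, dose map or mask to a NIfTI file
#'
#' SUV volumes and dose maps are stored as 64-bit floats; masks as 8-bit
#' integers with values 0/1. The written file round-trips through
#' [read_volume]/[read_mask] with identical shape and values.
#'
#' @param x an [suv_volume], `dose_map` or [roi_mask].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return invisibly `path`.
#' @export
write_volume <- function(x, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (inherits(x, "roi_mask")) {
    img <- nifti_from_grid(array(as.integer(x$member), dim = dim(x$member)), x$grid)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (inherits(x, "suv_volume")) {
    RNifti::writeNifti(nifti_from_grid(x$values, x$grid), path, datatype = "double")
  } else if (inherits(x, "dose_map")) {
    RNifti::writeNifti(nifti_from_grid(x$dose, x$grid), path, datatype = "double")
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Write a dose-level label volume to NIfTI
#'
#' Encodes a `dose_level_set` as a single integer volume: 0 outside any level
#' (GTV base / background) and k for voxels in level k.
#'
#' @param levels a `dose_level_set`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_level_labels <- function(levels, path) {
  lab <- array(0L, dim = levels$grid$shape)
  for (k in seq_len(levels$n_levels)) lab[levels$level_masks[[k]]$member] <- k
  img <- nifti_from_grid(lab, levels$grid)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
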