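#' Voxel grid geometry
#'
#' An `image_grid` records the geometry shared by all volumes of a case:
#' the number of voxels per axis, the voxel spacing in mm, and the world
#' coordinate of the first voxel. All internal computation works in 0-based
#' voxel indices; world coordinates appear only at the NIfTI boundary.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, world position (mm) of voxel
#'   (0,0,0). Default `c(0, 0, 0)`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (any(shape < 1L)) stop("all shape components must be >= 1")
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, %s mm spacing, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param grid an `image_grid`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

grid_of <- function(x) {
  if (inherits(x, "image_grid")) return(x)
  g <- x$grid
  if (!inherits(g, "image_grid")) stop("object does not carry an image_grid")
  g
}

#' Assert that two gridded objects live on the same voxel grid
#'
#' Shapes must agree exactly; spacing and origin within 1e-6 mm (float header
#' round-trip noise). Co-registration/resampling is out of scope: inputs are
#' assumed already co-registered, this only verifies grid identity.
#'
#' @param a,b objects carrying an `image_grid` (or grids themselves).
#' @return invisibly `TRUE`; raises an error naming the first differing field.
#' @export
assert_same_grid <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  tol <- 1e-6
  if (!identical(ga$shape, gb$shape))
    stop(sprintf("grid mismatch in shape: (%s) vs (%s)",
                 paste(ga$shape, collapse = ","), paste(gb$shape, collapse = ",")))
  if (any(abs(ga$spacing - gb$spacing) > tol))
    stop(sprintf("grid mismatch in spacing: (%s) vs (%s) mm",
                 paste(ga$spacing, collapse = ","), paste(gb$spacing, collapse = ",")))
  if (any(abs(ga$origin - gb$origin) > tol))
    stop(sprintf("grid mismatch in origin: (%s) vs (%s) mm",
                 paste(ga$origin, collapse = ","), paste(gb$origin, collapse = ",")))
  invisible(TRUE)
}

#' Standardized uptake value (SUV) volume
#'
#' A 3D scalar field of dimensionless SUV on a voxel grid. SUV must be
#' non-negative everywhere.
#'
#' @param values numeric 3D array matching `grid$shape`.
#' @param grid an `image_grid`.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, grid) {
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("value array shape does not equal grid shape")
  n_neg <- sum(values < 0)
  if (n_neg > 0)
    stop(sprintf("SUV must be non-negative: %d offending voxel(s)", n_neg))
  structure(list(grid = grid, values = values), class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("suv_volume: %s voxels, SUV range [%.3g, %.3g]\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A boolean field on a voxel grid with a short label (e.g. "GTV", "muscle").
#'
#' @param member logical 3D array matching `grid$shape`.
#' @param grid an `image_grid`.
#' @param label short text label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(member, grid, label = "ROI") {
  member <- array(as.logical(member), dim = dim(as.array(member)))
  if (!identical(dim(member), as.integer(grid$shape)))
    stop("mask array shape does not equal grid shape")
  if (anyNA(member)) stop("mask contains NA")
  structure(list(grid = grid, member = member, label = as.character(label)),
            class = "roi_mask")
}

#' Number of voxels in a mask
#' @param mask an `roi_mask`.
#' @return integer count of `TRUE` voxels.
#' @export
voxel_count <- function(mask) sum(mask$member)

#' Mask volume in ccm (cm^3)
#' @param mask an `roi_mask`.
#' @return volume in ccm: voxel count times voxel volume / 1000.
#' @export
volume_ccm <- function(mask) voxel_count(mask) * voxel_volume_mm3(mask$grid) / 1000

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels, %.1f ccm\n",
              x$label, voxel_count(x), volume_ccm(x)))
  invisible(x)
}
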