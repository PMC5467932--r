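#' Construct a voxel grid
#'
#' A `voxel_grid` is the raster substrate shared by every volume in a study:
#' PET activity (kBq/mL), CT attenuation (HU), SUV images, and binary masks
#' all live on the same lattice. Axes follow a fixed anatomical order:
#' x = left to right, y = posterior to anterior, z = inferior to superior,
#' with 0-based voxel indices mapping to physical millimetres through
#' `origin + index * spacing` (voxel-centre convention).
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3, millimetres per voxel along x, y, z;
#'   must be strictly positive.
#' @param origin numeric length-3, millimetre coordinate of the centre of
#'   voxel (0, 0, 0).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    d[1], d[2], d[3],
    paste(format(x$spacing), collapse = " x "),
    paste(format(x$origin), collapse = ", ")
  ))
  cat(sprintf("  value range: [%g, %g]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Volume of one voxel in millilitres
#' @param grid a [voxel_grid()].
#' @return scalar, mL per voxel.
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  prod(grid$spacing) / 1000
}

#' Check that two grids share the same lattice
#'
#' All volumes of one subject (PET frames, CT, SUV, masks) must share shape,
#' spacing and origin; cross-volume operations refuse mismatched lattices.
#'
#' @param a,b [voxel_grid()] objects.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_same_lattice <- function(a, b) {
  stopifnot(is_voxel_grid(a), is_voxel_grid(b))
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("voxel grids do not share the same lattice (shape/spacing/origin)",
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a binary mask grid
#'
#' Masks are stored as full-grid volumes containing only 0 and 1 (the raster
#' equivalent of a drawn 3D contour).
#'
#' @param mask a [voxel_grid()].
#' @param allow_empty if `FALSE`, an all-zero mask is an error.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_mask <- function(mask, allow_empty = TRUE) {
  stopifnot(is_voxel_grid(mask))
  v <- mask$values
  if (!all(v == 0 | v == 1))
    stop("mask contains values other than {0, 1}", call. = FALSE)
  if (!allow_empty && sum(v) == 0)
    stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

#' Mean of a volume inside a mask
#' @param grid value volume ([voxel_grid()]).
#' @param mask binary mask on the same lattice.
#' @return scalar mean over mask voxels.
#' @export
masked_mean <- function(grid, mask) {
  assert_same_lattice(grid, mask)
  assert_mask(mask, allow_empty = FALSE)
  mean(grid$values[mask$values == 1])
}

#' Maximum of a volume inside a mask
#' @inheritParams masked_mean
#' @return scalar maximum over mask voxels.
#' @export
masked_max <- function(grid, mask) {
  assert_same_lattice(grid, mask)
  assert_mask(mask, allow_empty = FALSE)
  max(grid$values[mask$values == 1])
}

#' Number of voxels set in a mask
#' @param mask binary mask.
#' @return integer count.
#' @export
mask_count <- function(mask) {
  assert_mask(mask)
  sum(mask$values == 1)
}

## Build a grid that shares a lattice with `grid` but holds new values.
grid_like <- function(grid, values) {
  voxel_grid(values, spacing = grid$spacing, origin = grid$origin)
}

## Physical voxel-centre coordinate arrays (mm) along each axis, as vectors
## indexed like the value array's dimnames would be.
axis_coords <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(k) grid$origin[k] + (seq_len(d[k]) - 1) * grid$spacing[k])
}
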