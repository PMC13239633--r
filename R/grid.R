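#' Define a volume sampling grid
#'
#' A `grid_spec` records the voxel lattice shared by all volumes in an
#' analysis: the number of voxels along each axis, the (isotropic) voxel
#' edge length, and the z-coordinate of the centre of the first axial
#' slice. Axial slice `k` (1-based) then has voxel-centre coordinate
#' `z_origin_mm + (k - 1) * voxel_size_mm`, the convention used when
#' restricting tract measurements to the internal-capsule slab.
#'
#' @param dims integer vector of length 3; voxel counts per axis (each >= 16).
#' @param voxel_size_mm positive scalar voxel edge length in mm.
#' @param z_origin_mm z-coordinate (mm) of the voxel centres of the first
#'   axial slice.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(48, 48, 48), 2, -40)
#' range(voxel_z_mm(g))
#' @export
grid_spec <- function(dims, voxel_size_mm, z_origin_mm) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)))
    stop("`dims` must be three voxel counts")
  if (any(dims < 16L))
    stop("grid too small: all dims must be >= 16, got ",
         paste(dims, collapse = "x"))
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar")
  if (!is.numeric(z_origin_mm) || length(z_origin_mm) != 1L ||
      !is.finite(z_origin_mm))
    stop("`z_origin_mm` must be a finite scalar")
  structure(list(dims = dims,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 z_origin_mm = as.numeric(z_origin_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels @ %g mm, z origin %g mm (z in [%g, %g])\n",
              paste(x$dims, collapse = " x "), x$voxel_size_mm, x$z_origin_mm,
              min(voxel_z_mm(x)), max(voxel_z_mm(x))))
  invisible(x)
}

#' Voxel-centre z coordinates of each axial slice
#'
#' @param grid a [grid_spec()].
#' @return Numeric vector of length `grid$dims[3]`, in mm.
#' @export
voxel_z_mm <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$z_origin_mm + (seq_len(grid$dims[3]) - 1L) * grid$voxel_size_mm
}

#' Axial slices whose voxel centres fall inside a z slab
#'
#' Inclusive at both ends on voxel-centre coordinates.
#'
#' @param grid a [grid_spec()].
#' @param slab_mm numeric length 2, `c(lo, hi)` in mm.
#' @return Integer vector of slice indices (possibly empty).
#' @export
slab_slices <- function(grid, slab_mm = c(-5, 12)) {
  z <- voxel_z_mm(grid)
  which(z >= slab_mm[1] & z <= slab_mm[2])
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$z_origin_mm, b$z_origin_mm))
}
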