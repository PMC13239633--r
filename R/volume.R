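#' Construct a scalar volume on a grid
#'
#' The container for quantitative anisotropy (QA) and CSF-normalized QA
#' (nQA) maps: a 3-D numeric array tied to a [grid_spec()]. Values must be
#' finite except for `NA`, which is reserved as the explicit no-data
#' sentinel used off-skeleton after projection (never 0, which would bias
#' downstream means).
#'
#' @param values numeric 3-D array.
#' @param grid a [grid_spec()] whose `dims` match `dim(values)`.
#' @return An object of class `qa_volume` with elements `values` and `grid`.
#' @export
qa_volume <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("dim(values) does not match grid dims")
  if (any(is.infinite(values)))
    stop("volume values must be finite (NA allowed as no-data)")
  structure(list(values = values, grid = grid), class = "qa_volume")
}

#' @export
print.qa_volume <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("qa_volume: %s voxels @ %g mm; %d defined voxels, range [%.4g, %.4g]\n",
              paste(x$grid$dims, collapse = " x "), x$grid$voxel_size_mm,
              length(v), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Bundle the masks used by normalization and projection
#'
#' @param csf logical array; ventricular CSF used as the normalization
#'   reference.
#' @param skeleton logical array; one-voxel-thick white-matter skeleton.
#' @param white_matter logical array; search region for projection.
#' @param lesion optional logical array; voxels excluded from the
#'   projection search.
#' @param grid a [grid_spec()].
#' @return An object of class `mask_set`.
#' @details Invariants enforced: all masks share the grid, CSF and white
#'   matter are disjoint, and the skeleton is contained in white matter.
#' @export
mask_set <- function(csf, skeleton, white_matter, lesion = NULL, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  chk <- function(m, nm) {
    if (!is.logical(m) || !identical(as.integer(dim(m)), grid$dims))
      stop("mask `", nm, "` must be a logical array matching the grid")
    m
  }
  csf <- chk(csf, "csf"); skeleton <- chk(skeleton, "skeleton")
  white_matter <- chk(white_matter, "white_matter")
  if (!is.null(lesion)) lesion <- chk(lesion, "lesion")
  if (any(csf & white_matter))
    stop("csf and white_matter masks overlap")
  if (any(skeleton & !white_matter))
    stop("skeleton mask extends outside white_matter")
  structure(list(csf = csf, skeleton = skeleton,
                 white_matter = white_matter, lesion = lesion, grid = grid),
            class = "mask_set")
}

## ---- NIfTI-1 I/O (RNifti) ----------------------------------------------

grid_to_xform <- function(grid) {
  m <- diag(c(rep(grid$voxel_size_mm, 3), 1))
  m[3, 4] <- grid$z_origin_mm
  m
}

#' Write a volume as NIfTI-1
#'
#' Voxel size goes to pixdim and the z origin to the sform offset, so that
#' [read_volume()] round-trips the grid.
#'
#' @param vol a [qa_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "qa_volume"))
  v <- vol$values
  img <- RNifti::asNifti(v, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid_to_xform(vol$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path file path.
#' @return A [qa_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D volume in ", path)
  vs <- RNifti::pixdim(img)[1]
  xf <- RNifti::xform(img)
  qa_volume(array(as.numeric(img), dim = d), grid_spec(d, vs, xf[3, 4]))
}

#' @rdname write_volume
#' @param mask logical array on `grid`.
#' @param grid a [grid_spec()].
#' @export
write_mask <- function(mask, grid, path) {
  write_volume(qa_volume(array(as.numeric(mask), dim = grid$dims), grid), path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  list(mask = array(v$values > 0.5, dim = v$grid$dims), grid = v$grid)
}

## RNG hygiene: run `expr` under a fixed seed without disturbing the
## caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a per-participant substream seed from a master seed so cohorts
## are reproducible under reordering. Kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}
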