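#' Normalize QA by the ventricular CSF mean
#'
#' Divides voxel-wise QA by the mean QA within the ventricular CSF mask of
#' the same scan, yielding nQA. CSF is used as the reference because its
#' signal variation is acquisition-related rather than pathological, so
#' any multiplicative scanner gain cancels exactly.
#'
#' @param qa a [qa_volume()] of raw QA values.
#' @param csf logical array (CSF mask) on the same grid, or a
#'   [mask_set()].
#' @return A [qa_volume()] of nQA values on the same grid.
#' @examples
#' g <- grid_spec(c(16, 16, 16), 2, -16)
#' qa <- qa_volume(array(2, g$dims), g)
#' csf <- array(FALSE, g$dims); csf[1:2, 1:2, 1:2] <- TRUE
#' range(normalize_qa(qa, csf)$values)  # 1 everywhere
#' @export
normalize_qa <- function(qa, csf) {
  stopifnot(inherits(qa, "qa_volume"))
  if (inherits(csf, "mask_set")) csf <- csf$csf
  if (!is.logical(csf) || !identical(dim(csf), dim(qa$values)))
    stop("`csf` must be a logical mask on the same grid")
  if (!any(csf)) stop("CSF mask is empty; cannot normalize")
  m <- mean(qa$values[csf], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("mean QA within the CSF mask is not positive (", format(m),
         "); cannot normalize")
  qa_volume(qa$values / m, qa$grid)
}

#' Project nQA onto the white-matter skeleton
#'
#' For each skeleton voxel, takes the maximum nQA over white-matter voxels
#' within a Chebyshev (chessboard) radius, analogous in intent to the
#' TBSS projection step: the local maximum re-centres each participant's
#' bundle core onto the template-space skeleton, absorbing residual rigid
#' misalignment up to the search radius. When a lesion mask is present its
#' voxels are excluded from the search, so necrotic near-zero tissue is
#' never "rescued" by projection — projection corrects misalignment, not
#' damage. Off-skeleton voxels are set to `NA`, the package's explicit
#' no-data sentinel (never 0, which would bias downstream means).
#'
#' @param nqa a [qa_volume()] of nQA values.
#' @param masks a [mask_set()] with non-empty skeleton.
#' @param search_radius_vox non-negative integer Chebyshev radius
#'   (default 2).
#' @return A [qa_volume()] defined (non-`NA`) only on skeleton voxels.
#' @export
project_to_skeleton <- function(nqa, masks, search_radius_vox = 2L) {
  stopifnot(inherits(nqa, "qa_volume"), inherits(masks, "mask_set"))
  if (!same_grid(nqa$grid, masks$grid))
    stop("nqa and masks are on different grids")
  r <- as.integer(search_radius_vox)
  if (is.na(r) || r < 0) stop("search_radius_vox must be >= 0")
  if (!any(masks$skeleton)) stop("skeleton mask is empty")

  d <- nqa$grid$dims
  skel_idx <- which(masks$skeleton, arr.ind = TRUE)
  searchable <- masks$white_matter
  if (!is.null(masks$lesion)) searchable <- searchable & !masks$lesion

  best <- rep(NA_real_, nrow(skel_idx))
  for (sx in -r:r) for (sy in -r:r) for (sz in -r:r) {
    cand <- skel_idx + rep(c(sx, sy, sz), each = nrow(skel_idx))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    ok[ok] <- searchable[cand[ok, , drop = FALSE]]
    v <- rep(NA_real_, nrow(skel_idx))
    v[ok] <- nqa$values[cand[ok, , drop = FALSE]]
    best <- pmax(best, v, na.rm = TRUE)
  }
  out <- array(NA_real_, d)
  out[skel_idx] <- best
  qa_volume(out, nqa$grid)
}
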