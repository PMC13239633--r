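#' Parameters for one synthetic participant QA volume
#'
#' Controls the phantom painter: a multiplicative white-matter level, per
#' tract-and-side attenuation (damage) and elevation (upregulation)
#' factors, a global scanner gain applied to the whole volume including
#' CSF, additive voxel noise, an optional rigid integer-voxel
#' misalignment, and an optional spherical lesion zeroed before gain and
#' noise (tissue loss, not acquisition artifact).
#'
#' @param global_scale multiplicative white-matter QA level (CSF is not
#'   scaled by it, so it moves global nQA).
#' @param tract_attenuation named numeric in `[0, 1]` over
#'   `crst_left`, `crst_right`, `cst_left`, `cst_right` (1 = intact).
#' @param tract_elevation named numeric `>= 1` over the same keys.
#' @param tract_scale named numeric `> 0`; extra per-tract multiplier used
#'   by the cohort generator to plant the control tract-vs-global
#'   regression structure. Default 1.
#' @param scanner_gain positive global multiplicative factor.
#' @param noise_sd additive Gaussian SD on voxel values (>= 0).
#' @param misalignment_vox integer length-3 rigid shift, in voxels,
#'   applied to the painted volume relative to template space.
#' @param lesion_center,lesion_radius_mm optional sphere (voxel indices /
#'   mm) zeroed before gain and noise.
#' @param background_level white-matter background value; defaults to the
#'   template set's calibrated level.
#' @param seed RNG seed for the noise field.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(global_scale = 1,
                           tract_attenuation = NULL,
                           tract_elevation = NULL,
                           tract_scale = NULL,
                           scanner_gain = 1,
                           noise_sd = 0,
                           misalignment_vox = c(0L, 0L, 0L),
                           lesion_center = NULL,
                           lesion_radius_mm = NULL,
                           background_level = NULL,
                           seed = 1L) {
  keys <- c("crst_left", "crst_right", "cst_left", "cst_right")
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, 4), keys)
    if (!is.null(x)) {
      if (is.null(names(x)) || !all(names(x) %in% keys))
        stop("tract factors must be named with: ", paste(keys, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  tract_attenuation <- fill(tract_attenuation, 1)
  tract_elevation <- fill(tract_elevation, 1)
  tract_scale <- fill(tract_scale, 1)
  if (any(tract_attenuation < 0 | tract_attenuation > 1))
    stop("tract_attenuation must lie in [0, 1]")
  if (any(tract_elevation < 1))
    stop("tract_elevation must be >= 1")
  if (any(tract_scale <= 0)) stop("tract_scale must be positive")
  if (scanner_gain <= 0) stop("scanner_gain must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  misalignment_vox <- as.integer(misalignment_vox)
  if (length(misalignment_vox) != 3L || any(is.na(misalignment_vox)))
    stop("misalignment_vox must be three integers")
  structure(list(global_scale = global_scale,
                 tract_attenuation = tract_attenuation,
                 tract_elevation = tract_elevation,
                 tract_scale = tract_scale,
                 scanner_gain = scanner_gain,
                 noise_sd = noise_sd,
                 misalignment_vox = misalignment_vox,
                 lesion_center = lesion_center,
                 lesion_radius_mm = lesion_radius_mm,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

shift_array <- function(a, s, fill = 0) {
  if (all(s == 0L)) return(a)
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    dst[[ax]] <- seq(max(1L, 1L + s[ax]), min(d[ax], d[ax] + s[ax]))
    src[[ax]] <- dst[[ax]] - s[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_mask <- function(mask, r) {
  if (r <= 0L) return(mask)
  out <- mask
  d <- dim(mask)
  for (sx in -r:r) for (sy in -r:r) for (sz in -r:r)
    if (any(c(sx, sy, sz) != 0L))
      out <- out | shift_array(mask, c(sx, sy, sz), fill = FALSE)
  out
}

#' Paint a synthetic participant QA volume
#'
#' Voxel values: `scanner_gain * [csf_level in (dilated) CSF;
#' global_scale * core_level * profile(tract) * factor in bundles;
#' global_scale * background_level in remaining white matter] + noise`,
#' where `factor = tract_scale * attenuation * elevation` and
#' `profile` is the template streamline-count profile normalized to 1 at
#' the bundle core. Where bundles overlap, the larger painted value wins.
#' The CSF value is painted with a small uniform margin around the CSF
#' mask so that integer-voxel misalignments leave the in-mask CSF mean
#' exact. The lesion sphere is zeroed before gain and noise; noise is
#' truncated so QA stays non-negative.
#'
#' @param templates output of [make_templates()] (templates + masks +
#'   levels), or a compatible list.
#' @param params a [phantom_params()].
#' @return A [qa_volume()] of synthetic QA values.
#' @examples
#' tpl <- make_templates(grid_spec(c(48, 48, 48), 2, -40))
#' qa <- make_participant_volume(tpl, phantom_params(noise_sd = 0))
#' @export
make_participant_volume <- function(templates, params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  grid <- templates$grid
  lv <- templates$levels
  masks <- templates$masks
  d <- grid$dims

  vol <- array(0, d)
  csf_paint <- dilate_mask(masks$csf, lv$geometry$csf_pad)
  vol[csf_paint] <- lv$csf_level

  bundle <- array(0, d)
  for (nm in names(templates$templates)) {
    tt <- templates$templates[[nm]]
    fam <- tolower(tt$name)
    prof <- tt$streamline_counts$values / max(tt$streamline_counts$values)
    fac <- params$tract_scale[nm] * params$tract_attenuation[nm] *
      params$tract_elevation[nm]
    bundle <- pmax(bundle,
                   params$global_scale * lv$core_level[fam] * prof * fac)
  }
  bg_level <- if (is.null(params$background_level)) lv$background_level else
    params$background_level
  wm_vals <- ifelse(bundle > 0, bundle, params$global_scale * bg_level)
  vol[masks$white_matter] <- wm_vals[masks$white_matter]

  if (!is.null(params$lesion_center)) {
    ctr <- params$lesion_center
    r_vox <- params$lesion_radius_mm / grid$voxel_size_mm
    co <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
    les <- (co$i - ctr[1])^2 + (co$j - ctr[2])^2 + (co$k - ctr[3])^2 <= r_vox^2
    vol[as.matrix(co)[les, , drop = FALSE]] <- 0
  }

  vol <- vol * params$scanner_gain
  vol <- shift_array(vol, params$misalignment_vox, fill = 0)
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
                       array(stats::rnorm(length(vol), 0, params$noise_sd), d))
    vol <- pmax(vol + noise, 0)
  }
  qa_volume(vol, grid)
}
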