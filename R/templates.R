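#' Construct a tract template
#'
#' A normative template for one descending motor tract: a streamline-count
#' volume (each voxel's value is the number of normative streamlines
#' passing through it; used as weights for the tract mean) plus the
#' normative tract volume used for composite corticomotor weighting.
#'
#' @param name `"CRST"` or `"CST"`.
#' @param side `"left"` or `"right"`.
#' @param streamline_counts a [qa_volume()] of non-negative counts.
#' @param normative_volume positive scalar; here the count of voxels with
#'   streamline count > 0 over the whole tract (the slab does not enter).
#' @return An object of class `tract_template`.
#' @export
tract_template <- function(name, side, streamline_counts, normative_volume) {
  name <- match.arg(name, c("CRST", "CST"))
  side <- match.arg(side, c("left", "right"))
  stopifnot(inherits(streamline_counts, "qa_volume"))
  if (any(streamline_counts$values < 0, na.rm = TRUE))
    stop("streamline counts must be non-negative")
  if (!is.numeric(normative_volume) || normative_volume <= 0)
    stop("normative_volume must be positive")
  structure(list(name = name, side = side,
                 streamline_counts = streamline_counts,
                 normative_volume = as.numeric(normative_volume)),
            class = "tract_template")
}

#' @export
print.tract_template <- function(x, ...) {
  cat(sprintf("tract_template: %s %s, %d voxels, normative volume %g\n",
              x$side, x$name, sum(x$streamline_counts$values > 0),
              x$normative_volume))
  invisible(x)
}

## Geometry of the synthetic template space, shared by make_templates()
## and the phantom painter. Bundles are straight vertical tubes with a
## Gaussian in-plane streamline-density profile; CRST medial, CST lateral.
template_geometry <- function(grid) {
  d <- grid$dims
  cx <- as.integer(round(d[1] / 2)); cy <- as.integer(round(d[2] / 2))
  dx_crst <- max(3L, as.integer(round(0.12 * d[1])))
  dx_cst  <- max(6L, as.integer(round(0.25 * d[1])))
  list(
    cx = cx, cy = cy,
    cores = list(
      crst_left  = c(cx - dx_crst, cy),
      crst_right = c(cx + dx_crst, cy),
      cst_left   = c(cx - dx_cst, cy),
      cst_right  = c(cx + dx_cst, cy)),
    sigma = c(crst = 1.6, cst = 2.2),
    radius = c(crst = 4L, cst = 5L),
    ## control-like core nQA levels (CSF reference value 1)
    core_level = c(crst = 3.25, cst = 4.98),
    ## background WM box and its one-voxel-thick skeleton sheet
    bg_x = (cx - 12L):(cx + 12L), bg_y = (cy + 9L):min(cy + 20L, d[2]),
    sheet_x = (cx - 10L):(cx + 10L), sheet_y = cy + 14L,
    ## ventricular CSF box (painted with a 2-voxel uniform margin, kept
    ## clear of the volume faces so rigid shifts never drag fill values
    ## into the mask)
    csf_x = (cx - 3L):(cx + 3L), csf_y = (cy - 16L):(cy - 10L),
    csf_z = 4L:(d[3] - 3L),
    csf_pad = 2L)
}

gaussian_tube <- function(grid, core_xy, sigma, radius, amplitude) {
  d <- grid$dims
  gx <- outer(seq_len(d[1]) - core_xy[1], seq_len(d[2]) - core_xy[2],
              function(i, j) sqrt(i^2 + j^2))
  plane <- ifelse(gx <= radius, amplitude * exp(-gx^2 / (2 * sigma^2)), 0)
  array(rep(plane, d[3]), dim = d)
}

#' Generate synthetic normative tract templates and analysis masks
#'
#' Builds a self-contained synthetic template space: four streamline-count
#' templates (left/right CRST and CST), a one-voxel-thick white-matter
#' skeleton (the four bundle core lines plus a background sheet), a
#' background white-matter box, and a ventricular CSF box. Bundles are
#' straight vertical tubes with smooth Gaussian streamline-count profiles
#' peaking at the core, so slab-weighted arithmetic downstream is exact
#' and checkable. The CST is larger than the CRST (larger normative
#' volume), mirroring real template sets; real normative templates can be
#' substituted at run time via [read_volume()].
#'
#' @param grid a [grid_spec()] whose axial voxel centres must cover the
#'   internal-capsule slab z in `[-5, 12]` mm.
#' @param seed integer; jitters template amplitudes reproducibly.
#' @return A list with elements `templates` (named list of four
#'   [tract_template()]: `crst_left`, `crst_right`, `cst_left`,
#'   `cst_right`), `masks` (a [mask_set()]), `grid`, and `levels`
#'   (internal painting levels used by [make_participant_volume()]).
#' @examples
#' tpl <- make_templates(grid_spec(c(48, 48, 48), 2, -40), seed = 1)
#' sapply(tpl$templates, function(t) t$normative_volume)
#' @export
make_templates <- function(grid = grid_spec(c(48, 48, 48), 2, -40), seed = 1L) {
  z <- voxel_z_mm(grid)
  if (min(z) > -5 || max(z) < 12)
    stop(sprintf(paste0("grid z range [%g, %g] mm does not cover the ",
                        "internal-capsule slab [-5, 12] mm"), min(z), max(z)))
  geo <- template_geometry(grid)
  d <- grid$dims
  idx <- c(geo$bg_x, geo$sheet_x, geo$csf_x,
           sapply(geo$cores, `[`, 1) + geo$radius["cst"],
           sapply(geo$cores, `[`, 1) - geo$radius["cst"])
  idy <- c(geo$bg_y, geo$sheet_y, geo$csf_y - geo$csf_pad)
  if (min(idx) < 1 || max(idx) > d[1] || min(idy) < 1 || max(idy) > d[2])
    stop("grid too small for the template geometry; use at least 44 voxels ",
         "in x and y")
  amp <- with_seed(seed, stats::runif(4, 0.95, 1.05)) *
    c(crst_left = 40, crst_right = 40, cst_left = 120, cst_right = 120)

  templates <- list()
  wm <- array(FALSE, d)
  skeleton <- array(FALSE, d)
  for (nm in names(geo$cores)) {
    fam <- sub("_.*", "", nm)
    counts <- gaussian_tube(grid, geo$cores[[nm]], geo$sigma[fam],
                            geo$radius[fam], amp[nm])
    templates[[nm]] <- tract_template(
      name = toupper(fam), side = sub(".*_", "", nm),
      streamline_counts = qa_volume(counts, grid),
      normative_volume = sum(counts > 0))
    wm <- wm | (counts > 0)
    skeleton[geo$cores[[nm]][1], geo$cores[[nm]][2], ] <- TRUE
  }

  bg <- array(FALSE, d)
  bg[geo$bg_x, geo$bg_y, ] <- TRUE
  wm <- wm | bg
  skeleton[geo$sheet_x, geo$sheet_y, ] <- TRUE

  csf <- array(FALSE, d)
  csf[geo$csf_x, geo$csf_y, geo$csf_z] <- TRUE

  masks <- mask_set(csf = csf, skeleton = skeleton, white_matter = wm,
                    grid = grid)

  ## background level chosen so the noise-free skeleton mean sits at the
  ## control-like global nQA level 2.658
  n_core <- 4L * d[3]
  n_sheet <- sum(skeleton) - n_core
  bg_level <- (2.658 * sum(skeleton) -
                 d[3] * (2 * geo$core_level["crst"] + 2 * geo$core_level["cst"])) /
    n_sheet
  list(templates = templates, masks = masks, grid = grid,
       levels = list(core_level = geo$core_level, csf_level = 1,
                     background_level = as.numeric(bg_level),
                     global_level = 2.658, geometry = geo))
}
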