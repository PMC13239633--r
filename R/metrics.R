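#' Streamline-weighted tract mean nQA over the internal-capsule slab
#'
#' Weighted mean of skeletonized nQA over skeleton voxels whose axial
#' voxel-centre z falls in the slab (inclusive at both ends), with each
#' voxel weighted by the tract template's streamline count there. The
#' default slab, z in `[-5, 12]` mm of standard space, is the internal
#' capsule region, where descending motor fibres are dense and diffusion
#' distortions are mild.
#'
#' @param skel_nqa a [qa_volume()] from [project_to_skeleton()] (non-`NA`
#'   exactly on skeleton voxels).
#' @param template a [tract_template()] on the same grid.
#' @param slab_mm numeric `c(lo, hi)` in mm; default `c(-5, 12)`.
#' @return Scalar weighted mean nQA.
#' @export
tract_mean_nqa <- function(skel_nqa, template, slab_mm = c(-5, 12)) {
  stopifnot(inherits(skel_nqa, "qa_volume"), inherits(template, "tract_template"))
  if (!same_grid(skel_nqa$grid, template$streamline_counts$grid))
    stop("volume and template are on different grids")
  ks <- slab_slices(skel_nqa$grid, slab_mm)
  w <- template$streamline_counts$values
  v <- skel_nqa$values
  keep <- array(FALSE, dim(v)); keep[, , ks] <- TRUE
  sel <- keep & !is.na(v) & w > 0
  tw <- sum(w[sel])
  if (tw <= 0)
    stop(sprintf("no skeleton voxels with positive streamline weight for %s %s in slab [%g, %g] mm",
                 template$side, template$name, slab_mm[1], slab_mm[2]))
  sum(w[sel] * v[sel]) / tw
}

#' Global mean white-matter nQA
#'
#' Unweighted mean of skeletonized nQA over all skeleton voxels; the
#' participant-level covariate used to adjust tract values.
#'
#' @param skel_nqa a [qa_volume()] from [project_to_skeleton()].
#' @param masks optional [mask_set()]; defaults to the non-`NA` voxels of
#'   `skel_nqa`.
#' @return Scalar mean nQA.
#' @export
global_wm_nqa <- function(skel_nqa, masks = NULL) {
  stopifnot(inherits(skel_nqa, "qa_volume"))
  sel <- if (is.null(masks)) !is.na(skel_nqa$values) else masks$skeleton
  if (!any(sel)) stop("skeleton is empty")
  mean(skel_nqa$values[sel], na.rm = TRUE)
}

#' Adjust a tract nQA value for global white-matter nQA
#'
#' Removes the component of a tract's nQA explained by the participant's
#' global white-matter level, using a control-fitted slope:
#' `adjusted = unadjusted - slope * (global_nqa - control_global_mean)`.
#' The result is the tract value expected for a person with the control
#' cohort's average global nQA, isolating tract-specific deviation.
#'
#' @param unadjusted tract nQA.
#' @param global_nqa the participant's global white-matter nQA.
#' @param slope control-fitted regression slope of tract nQA on global
#'   nQA.
#' @param control_global_mean mean global nQA across controls.
#' @return Adjusted tract nQA (vectorized over its arguments).
#' @examples
#' adjust_tract_nqa(3.0, 3.0, 1.186, 2.658)  # 2.594
#' @export
adjust_tract_nqa <- function(unadjusted, global_nqa, slope, control_global_mean) {
  stopifnot(is.finite(unadjusted), is.finite(global_nqa),
            is.finite(slope), is.finite(control_global_mean))
  unadjusted - slope * (global_nqa - control_global_mean)
}

#' Composite corticomotor strength
#'
#' Weighted average of CRST and CST values, weighted by normative tract
#' volume so the larger CST contributes proportionally more.
#'
#' @param crst_value,cst_value tract values (adjusted nQA).
#' @param weights named numeric `c(crst = , cst = )`, positive, summing
#'   to 1.
#' @return Scalar weighted average.
#' @export
composite_corticomotor <- function(crst_value, cst_value, weights) {
  if (is.null(names(weights))) names(weights) <- c("crst", "cst")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be positive and sum to 1")
  weights[["crst"]] * crst_value + weights[["cst"]] * cst_value
}

#' Convert an adjusted tract value to a control-referenced z-score
#'
#' @param adjusted adjusted tract nQA.
#' @param ref_mean,ref_sd control mean and SD of the adjusted value for
#'   that tract role; `ref_sd` must be positive.
#' @return `(adjusted - ref_mean) / ref_sd`.
#' @export
tract_zscore <- function(adjusted, ref_mean, ref_sd) {
  if (!is.numeric(ref_sd) || any(ref_sd <= 0))
    stop("ref_sd must be positive")
  (adjusted - ref_mean) / ref_sd
}

#' Assign left/right tract values to ipsi/contralesional roles
#'
#' For stroke participants the ipsilesional side is the lesion side; for
#' controls it is the lesion side of the matched stroke partner (sharing
#' `pair_id`), so control "ipsilesional" values are side-matched to their
#' counterpart.
#'
#' @param values data.frame with columns `id`, `crst_left`, `crst_right`,
#'   `cst_left`, `cst_right` (and optionally others, carried through).
#' @param cohort data.frame with columns `id`, `group`, `pair_id`,
#'   `lesion_side`.
#' @return `values` with added columns `icrst`, `ccrst`, `icst`, `ccst`
#'   and `ipsi_side`.
#' @export
assign_laterality <- function(values, cohort) {
  need <- c("id", "crst_left", "crst_right", "cst_left", "cst_right")
  if (!all(need %in% names(values)))
    stop("`values` must have columns: ", paste(need, collapse = ", "))
  m <- match(values$id, cohort$id)
  if (anyNA(m)) stop("ids missing from cohort table: ",
                     paste(values$id[is.na(m)], collapse = ", "))
  co <- cohort[m, ]
  ipsi <- character(nrow(co))
  for (i in seq_len(nrow(co))) {
    if (co$group[i] == "stroke") {
      ipsi[i] <- co$lesion_side[i]
    } else {
      partner <- cohort[cohort$pair_id == co$pair_id[i] &
                          cohort$group == "stroke", ]
      if (nrow(partner) != 1L || !partner$lesion_side %in% c("left", "right"))
        stop("control ", co$id[i],
             " has no matched stroke partner with a lesion side")
      ipsi[i] <- partner$lesion_side
    }
  }
  contra <- ifelse(ipsi == "left", "right", "left")
  pick <- function(fam, side)
    mapply(function(i, s) values[[paste0(fam, "_", s)]][i],
           seq_len(nrow(values)), side)
  values$ipsi_side <- ipsi
  values$icrst <- pick("crst", ipsi)
  values$ccrst <- pick("crst", contra)
  values$icst <- pick("cst", ipsi)
  values$ccst <- pick("cst", contra)
  values
}

#' Fit the control reference model
#'
#' Fits, on control participants only, the linear regressions of
#' tract-specific nQA (averaged across left and right) on global nQA —
#' one slope per tract family — then derives everything needed to score
#' any participant against the control cohort: the control global mean,
#' per-role mean and SD of adjusted nQA, and composite corticomotor
#' weights from template normative volumes (averaged across sides per
#' family).
#'
#' @param controls data.frame of control participants with columns
#'   `global_nqa`, `crst_left`, `crst_right`, `cst_left`, `cst_right`,
#'   `icrst`, `ccrst`, `icst`, `ccst` (see [assign_laterality()]).
#' @param templates named list of four [tract_template()] (or the output
#'   of [make_templates()]); used only for normative-volume weights.
#' @return An object of class `reference_model`: `slopes`, `r2`,
#'   `control_global_mean`, `composite_weights`, `tract_stats`
#'   (data.frame role/mean/sd), `n_controls`.
#' @export
fit_reference <- function(controls, templates) {
  if (!is.null(templates$templates)) templates <- templates$templates
  if (nrow(controls) < 3) stop("need at least 3 controls to fit a reference")
  if (stats::sd(controls$global_nqa) == 0)
    stop("zero variance in control global nQA; cannot fit slopes")

  slopes <- r2 <- c(crst = NA_real_, cst = NA_real_)
  for (fam in c("crst", "cst")) {
    y <- (controls[[paste0(fam, "_left")]] + controls[[paste0(fam, "_right")]]) / 2
    f <- stats::lm(y ~ controls$global_nqa)
    slopes[fam] <- stats::coef(f)[2]
    r2[fam] <- suppressWarnings(summary(f)$r.squared)
  }
  g0 <- mean(controls$global_nqa)

  nv <- sapply(templates, function(t) t$normative_volume)
  fam <- sapply(templates, function(t) tolower(t$name))
  fam_nv <- c(crst = mean(nv[fam == "crst"]), cst = mean(nv[fam == "cst"]))
  w <- fam_nv / sum(fam_nv)

  adj <- data.frame(
    icrst = adjust_tract_nqa(controls$icrst, controls$global_nqa, slopes["crst"], g0),
    ccrst = adjust_tract_nqa(controls$ccrst, controls$global_nqa, slopes["crst"], g0),
    icst = adjust_tract_nqa(controls$icst, controls$global_nqa, slopes["cst"], g0),
    ccst = adjust_tract_nqa(controls$ccst, controls$global_nqa, slopes["cst"], g0))
  adj$icm <- composite_corticomotor(adj$icrst, adj$icst, w)
  adj$ccm <- composite_corticomotor(adj$ccrst, adj$ccst, w)

  ts <- data.frame(role = c("iCRST", "cCRST", "iCST", "cCST",
                            "iCorticomotor", "cCorticomotor"),
                   mean = sapply(adj, mean), sd = sapply(adj, stats::sd),
                   row.names = NULL)
  if (any(ts$sd <= 1e-12 * pmax(1, abs(ts$mean))))
    stop("control adjusted values have zero SD for at least one tract role")
  structure(list(slopes = slopes, r2 = r2, control_global_mean = g0,
                 composite_weights = w, tract_stats = ts,
                 n_controls = nrow(controls)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model (%d controls)\n", x$n_controls))
  cat(sprintf("  slopes: CRST %.3f (r2 %.3f), CST %.3f (r2 %.3f)\n",
              x$slopes["crst"], x$r2["crst"], x$slopes["cst"], x$r2["cst"]))
  cat(sprintf("  control global mean nQA: %.3f\n", x$control_global_mean))
  cat(sprintf("  composite weights: CRST %.3f, CST %.3f\n",
              x$composite_weights["crst"], x$composite_weights["cst"]))
  print(x$tract_stats, row.names = FALSE)
  invisible(x)
}

#' Frozen published-constant reference preset
#'
#' A reference model holding the published normative constants, for
#' worked examples and for scoring new data against the original control
#' cohort: adjustment slopes 1.186 (CRST) and 2.702 (CST) with r2 0.735
#' and 0.883, control global mean nQA 2.658, and the z-score constants
#' per role (means 3.407, 3.093, 5.106, 4.862, 4.023, 3.734; SDs 0.357,
#' 0.272, 0.718, 0.534, 0.145, 0.169). Note: the published per-role
#' control summary SDs (0.14, 0.22, 0.24, 0.24) differ from these z-score
#' denominators; the preset carries the z-score denominators and exposes
#' the summary SDs as `tract_stats$sd_summary`. This preset is never used
#' as a silent default — [fit_reference()] always refits from the
#' supplied controls.
#'
#' @param name preset name; currently only `"published"`.
#' @return A `reference_model`.
#' @examples
#' ref <- reference_preset()
#' tract_zscore(3.365, 3.093, 0.272)  # 1.0
#' @export
reference_preset <- function(name = "published") {
  name <- match.arg(name)
  ts <- data.frame(role = c("iCRST", "cCRST", "iCST", "cCST",
                            "iCorticomotor", "cCorticomotor"),
                   mean = c(3.407, 3.093, 5.106, 4.862, 4.023, 3.734),
                   sd = c(0.357, 0.272, 0.718, 0.534, 0.145, 0.169),
                   sd_summary = c(0.14, 0.22, 0.24, 0.24, 0.14, 0.17))
  structure(list(slopes = c(crst = 1.186, cst = 2.702),
                 r2 = c(crst = 0.735, cst = 0.883),
                 control_global_mean = 2.658,
                 composite_weights = c(crst = 0.38, cst = 0.62),
                 tract_stats = ts, n_controls = 10L, preset = name),
            class = "reference_model")
}

#' Per-participant tract strength records
#'
#' Runs the full tract-strength scoring for every participant: adjusts
#' each role's unadjusted nQA for global nQA with the reference slopes,
#' forms the composite corticomotor values, and z-scores everything
#' against the reference tract statistics.
#'
#' @param values data.frame from [assign_laterality()] with a
#'   `global_nqa` column.
#' @param ref a `reference_model`.
#' @return Tidy data.frame, one row per participant x role, with columns
#'   `id`, `role`, `unadjusted_nqa`, `global_nqa`, `adjusted_nqa`,
#'   `z_score`.
#' @export
compute_tract_strengths <- function(values, ref) {
  stopifnot(inherits(ref, "reference_model"))
  fam_of <- c(iCRST = "crst", cCRST = "crst", iCST = "cst", cCST = "cst")
  col_of <- c(iCRST = "icrst", cCRST = "ccrst", iCST = "icst", cCST = "ccst")
  out <- list()
  adj <- list()
  for (role in names(col_of)) {
    un <- values[[col_of[role]]]
    a <- adjust_tract_nqa(un, values$global_nqa, ref$slopes[fam_of[role]],
                          ref$control_global_mean)
    adj[[role]] <- a
    st <- ref$tract_stats[ref$tract_stats$role == role, ]
    out[[role]] <- data.frame(id = values$id, role = role,
                              unadjusted_nqa = un,
                              global_nqa = values$global_nqa,
                              adjusted_nqa = a,
                              z_score = tract_zscore(a, st$mean, st$sd))
  }
  for (role in c("iCorticomotor", "cCorticomotor")) {
    pre <- if (role == "iCorticomotor") c("iCRST", "iCST") else c("cCRST", "cCST")
    a <- composite_corticomotor(adj[[pre[1]]], adj[[pre[2]]],
                                ref$composite_weights)
    un <- composite_corticomotor(values[[col_of[pre[1]]]],
                                 values[[col_of[pre[2]]]],
                                 ref$composite_weights)
    st <- ref$tract_stats[ref$tract_stats$role == role, ]
    out[[role]] <- data.frame(id = values$id, role = role,
                              unadjusted_nqa = un,
                              global_nqa = values$global_nqa,
                              adjusted_nqa = a,
                              z_score = tract_zscore(a, st$mean, st$sd))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$id, res$role), ]
}
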