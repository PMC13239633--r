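#' Assemble a pipeline run configuration
#'
#' Collects every knob of the simulate -> normalize -> skeletonize ->
#' tracts -> stats pipeline with the analysis defaults: internal-capsule
#' slab `[-5, 12]` mm, projection search radius 2 voxels, pooled-variance
#' t-tests, 10% change-in-estimate threshold, alpha 0.05.
#'
#' @param grid a [grid_spec()] for the synthetic template space.
#' @param cohort a [cohort_params()].
#' @param volume_noise_sd,misalignment,gain_range phantom options passed
#'   to [make_cohort()].
#' @param search_radius_vox projection search radius (voxels).
#' @param slab_mm internal-capsule slab bounds (mm, inclusive).
#' @param use_preset if `TRUE`, score against [reference_preset()] instead
#'   of refitting the control reference (never the default).
#' @param template_paths optional named list of NIfTI paths
#'   (`crst_left`, `crst_right`, `cst_left`, `cst_right`) holding real
#'   streamline-count templates to use instead of synthetic ones.
#' @param var_equal pooled-variance group tests if `TRUE`.
#' @param shrinkage_threshold change-in-estimate threshold (default 0.10).
#' @param alpha significance level.
#' @param write_volumes write per-stage NIfTI volumes (else tables only).
#' @param seed master seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid = grid_spec(c(48, 48, 48), 2, -40),
                       cohort = cohort_params(),
                       volume_noise_sd = 0.05,
                       misalignment = TRUE,
                       gain_range = c(0.85, 1.2),
                       search_radius_vox = 2L,
                       slab_mm = c(-5, 12),
                       use_preset = FALSE,
                       template_paths = NULL,
                       var_equal = TRUE,
                       shrinkage_threshold = 0.10,
                       alpha = 0.05,
                       write_volumes = TRUE,
                       seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cohort, "cohort_params"))
  if (slab_mm[1] > slab_mm[2]) stop("slab_mm must be c(lo, hi)")
  cohort$seed <- as.integer(seed)
  structure(list(grid = grid, cohort = cohort,
                 volume_noise_sd = volume_noise_sd,
                 misalignment = misalignment, gain_range = gain_range,
                 search_radius_vox = as.integer(search_radius_vox),
                 slab_mm = slab_mm, use_preset = use_preset,
                 template_paths = template_paths,
                 var_equal = var_equal,
                 shrinkage_threshold = shrinkage_threshold,
                 alpha = alpha, write_volumes = write_volumes,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), f)
  unname(tools::md5sum(f))
}

load_external_templates <- function(paths, grid) {
  need <- c("crst_left", "crst_right", "cst_left", "cst_right")
  if (!all(need %in% names(paths)))
    stop("template_paths must name: ", paste(need, collapse = ", "))
  out <- list()
  for (nm in need) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("template file not found: ", p)
    v <- read_volume(p)
    if (!same_grid(v$grid, grid))
      stop("template grid mismatch for ", nm, ": ", p)
    out[[nm]] <- tract_template(toupper(sub("_.*", "", nm)),
                                sub(".*_", "", nm), v, sum(v$values > 0))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> normalize -> skeletonize -> tracts -> stats as
#' one deterministic, seeded run, writing all tables, volumes, the report
#' JSON and a provenance record (config digest, package version, file
#' hashes, per-stage wall time) into `out_dir`. When `out_dir` already
#' holds a complete run from an identical configuration, the cached
#' report is returned instead of recomputing.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the report list (also at `out_dir/report.json`):
#'   group comparisons, upregulation model, confounding assessment,
#'   influence report, reference model.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  prov_path <- file.path(out_dir, "provenance.json")
  report_path <- file.path(out_dir, "report.json")
  if (file.exists(prov_path) && file.exists(report_path)) {
    old <- tryCatch(jsonlite::read_json(prov_path), error = function(e) NULL)
    if (!is.null(old) && identical(old$config_digest, digest) &&
        all(file.exists(names(unlist(old$file_md5)))))
      return(invisible(jsonlite::read_json(report_path, simplifyVector = TRUE)))
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, t) timings[[stage]] <<- round(t, 3)

  ## ---- simulate -------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  templates <- if (!is.null(config$template_paths)) {
    base <- make_templates(config$grid, seed = config$seed)
    base$templates <- load_external_templates(config$template_paths, config$grid)
    base
  } else make_templates(config$grid, seed = config$seed)
  sim <- make_cohort(config$cohort, templates = templates,
                     volume_noise_sd = config$volume_noise_sd,
                     misalignment = config$misalignment,
                     gain_range = config$gain_range)
  write_cohort(sim$cohort, config$cohort, file.path(out_dir, "cohort.csv"),
               file.path(out_dir, "generator_params.json"))
  vol_dir <- file.path(out_dir, "volumes")
  if (config$write_volumes) {
    dir.create(vol_dir, showWarnings = FALSE)
    for (nm in names(templates$templates))
      write_volume(templates$templates[[nm]]$streamline_counts,
                   file.path(vol_dir, paste0("template_", nm, ".nii.gz")))
    write_mask(templates$masks$skeleton, config$grid,
               file.path(vol_dir, "mask_skeleton.nii.gz"))
    write_mask(templates$masks$csf, config$grid,
               file.path(vol_dir, "mask_csf.nii.gz"))
    write_mask(templates$masks$white_matter, config$grid,
               file.path(vol_dir, "mask_wm.nii.gz"))
  }
  tick("simulate", proc.time()[["elapsed"]] - ts)

  ## ---- normalize + skeletonize + tract measurement --------------------
  ts <- proc.time()[["elapsed"]]
  rows <- list()
  for (id in sim$cohort$id) {
    qa <- make_participant_volume(templates, sim$phantoms[[id]])
    if (config$write_volumes)
      write_volume(qa, file.path(vol_dir, paste0(id, "_qa.nii.gz")))
    nqa <- normalize_qa(qa, templates$masks)
    skel <- project_to_skeleton(nqa, templates$masks,
                                config$search_radius_vox)
    if (config$write_volumes)
      write_volume(skel, file.path(vol_dir, paste0(id, "_nqa_skel.nii.gz")))
    rows[[id]] <- data.frame(
      id = id,
      global_nqa = global_wm_nqa(skel, templates$masks),
      crst_left = tract_mean_nqa(skel, templates$templates$crst_left, config$slab_mm),
      crst_right = tract_mean_nqa(skel, templates$templates$crst_right, config$slab_mm),
      cst_left = tract_mean_nqa(skel, templates$templates$cst_left, config$slab_mm),
      cst_right = tract_mean_nqa(skel, templates$templates$cst_right, config$slab_mm),
      stringsAsFactors = FALSE)
  }
  side_values <- do.call(rbind, c(rows, make.row.names = FALSE))
  side_values <- assign_laterality(side_values, sim$cohort)
  tick("quantify", proc.time()[["elapsed"]] - ts)

  ## ---- reference + strengths ------------------------------------------
  ts <- proc.time()[["elapsed"]]
  ref <- if (config$use_preset) reference_preset() else
    fit_reference(side_values[sim$cohort$group == "control", ],
                  templates$templates)
  strengths <- compute_tract_strengths(side_values, ref)
  utils::write.csv(strengths, file.path(out_dir, "tract_strengths.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(slopes = as.list(ref$slopes), r2 = as.list(ref$r2),
         control_global_mean = ref$control_global_mean,
         composite_weights = as.list(ref$composite_weights),
         tract_stats = ref$tract_stats, n_controls = ref$n_controls),
    file.path(out_dir, "reference_model.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  tick("tracts", proc.time()[["elapsed"]] - ts)

  ## ---- statistics ------------------------------------------------------
  ts <- proc.time()[["elapsed"]]
  wide <- function(role, what = "z_score") {
    s <- strengths[strengths$role == role, ]
    s[[what]][match(sim$cohort$id, s$id)]
  }
  grp <- sim$cohort$group
  comparisons <- do.call(rbind, lapply(
    unique(strengths$role), function(role) {
      gz <- group_compare(wide(role), grp, var_equal = config$var_equal)
      gn <- group_compare(wide(role, "unadjusted_nqa"), grp,
                          var_equal = config$var_equal)
      data.frame(role = role,
                 stroke_nqa = gn$mean_stroke, control_nqa = gn$mean_control,
                 diff_nqa = gn$difference,
                 diff_nqa_lo = gn$conf_int[1], diff_nqa_hi = gn$conf_int[2],
                 p_nqa = gn$p_value,
                 stroke_z = gz$mean_stroke, diff_z = gz$difference,
                 p_z = gz$p_value)
    }))
  utils::write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)

  icm_z <- wide("iCorticomotor"); ccrst_z <- wide("cCRST")
  walk <- sim$cohort$six_mwd_m
  upreg_model <- fit_linear(ccrst_z, data.frame(icorticomotor = icm_z),
                            ids = sim$cohort$id)
  conf <- assess_confounding(walk, ccrst_z, icm_z,
                             threshold = config$shrinkage_threshold,
                             ids = sim$cohort$id)
  infl <- cooks_influence(conf$model_adjusted)
  tick("stats", proc.time()[["elapsed"]] - ts)

  report <- list(
    seed = config$seed, n_pairs = config$cohort$n_pairs,
    reference = list(slopes = as.list(ref$slopes), r2 = as.list(ref$r2),
                     control_global_mean = ref$control_global_mean),
    upregulation = list(
      coef = upreg_model$coefficients$estimate[2],
      se = upreg_model$coefficients$se[2],
      p = upreg_model$coefficients$p[2]),
    confounding = list(
      unadjusted_coef = conf$unadjusted_coef,
      adjusted_coef = conf$adjusted_coef,
      shrinkage_fraction = conf$shrinkage_fraction,
      threshold = conf$threshold, confounded = conf$confounded,
      unadjusted_r_squared = conf$model_unadjusted$r_squared),
    influence = list(
      threshold = infl$threshold,
      max_cooks_distance = max(infl$cooks_distance),
      flagged = as.character(infl$flagged),
      loo = infl$loo))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "provenance.json"))
  prov <- list(config_digest = digest,
               package_version = as.character(utils::packageVersion("tractconfound")),
               seed = config$seed,
               stage_seconds = timings,
               total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
               file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
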