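#' Parameters of the synthetic stroke/control cohort
#'
#' Encodes the hypothesized causal structure under study: a latent
#' ipsilesional corticomotor deficit `D` (in control-SD units) drives both
#' contralesional CRST upregulation and reduced walking capacity, while
#' the direct effect of cCRST strength on walking (`beta_direct`) defaults
#' to zero — the confounded-null scenario.
#'
#' Defaults emulate the published study conditions: 10 matched pairs,
#' stroke corticomotor deficit 11.25 +/- 3.4 control SDs, upregulation
#' slope 0.12 z per deficit unit, 34 m of 6-min walk distance per
#' corticomotor SD, 537 m control-level intercept, 90 m walking noise.
#'
#' @param n_pairs matched stroke/control pairs (>= 2).
#' @param damage_mean,damage_sd distribution of the latent deficit `D`
#'   (truncated at 0), in control-SD units of composite corticomotor
#'   strength.
#' @param delta_upreg coefficient from `D` to cCRST strength (z units per
#'   deficit unit).
#' @param gamma_walk coefficient from ipsilesional corticomotor strength
#'   to 6-min walk distance (m per SD).
#' @param beta_direct direct effect of cCRST strength on 6MWD (m per z);
#'   0 gives the confounded-null cohort.
#' @param walk_intercept_m,walk_noise_sd_m intercept and noise SD of the
#'   walking model (m); 6MWD is truncated at 0.
#' @param upreg_noise_sd SD of the cCRST upregulation noise (z units).
#' @param tract_z_noise_sd baseline per-tract z noise for the remaining
#'   stroke tracts (z units).
#' @param global_nqa_sd between-participant SD of global white-matter nQA.
#' @param seed master RNG seed; per-participant streams are derived by
#'   counter offset so cohorts are reproducible under reordering.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_pairs = 10,
                          damage_mean = 11.25, damage_sd = 3.4,
                          delta_upreg = 0.12,
                          gamma_walk = 34,
                          beta_direct = 0,
                          walk_intercept_m = 537, walk_noise_sd_m = 90,
                          upreg_noise_sd = 1.5,
                          tract_z_noise_sd = 1.0,
                          global_nqa_sd = 0.18,
                          seed = 1L) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (damage_sd < 0 || upreg_noise_sd < 0 || walk_noise_sd_m < 0 ||
      tract_z_noise_sd < 0 || global_nqa_sd < 0)
    stop("noise SDs must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs),
                 damage_mean = damage_mean, damage_sd = damage_sd,
                 delta_upreg = delta_upreg, gamma_walk = gamma_walk,
                 beta_direct = beta_direct,
                 walk_intercept_m = walk_intercept_m,
                 walk_noise_sd_m = walk_noise_sd_m,
                 upreg_noise_sd = upreg_noise_sd,
                 tract_z_noise_sd = tract_z_noise_sd,
                 global_nqa_sd = global_nqa_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

## internal generator constants shared by the volume and tabular paths
cohort_constants <- function() {
  list(global_mean = 2.658,
       slopes = c(crst = 1.186, cst = 2.702),
       tract_mean = c(crst = 3.25, cst = 4.98),
       tract_sd = c(crst = 0.18, cst = 0.24),
       ipsi_damage_rate = c(crst = 0.60, cst = 0.88),
       cst_upreg_ratio = 2.1,
       composite_w = c(crst = 0.38, cst = 0.62))
}

rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmax(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
  x
}

## One participant's latent draws, on a dedicated substream. Draw order is
## fixed so streams stay stable across code paths.
draw_participant_latents <- function(params, pair, group, cc) {
  idx <- 2L * (pair - 1L) + if (group == "stroke") 1L else 2L
  with_seed(derive_seed(params$seed, idx), {
    g <- max(1.5, stats::rnorm(1, cc$global_mean, params$global_nqa_sd))
    base_dev <- stats::setNames(stats::rnorm(4), # control-scale tract devs
                                c("crst_left", "crst_right",
                                  "cst_left", "cst_right"))
    if (group == "control") {
      D <- 0
      dev <- base_dev
      icm_z <- stats::rnorm(1)
      ccm_z <- stats::rnorm(1)
      walk <- params$walk_intercept_m +
        stats::rnorm(1, 0, params$walk_noise_sd_m)
      ccrst_dev <- NA_real_
    } else {
      D <- rtruncnorm0(1, params$damage_mean, params$damage_sd)
      side <- if (pair %% 2L == 1L) "left" else "right"
      other <- if (side == "left") "right" else "left"
      dev <- stats::setNames(numeric(4), names(base_dev))
      for (fam in c("crst", "cst")) {
        dev[paste0(fam, "_", side)] <- -cc$ipsi_damage_rate[fam] * D +
          stats::rnorm(1, 0, params$tract_z_noise_sd)
      }
      ccrst_dev <- params$delta_upreg * D +
        stats::rnorm(1, 0, params$upreg_noise_sd)
      dev[paste0("crst_", other)] <- ccrst_dev
      dev[paste0("cst_", other)] <- cc$cst_upreg_ratio * params$delta_upreg * D +
        stats::rnorm(1, 0, params$tract_z_noise_sd)
      icm_z <- -D
      ccm_z <- sum(cc$composite_w * cc$tract_sd *
                     dev[paste0(c("crst", "cst"), "_", other)]) /
        sqrt(sum((cc$composite_w * cc$tract_sd)^2))
      walk <- max(0, params$walk_intercept_m + params$gamma_walk * icm_z +
                    params$beta_direct * ccrst_dev +
                    stats::rnorm(1, 0, params$walk_noise_sd_m))
    }
    list(D = D, g = g, dev = dev, icm_z = icm_z, ccrst_z = ccrst_dev,
         ccm_z = ccm_z, six_mwd_m = walk)
  })
}

## unadjusted tract nQA implied by the latents (the planted regression)
latent_tract_values <- function(lat, cc) {
  fam <- sub("_.*", "", names(lat$dev))
  stats::setNames(cc$tract_mean[fam] + cc$slopes[fam] * (lat$g - cc$global_mean) +
                    cc$tract_sd[fam] * lat$dev, names(lat$dev))
}

#' Generate a synthetic cohort with participant QA volumes
#'
#' Draws a matched stroke/control cohort from the latent causal model of
#' [cohort_params()] and realizes each participant as phantom painting
#' parameters for [make_participant_volume()]: ipsilesional attenuation
#' increasing with the latent deficit `D`, contralesional elevation
#' `1 + delta_upreg * D` (plus noise), a per-participant global nQA level
#' with the control tract-vs-global regression slopes planted exactly, and
#' optional scanner gain, rigid misalignment and voxel noise. Lesion sides
#' alternate across pairs; each control inherits its matched stroke
#' partner's pair id.
#'
#' @param params a [cohort_params()].
#' @param templates output of [make_templates()]; generated on a default
#'   48^3 grid when `NULL`.
#' @param volume_noise_sd additive voxel noise SD for the phantoms.
#' @param misalignment logical; draw random +-1-voxel rigid shifts.
#' @param gain_range range of the per-participant scanner gain
#'   (`c(1, 1)` disables gain variation).
#' @return A list with `cohort` (data.frame: id, group, pair_id,
#'   lesion_side, six_mwd_m, true_damage), `phantoms` (named list of
#'   [phantom_params()]), `latents` (per-participant latent draws), and
#'   `templates`.
#' @export
make_cohort <- function(params = cohort_params(), templates = NULL,
                        volume_noise_sd = 0.05, misalignment = TRUE,
                        gain_range = c(0.85, 1.2)) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(templates)) templates <- make_templates()
  cc <- cohort_constants()
  d3 <- templates$grid$dims[3]
  n_skel <- sum(templates$masks$skeleton)
  n_sheet <- n_skel - 4L * d3

  rows <- list(); phantoms <- list(); lat_rows <- list()
  for (pair in seq_len(params$n_pairs)) {
    side <- if (pair %% 2L == 1L) "left" else "right"
    for (group in c("stroke", "control")) {
      id <- sprintf("%s%02d", if (group == "stroke") "S" else "C", pair)
      lat <- draw_participant_latents(params, pair, group, cc)
      target <- latent_tract_values(lat, cc)
      gscale <- lat$g / cc$global_mean

      ## decompose target values into the phantom factor product
      atten <- stats::setNames(rep(1, 4), names(target))
      elev <- stats::setNames(rep(1, 4), names(target))
      base <- target
      if (group == "stroke") {
        other <- if (side == "left") "right" else "left"
        for (fam in c("crst", "cst")) {
          ik <- paste0(fam, "_", side); ck <- paste0(fam, "_", other)
          eff_i <- cc$tract_sd[fam] * cc$ipsi_damage_rate[fam] * lat$D
          base[ik] <- target[ik] + eff_i
          atten[ik] <- max(0, min(1, 1 - eff_i / base[ik]))
          up <- if (fam == "crst") params$delta_upreg else
            cc$cst_upreg_ratio * params$delta_upreg
          eff_c <- cc$tract_sd[fam] * up * lat$D
          base[ck] <- target[ck] - eff_c
          elev[ck] <- max(1, 1 + eff_c / base[ck])
        }
      }
      tract_scale <- base / (cc$tract_mean[sub("_.*", "", names(base))] * gscale)

      painted <- gscale * cc$tract_mean[sub("_.*", "", names(base))] *
        tract_scale * atten * elev
      bg <- (lat$g * n_skel - d3 * sum(painted)) / n_sheet / gscale

      extras <- with_seed(derive_seed(params$seed, 5e5 + 2L * (pair - 1L) +
                                        (group == "control")), {
        list(gain = stats::runif(1, gain_range[1], gain_range[2]),
             shift = if (misalignment) sample(-1:1, 3, replace = TRUE)
                     else c(0L, 0L, 0L))
      })
      phantoms[[id]] <- phantom_params(
        global_scale = gscale,
        tract_attenuation = atten, tract_elevation = elev,
        tract_scale = tract_scale,
        scanner_gain = extras$gain, noise_sd = volume_noise_sd,
        misalignment_vox = extras$shift,
        background_level = bg,
        seed = derive_seed(params$seed, 1e6 + 2L * (pair - 1L) +
                             (group == "control")))
      rows[[id]] <- data.frame(
        id = id, group = group, pair_id = pair,
        lesion_side = if (group == "stroke") side else "none",
        six_mwd_m = lat$six_mwd_m, true_damage = lat$D,
        stringsAsFactors = FALSE)
      lat_rows[[id]] <- data.frame(id = id, global_nqa = lat$g,
                                   icm_z = lat$icm_z, ccrst_z = lat$ccrst_z,
                                   t(target), stringsAsFactors = FALSE)
    }
  }
  list(cohort = do.call(rbind, c(rows, make.row.names = FALSE)),
       phantoms = phantoms,
       latents = do.call(rbind, c(lat_rows, make.row.names = FALSE)),
       templates = templates)
}

#' Generate a tabular cohort with analytic tract-strength z-scores
#'
#' The fast path for exercising the statistics stage alone: the same
#' latent causal model as [make_cohort()] (identical per-participant
#' substreams, so the noise-free latents match exactly), but tract values
#' and z-scores are emitted analytically instead of being measured from
#' volumes. Controls' z columns are standard-normal by construction;
#' stroke z columns carry the planted damage and upregulation effects.
#'
#' @param params a [cohort_params()].
#' @return A data.frame with one row per participant: cohort columns
#'   (id, group, pair_id, lesion_side, six_mwd_m, true_damage), global and
#'   per-side unadjusted tract nQA (`global_nqa`, `crst_left_nqa`, ...),
#'   and one z-score column per tract role (`icrst_z`, `ccrst_z`,
#'   `icst_z`, `ccst_z`, `icm_z`, `ccm_z`).
#' @examples
#' head(make_tabular_cohort(cohort_params(n_pairs = 5)))
#' @export
make_tabular_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  cc <- cohort_constants()
  rows <- list()
  for (pair in seq_len(params$n_pairs)) {
    side <- if (pair %% 2L == 1L) "left" else "right"
    other <- if (side == "left") "right" else "left"
    for (group in c("stroke", "control")) {
      id <- sprintf("%s%02d", if (group == "stroke") "S" else "C", pair)
      lat <- draw_participant_latents(params, pair, group, cc)
      tv <- latent_tract_values(lat, cc)
      ipsi <- paste0(c("crst", "cst"), "_", side)
      contra <- paste0(c("crst", "cst"), "_", other)
      rows[[id]] <- data.frame(
        id = id, group = group, pair_id = pair,
        lesion_side = if (group == "stroke") side else "none",
        six_mwd_m = lat$six_mwd_m, true_damage = lat$D,
        global_nqa = lat$g,
        crst_left_nqa = tv[["crst_left"]], crst_right_nqa = tv[["crst_right"]],
        cst_left_nqa = tv[["cst_left"]], cst_right_nqa = tv[["cst_right"]],
        icrst_z = lat$dev[[ipsi[1]]], ccrst_z = lat$dev[[contra[1]]],
        icst_z = lat$dev[[ipsi[2]]], ccst_z = lat$dev[[contra[2]]],
        icm_z = lat$icm_z, ccm_z = lat$ccm_z,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a cohort table and its generator parameters
#'
#' @param cohort a cohort data.frame.
#' @param params the [cohort_params()] used to generate it.
#' @param csv_path,json_path output paths (CSV table, JSON parameter
#'   sidecar).
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, params, csv_path, json_path = NULL) {
  utils::write.csv(cohort, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(unclass(params), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
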