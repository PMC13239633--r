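test_that("streamline-weighted slab mean matches hand arithmetic and respects the slab", {
  g <- tiny_grid(16, 2, -16)              # slices k=1..16 at z = -16..14
  ks <- slab_slices(g, c(-5, 12))         # z in {-4,...,12}
  expect_equal(voxel_z_mm(g)[ks], seq(-4, 12, by = 2))

  # uniform skeleton value c: weighted mean is c for any weights
  co <- cbind(5:9, 5, ks[1:5])
  sk <- skeleton_toy(co, rep(2.7, 5), g)
  tt <- count_template(co, c(1, 4, 9, 2, 7), g)
  expect_equal(tract_mean_nqa(sk, tt), 2.7)

  # two voxels, values (2, 4), weights (1, 3) -> 3.5
  co2 <- cbind(5:6, 5, ks[1])
  expect_equal(tract_mean_nqa(skeleton_toy(co2, c(2, 4), g),
                              count_template(co2, c(1, 3), g)), 3.5)

  # a high-value voxel outside the slab never enters
  co3 <- rbind(co2, c(7, 5, which(abs(voxel_z_mm(g) - 14) < 1e-9)))
  sk3a <- skeleton_toy(co3, c(2, 4, 100), g)
  sk3b <- skeleton_toy(co3, c(2, 4, 900), g)
  tt3 <- count_template(co3, c(1, 3, 50), g)
  expect_equal(tract_mean_nqa(sk3a, tt3), 3.5)
  expect_equal(tract_mean_nqa(sk3a, tt3), tract_mean_nqa(sk3b, tt3))

  # zero total weight in slab errors, naming tract and slab
  expect_error(tract_mean_nqa(skeleton_toy(co2, c(2, 4), g),
                              count_template(cbind(12, 12, 16), 5, g)),
               "left CRST.*\\[-5, 12\\]")
})

test_that("weighted slab mean equals a brute-force voxel loop", {
  g <- tiny_grid()
  set.seed(42)
  n <- 40
  co <- unique(cbind(sample(3:14, n, TRUE), sample(3:14, n, TRUE),
                     sample(1:16, n, TRUE)))
  vals <- stats::runif(nrow(co), 1, 5)
  w <- stats::rpois(nrow(co), 6)
  sk <- skeleton_toy(co, vals, g)
  tt <- count_template(co, w, g)

  # oracle: explicit loop over all voxels of the grid
  z <- voxel_z_mm(g)
  num <- den <- 0
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    v <- sk$values[i, j, k]; wt <- tt$streamline_counts$values[i, j, k]
    if (!is.na(v) && wt > 0 && z[k] >= -5 && z[k] <= 12) {
      num <- num + wt * v; den <- den + wt
    }
  }
  expect_equal(tract_mean_nqa(sk, tt), num / den, tolerance = 1e-10)
})

test_that("global white-matter nQA is the unweighted skeleton mean", {
  g <- tiny_grid()
  co <- cbind(c(4, 5), 4, 4)
  expect_equal(global_wm_nqa(skeleton_toy(co, c(1, 3), g)), 2)
  expect_equal(global_wm_nqa(skeleton_toy(co, c(2.2, 2.2), g)), 2.2)
  # adding a voxel outside the skeleton mask leaves it unchanged
  masks <- mask_set(array(FALSE, g$dims),
                    {s <- array(FALSE, g$dims); s[co] <- TRUE; s},
                    {w <- array(FALSE, g$dims); w[3:6, 3:6, 3:6] <- TRUE; w},
                    grid = g)
  a <- array(NA_real_, g$dims); a[co] <- c(1, 3); a[6, 6, 6] <- 50
  expect_equal(global_wm_nqa(qa_volume(a, g), masks), 2)
  expect_error(global_wm_nqa(skeleton_toy(cbind(1, 1, 1), NA_real_, g)
                             , NULL), "empty")
})

test_that("global adjustment and z-scoring reproduce the published worked examples", {
  # at the control global mean the adjustment is a no-op
  expect_equal(adjust_tract_nqa(3.2, 2.658, 1.186, 2.658), 3.2)
  # hand arithmetic: 3.0 - 1.186 * (3.0 - 2.658) = 2.594 (3 d.p.)
  expect_equal(adjust_tract_nqa(3.0, 3.0, 1.186, 2.658), 2.594388,
               tolerance = 1e-6)
  expect_equal(adjust_tract_nqa(5, 9, 0, 2.658), 5)

  expect_equal(tract_zscore(3.093, 3.093, 0.272), 0)
  expect_equal(tract_zscore(3.365, 3.093, 0.272), 1, tolerance = 1e-12)
  expect_equal(tract_zscore(4.1 + 2 * 0.3, 4.1, 0.3), 2)
  expect_error(tract_zscore(1, 0, 0), "positive")
})

test_that("composite corticomotor weighting is a normative-volume weighted average", {
  expect_equal(composite_corticomotor(2, 4, c(crst = 0.5, cst = 0.5)), 3)
  expect_equal(composite_corticomotor(2, 4, c(crst = 0.25, cst = 0.75)), 3.5)
  expect_equal(composite_corticomotor(7.3, 7.3, c(crst = 0.38, cst = 0.62)), 7.3)
  expect_error(composite_corticomotor(1, 2, c(crst = 0.5, cst = 0.6)), "sum to 1")
})

test_that("ipsi/contra roles follow the lesion side, with controls matched to their stroke partner", {
  cohort <- data.frame(
    id = c("S01", "C01", "S02", "C02"),
    group = c("stroke", "control", "stroke", "control"),
    pair_id = c(1, 1, 2, 2),
    lesion_side = c("right", "none", "left", "none"))
  vals <- data.frame(id = cohort$id,
                     crst_left = 1:4, crst_right = 11:14,
                     cst_left = 21:24, cst_right = 31:34)
  out <- assign_laterality(vals, cohort)
  expect_equal(out$icrst[out$id == "S01"], 11)  # right lesion: ipsi = right
  expect_equal(out$ccrst[out$id == "S01"], 1)
  expect_equal(out$icst[out$id == "C02"], 24)   # partner S02 lesioned left
  expect_equal(out$ipsi_side, c("right", "right", "left", "left"))

  orphan <- cohort[cohort$id != "S02", ]
  expect_error(assign_laterality(vals[vals$id != "S02", ], orphan),
               "no matched stroke partner")
})

test_that("reference fitting is exact on noise-free linear controls and standardizes them to mean 0 / SD 1", {
  g0 <- 2.658
  glob <- seq(2.2, 3.1, length.out = 8)
  ctrl <- data.frame(id = sprintf("C%02d", 1:8), global_nqa = glob)
  ctrl$crst_left <- ctrl$crst_right <- 3.4 + 1.186 * (glob - g0)
  ctrl$cst_left <- ctrl$cst_right <- 5.1 + 2.702 * (glob - g0)
  cohort <- rbind(
    data.frame(id = ctrl$id, group = "control", pair_id = 1:8,
               lesion_side = "none"),
    data.frame(id = sprintf("S%02d", 1:8), group = "stroke", pair_id = 1:8,
               lesion_side = rep(c("left", "right"), 4)))
  tpl <- shared_templates()
  # perfectly collinear adjusted values have no spread to standardize by
  expect_error(fit_reference(assign_laterality(ctrl, cohort), tpl), "zero SD")

  # antisymmetric L/R noise cancels in the L/R average the slope fit uses,
  # so the planted slopes are recovered exactly with r-squared 1, while
  # per-role adjusted values keep a nonzero spread
  e <- seq(-0.07, 0.07, length.out = 8)
  ctrl$crst_left <- ctrl$crst_left + e; ctrl$crst_right <- ctrl$crst_right - e
  ctrl$cst_left <- ctrl$cst_left + 2 * e; ctrl$cst_right <- ctrl$cst_right - 2 * e
  ctrl <- assign_laterality(ctrl, cohort)
  ref <- fit_reference(ctrl, tpl)
  expect_equal(unname(ref$slopes[["crst"]]), 1.186, tolerance = 1e-10)
  expect_equal(unname(ref$slopes[["cst"]]), 2.702, tolerance = 1e-10)
  expect_equal(unname(ref$r2), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(ref$control_global_mean), mean(glob))
  expect_equal(sum(ref$composite_weights), 1)
  expect_gt(ref$composite_weights[["cst"]], ref$composite_weights[["crst"]])

  strengths <- compute_tract_strengths(ctrl, ref)
  for (role in unique(strengths$role)) {
    z <- strengths$z_score[strengths$role == role]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  }

  expect_error(fit_reference(ctrl[1:2, ], tpl), "at least 3")
  ctrl0 <- ctrl; ctrl0$global_nqa <- 2.6
  expect_error(fit_reference(ctrl0, tpl), "zero variance")
})

test_that("slopes planted in the synthetic control cohort are recovered by the reference fit", {
  tab <- make_tabular_cohort(cohort_params(n_pairs = 200, seed = 42))
  ctrl <- tabular_sides(tab)
  ctrl <- ctrl[ctrl$group == "control", ]
  ref <- fit_reference(ctrl, shared_templates())
  # analytic SE of the slope given the generator's own noise levels
  se_crst <- (0.18 / sqrt(2)) / (stats::sd(ctrl$global_nqa) * sqrt(200))
  se_cst <- (0.24 / sqrt(2)) / (stats::sd(ctrl$global_nqa) * sqrt(200))
  expect_lt(abs(ref$slopes[["crst"]] - 1.186), 3 * se_crst)
  expect_lt(abs(ref$slopes[["cst"]] - 2.702), 3 * se_cst)
  expect_gt(ref$r2[["crst"]], 0.55); expect_lt(ref$r2[["crst"]], 0.9)
  expect_gt(ref$r2[["cst"]], 0.8)
})

test_that("scanner gain never reaches a z-score and planted attenuation lowers iCRST monotonically", {
  tpl <- shared_templates()
  ref <- reference_preset()
  score_one <- function(atten, gain) {
    v <- make_participant_volume(
      tpl, phantom_params(noise_sd = 0, scanner_gain = gain,
                          tract_attenuation = c(crst_left = atten)))
    sk <- project_to_skeleton(normalize_qa(v, tpl$masks), tpl$masks, 2)
    vals <- data.frame(id = "S01",
                       global_nqa = global_wm_nqa(sk),
                       crst_left = tract_mean_nqa(sk, tpl$templates$crst_left),
                       crst_right = tract_mean_nqa(sk, tpl$templates$crst_right),
                       cst_left = tract_mean_nqa(sk, tpl$templates$cst_left),
                       cst_right = tract_mean_nqa(sk, tpl$templates$cst_right))
    cohort <- data.frame(id = "S01", group = "stroke", pair_id = 1,
                         lesion_side = "left")
    s <- compute_tract_strengths(assign_laterality(vals, cohort), ref)
    s$z_score[s$role == "iCRST"]
  }
  z1 <- sapply(c(1, 0.85, 0.7, 0.55, 0.4), score_one, gain = 1)
  z2 <- sapply(c(1, 0.85, 0.7, 0.55, 0.4), score_one, gain = 2.4)
  expect_identical(z1, z2)                  # gain invariance of z-scores
  expect_true(all(diff(z1) < 0))            # strictly decreasing with damage
})
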