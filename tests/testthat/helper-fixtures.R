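# Shared fixtures, built in code.

tiny_grid <- function(n = 16, vs = 2, z0 = -16) grid_spec(rep(n, 3), vs, z0)

# Single shared synthetic template set (deterministic), built once.
shared_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_templates(grid_spec(c(48, 48, 48), 2, -40),
                                                 seed = 1L)
    cache
  }
})

# A skeleton-valued toy volume: values at given voxel coordinates, NA
# elsewhere (as produced by project_to_skeleton()).
skeleton_toy <- function(coords, values, grid = tiny_grid()) {
  a <- array(NA_real_, grid$dims)
  a[coords] <- values
  qa_volume(a, grid)
}

count_template <- function(coords, counts, grid = tiny_grid(),
                           name = "CRST", side = "left") {
  a <- array(0, grid$dims)
  a[coords] <- counts
  tract_template(name, side, qa_volume(a, grid), max(sum(counts > 0), 1))
}

# Rename tabular-cohort nQA columns to the side-keyed names expected by
# assign_laterality()/fit_reference().
tabular_sides <- function(tab) {
  for (nm in c("crst_left", "crst_right", "cst_left", "cst_right"))
    names(tab)[names(tab) == paste0(nm, "_nqa")] <- nm
  assign_laterality(tab, tab)
}

# A vector of length n with an exact given mean (n - 1 spread values plus
# a balancing one); used to rebuild groups from printed summary means.
vector_with_mean <- function(n, mean, spread = 0.3) {
  x <- mean + spread * scale(seq_len(n - 1), scale = FALSE)
  c(x, n * mean - sum(x))
}
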