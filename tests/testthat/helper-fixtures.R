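# shared fixtures, built in code

.fixture_env <- new.env(parent = emptyenv())

test_atlas <- function() {
  if (is.null(.fixture_env$atlas)) .fixture_env$atlas <- load_atlas_spec()
  .fixture_env$atlas
}

# noise-free reference cohort (deterministic, cached: several files use it)
noise_free_cohort <- function() {
  if (is.null(.fixture_env$nf)) {
    cfg <- cohort_config("reference", noise_sd = 0, level_sds = rep(0, 5))
    .fixture_env$nf <- generate_roi_cohort(cfg, test_atlas())
  }
  .fixture_env$nf
}

# single-scan table with equal voxel counts
tiny_scan <- function(means, n_voxels = 10L,
                      structures = letters[seq_along(means)]) {
  data.frame(structure = structures, n_voxels = n_voxels,
             mean_counts = means, stringsAsFactors = FALSE)
}

# per-scan perfusion vectors for a cohort result, in onset-relative naming
cohort_pi_vectors <- function(cohort, atlas = test_atlas(),
                              denominator = "rest") {
  key <- interaction(cohort$tables$patient, cohort$tables$state, drop = TRUE)
  scans <- split(cohort$tables, key)
  out <- lapply(scans, function(d) {
    side <- cohort$clinical$onset_side[match(d$patient[1], cohort$clinical$patient)]
    perfusion_index(relabel_ipsilateral(d, side, atlas), denominator)
  })
  names(out) <- vapply(scans, function(d) paste(d$patient[1], d$state[1], sep = "."),
                       character(1))
  out
}
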