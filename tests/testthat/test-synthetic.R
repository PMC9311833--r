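test_that("cohort generation is deterministic per seed and positive", {
  atlas <- test_atlas()
  cfg <- cohort_config("reference", seed = 42L)
  c1 <- generate_roi_cohort(cfg, atlas)
  c2 <- generate_roi_cohort(cfg, atlas)
  expect_identical(c1, c2)
  c3 <- generate_roi_cohort(cohort_config("reference", seed = 43L), atlas)
  expect_false(identical(c1$tables$mean_counts, c3$tables$mean_counts))
  expect_identical(nrow(c1$tables), 9L * 2L * 74L)
  expect_true(all(c1$tables$mean_counts > 0))
  expect_identical(sort(unique(c1$tables$state)), c("ictal", "interictal"))
  # the clinical scores are the reference cohort's
  expect_identical(c1$clinical$score, c(3L, 5L, 7L, 7L, 7L, 4L, 7L, 7L, 4L))
  expect_identical(c1$clinical$stratum,
                   ifelse(c1$clinical$score > 5, "high", "low"))
})

test_that("planted level draws respect the reported perfusion ranges", {
  coh <- generate_roi_cohort(cohort_config("reference"), test_atlas())
  tr <- subset(coh$truth, state == "interictal")
  hypo <- tr$pi_level[tr$level == "hypo"]
  hyper <- tr$pi_level[tr$level == "hyper"]
  expect_true(all(hypo >= 0.42 & hypo <= 0.64))
  expect_true(all(hyper >= 1.16 & hyper <= 1.46))
  # each patient's planted sets have the configured sizes
  expect_identical(sum(tr$level == "hypo"), 9L * 6L)
  expect_identical(sum(tr$level == "hyper"), 9L * 7L)
})

test_that("noise-free quantification recovers the planted values exactly", {
  coh <- noise_free_cohort()
  vecs <- cohort_pi_vectors(coh, denominator = "global")
  for (p in c("P1", "P4")) {
    for (st in c("interictal", "ictal")) {
      v <- vecs[[paste(p, st, sep = ".")]]
      tr <- subset(coh$truth, patient == p & state == st)
      side <- coh$clinical$onset_side[match(p, coh$clinical$patient)]
      rel <- tr$structure_rel
      expect_equal(unname(as.numeric(v[rel])), tr$pi_true, tolerance = 1e-12)
      # interictal planted vector averages 1, so levels survive untouched
      if (st == "interictal") {
        expect_equal(unname(as.numeric(v[rel])), tr$pi_level, tolerance = 1e-12)
      }
    }
  }
})

test_that("an all-ones change map makes ictal scans identical to interictal", {
  atlas <- test_atlas()
  cfg <- cohort_config("reference", noise_sd = 0, level_sds = rep(0, 5))
  cfg$change_map$hyper_factor <- 1
  cfg$change_map$hypo_factor <- 1
  cfg$change_map$extra_factors[] <- 1
  coh <- generate_roi_cohort(cfg, atlas)
  int <- subset(coh$tables, state == "interictal")
  ict <- subset(coh$tables, state == "ictal")
  expect_equal(int$mean_counts, ict$mean_counts)
})

test_that("high-risk patients carry the planted invariance biomarker", {
  coh <- noise_free_cohort()
  tr <- subset(coh$truth, state == "ictal")
  bio <- c("putamen_ipsi", "entorhinal_area_ipsi", "middle_temporal_gyrus_ipsi")
  for (p in coh$clinical$patient) {
    f <- tr$change_factor[tr$patient == p & tr$structure_rel %in% bio]
    if (coh$clinical$stratum[coh$clinical$patient == p] == "high") {
      expect_identical(unique(f), 1)
    } else {
      expect_true(all(f != 1))
    }
  }
})

test_that("phantom volumes are deterministic and honour the Poisson switch", {
  atlas <- test_atlas()
  truth <- c(putamen_L = 1.4, putamen_R = 0.5)
  cfgp <- phantom_config(grid_shape = c(12L, 12L, 12L), psf_fwhm_mm = 4,
                         voxel_size_mm = 3, poisson = TRUE, seed = 1L)
  p1 <- generate_phantom(cfgp, atlas, truth)
  p2 <- generate_phantom(cfgp, atlas, truth)
  expect_identical(p1$activity, p2$activity)
  cfgp2 <- cfgp; cfgp2$seed <- 2L
  p3 <- generate_phantom(cfgp2, atlas, truth)
  expect_false(identical(p1$activity, p3$activity))
  # different seeds, same expectation (the noiseless blurred volume)
  cfg0 <- cfgp; cfg0$poisson <- FALSE
  noiseless <- generate_phantom(cfg0, atlas, truth)$activity
  expect_lt(abs(mean(p1$activity - noiseless)),
            4 * sqrt(sum(noiseless)) / length(noiseless))
  # integer counts under Poisson
  expect_true(all(p1$activity == round(p1$activity)))
  expect_error(generate_phantom(phantom_config(grid_shape = c(2L, 2L, 2L)),
                                atlas, setNames(rep(1, 30), atlas$name[1:30])),
               "too small")
})

test_that("cohort writer emits plain CSV round-trippable tables", {
  coh <- noise_free_cohort()
  d <- tempfile()
  paths <- write_cohort(coh, d)
  back <- read.csv(paths[1], stringsAsFactors = FALSE)
  expect_equal(back$mean_counts, coh$tables$mean_counts)
  expect_identical(nrow(read.csv(paths[2])), 9L)
  unlink(d, recursive = TRUE)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(cohort_config("other"), "unknown cohort configuration")
  expect_error(cohort_config("reference", noise_sd = -1), "noise_sd")
  expect_error(cohort_config("reference", n_patients = 1), "n_patients")
  atlas <- test_atlas()
  cfg <- cohort_config("reference")
  cfg$hypo_structures <- c(cfg$hypo_structures, "nonexistent_ipsi")
  expect_error(generate_roi_cohort(cfg, atlas), "absent from atlas")
})
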