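test_that("ROI means are masked means by direct summation", {
  atlas <- test_atlas()
  # hand-built 3x3x3 volume with two 4-voxel ROIs (8s and 2s)
  act <- array(0, c(3, 3, 3))
  lab <- array(0L, c(3, 3, 3))
  lab[1:2, 1:2, 1] <- 1L   # putamen_L has catalogue id 1? use real ids
  act[1:2, 1:2, 1] <- 8
  lab[1:2, 1:2, 3] <- 2L
  act[1:2, 1:2, 3] <- 2
  gm <- array(1L, c(3, 3, 3))
  tab <- compute_roi_means(act, lab, gm, atlas)
  expect_identical(tab$n_voxels, c(4L, 4L))
  expect_equal(tab$mean_counts, c(8, 2))
  # constant field: every ROI mean equals the constant
  tabc <- compute_roi_means(array(3.5, c(3, 3, 3)), lab, gm, atlas)
  expect_equal(tabc$mean_counts, c(3.5, 3.5))
  # masking excludes voxels from the mean and can empty a structure
  gm2 <- gm; gm2[1, , ] <- 0L   # halves ROI 1, keeps 2 voxels each
  act2 <- act; act2[1, 1:2, 1] <- 100  # excluded voxels must not matter
  tab2 <- compute_roi_means(act2, lab, gm2, atlas)
  expect_equal(tab2$mean_counts[tab2$structure_id == 1L], 8)
  expect_identical(tab2$n_voxels[tab2$structure_id == 1L], 2L)
  gm3 <- array(0L, c(3, 3, 3)); gm3[lab == 1L] <- 1L
  tab3 <- compute_roi_means(act, lab, gm3, atlas)
  expect_identical(tab3$structure_id, 1L)
  expect_true("superior_frontal_gyrus_R" %in% attr(tab3, "absent"))
  expect_error(compute_roi_means(act, lab[, , 1:2], gm, atlas), "grid")
  expect_error(compute_roi_means(act, lab, array(0L, c(3, 3, 3)), atlas), "empty")
})

test_that("perfusion index uses the leave-one-out rest reference", {
  # 3 ROIs, equal voxel counts, means (2,1,1): rest reference gives
  # (2/1, 1/1.5, 1/1.5)
  v <- perfusion_index(tiny_scan(c(2, 1, 1)))
  expect_equal(unname(as.numeric(v)), c(2, 2 / 3, 2 / 3))
  vg <- perfusion_index(tiny_scan(c(2, 1, 1)), "global")
  expect_equal(unname(as.numeric(vg)), c(1.5, 0.75, 0.75))
  # homogeneous perfusion: every PI = 1 under either reference
  expect_equal(unname(as.numeric(perfusion_index(tiny_scan(c(4, 4, 4))))),
               rep(1, 3))
  # voxel-count weighting of the rest mean
  tab <- data.frame(structure = c("a", "b"), n_voxels = c(1L, 3L),
                    mean_counts = c(8, 4))
  expect_equal(unname(as.numeric(perfusion_index(tab))), c(8 / 4, 4 / 8))
  expect_error(perfusion_index(tiny_scan(c(1, 0))), "zero or negative")
  expect_error(perfusion_index(tiny_scan(5)), ">= 2 structures")
})

test_that("perfusion index is invariant to global rescaling", {
  set.seed(11)
  for (rep in 1:5) {
    means <- runif(20, 10, 200)
    nv <- sample(50:500, 20, replace = TRUE)
    tab <- data.frame(structure = paste0("s", 1:20), n_voxels = nv,
                      mean_counts = means)
    for (denom in c("rest", "global")) {
      v1 <- as.numeric(perfusion_index(tab, denom))
      tab2 <- tab; tab2$mean_counts <- tab$mean_counts * 7.3
      expect_equal(as.numeric(perfusion_index(tab2, denom)), v1)
    }
  }
})

test_that("change vector is the relative interictal-to-ictal difference", {
  int <- perfusion_vector(c(a = 1.0, b = 0.5, c = 1.2), "P1", "interictal")
  ict <- perfusion_vector(c(a = 1.3, b = 0.4, c = 1.2), "P1", "ictal")
  ch <- change_vector(int, ict)
  expect_equal(unname(as.numeric(ch)), c(0.30, -0.20, 0))
  expect_identical(attr(ch, "state"), "change")
  # identical states give exact zero everywhere
  expect_equal(unname(as.numeric(change_vector(int, int))), rep(0, 3))
  # structure-set mismatch / patient mismatch are errors
  expect_error(change_vector(int, ict[1:2]), "different structure sets")
  ict2 <- perfusion_vector(c(a = 1, b = 1, c = 1), "P2", "ictal")
  expect_error(change_vector(int, ict2), "different patients")
  # order of structures does not matter
  ict3 <- perfusion_vector(c(c = 1.2, a = 1.3, b = 0.4), "P1", "ictal")
  expect_equal(as.numeric(change_vector(int, ict3)), as.numeric(ch))
})

test_that("Gaussian blur preserves mass and fwhm 0 is the identity", {
  v <- array(runif(6 * 5 * 4), c(6, 5, 4))
  expect_identical(gaussian_blur(v, 0), v)
  b <- gaussian_blur(v, 6, voxel_size_mm = 2)
  expect_equal(dim(b), dim(v))
  # interior impulse spreads symmetrically; total mass within the volume
  # is preserved up to edge truncation
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  bi <- gaussian_blur(imp, 4, voxel_size_mm = 1)
  expect_equal(sum(bi), 1, tolerance = 1e-6)
  expect_equal(bi[7, 8, 8], bi[9, 8, 8])
  expect_equal(bi[8, 7, 8], bi[8, 9, 8])
  expect_gt(bi[8, 8, 8], bi[8, 8, 7])
})

test_that("partial-volume blur biases adjacent ROIs toward each other", {
  atlas <- test_atlas()
  cfg0 <- phantom_config(grid_shape = c(16L, 16L, 16L), psf_fwhm_mm = 0,
                         voxel_size_mm = 3, gap_voxels = 0L)
  truth <- c(putamen_L = 1.4, putamen_R = 0.5)
  ph0 <- generate_phantom(cfg0, atlas, truth)
  tab0 <- compute_roi_means(ph0$activity, ph0$labels, ph0$gm_mask, atlas)
  expect_equal(tab0$mean_counts,
               unname(truth[match(tab0$structure, names(truth))] * 100))
  cfg8 <- phantom_config(grid_shape = c(16L, 16L, 16L), psf_fwhm_mm = 8,
                         voxel_size_mm = 3, gap_voxels = 0L)
  ph8 <- generate_phantom(cfg8, atlas, truth)
  tab8 <- compute_roi_means(ph8$activity, ph8$labels, ph8$gm_mask, atlas)
  hot0 <- tab0$mean_counts[match("putamen_L", tab0$structure)]
  hot8 <- tab8$mean_counts[match("putamen_L", tab8$structure)]
  cold8 <- tab8$mean_counts[match("putamen_R", tab8$structure)]
  expect_lt(hot8, hot0)   # hot ROI loses signal
  # the cold ROI gains signal from its hot neighbour: compare against a
  # control phantom where the neighbour is equally cold (isolates cross-talk
  # from the unavoidable loss into the zero background)
  ph_ctrl <- generate_phantom(cfg8, atlas, c(putamen_L = 0.5, putamen_R = 0.5))
  tab_ctrl <- compute_roi_means(ph_ctrl$activity, ph_ctrl$labels,
                                ph_ctrl$gm_mask, atlas)
  cold_ctrl <- tab_ctrl$mean_counts[match("putamen_R", tab_ctrl$structure)]
  expect_gt(cold8, cold_ctrl)
})

test_that("GTM correction inverts the blur on noiseless phantoms", {
  atlas <- test_atlas()
  truth <- c(putamen_L = 1.4, putamen_R = 0.5)
  cfg <- phantom_config(grid_shape = c(16L, 16L, 16L), psf_fwhm_mm = 8,
                        voxel_size_mm = 3, gap_voxels = 0L)
  ph <- generate_phantom(cfg, atlas, truth)
  tab <- compute_roi_means(ph$activity, ph$labels, ph$gm_mask, atlas)
  corrected <- pvc_region_gtm(tab, ph$labels, ph$gm_mask, psf_fwhm_mm = 8,
                              voxel_size_mm = 3)
  expected <- unname(truth[match(corrected$structure, names(truth))] * 100)
  expect_equal(corrected$mean_counts, expected, tolerance = 1e-6)
  # identity at fwhm 0 (exact)
  expect_identical(pvc_region_gtm(tab, ph$labels, ph$gm_mask, 0), tab)
  # a single region is underdetermined for cross-talk
  expect_error(pvc_region_gtm(tab[1, ], ph$labels, ph$gm_mask, 8), ">= 2 regions")
})

test_that("NIfTI round trip quantifies a phantom from disk", {
  atlas <- test_atlas()
  truth <- c(putamen_L = 1.4, putamen_R = 0.5, medulla = 1.0,
             thalamus_L = 1.0)
  cfg <- phantom_config(grid_shape = c(12L, 12L, 12L), psf_fwhm_mm = 0,
                        voxel_size_mm = 3)
  ph <- generate_phantom(cfg, atlas, truth)
  d <- tempfile(); paths <- write_phantom_nifti(ph, d, voxel_size_mm = 3)
  v <- quantify_nifti(paths[1], paths[2], paths[3], atlas,
                      denominator = "global")
  expect_equal(unname(as.numeric(v[names(truth)])),
               unname(truth / mean(truth)), tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})
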