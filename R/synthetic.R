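#' Clinical table of the reference nine-patient cohort
#'
#' The bundled reference cohort mirrors the nine-patient drug-resistant focal
#' epilepsy series that motivated this pipeline: per patient, the seizure
#' onset side, the seven SUDEP-7 inventory items (as booleans), the ictal
#' SPECT injection latency and the seizure duration. Under the default item
#' weights the SUDEP-7 scores are 3, 5, 7, 7, 7, 4, 7, 7, 4.
#'
#' @return Data frame with columns `patient`, `onset_side`, `i1`..`i7`,
#'   `injection_time_s`, `seizure_duration_s`.
#' @export
reference_clinical <- function() {
  score7 <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)   # i1+i3+i6+i7 = 7
  score4 <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)  # i2+i3+i6 = 4
  items <- rbind(
    c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),        # 3 = i2+i6
    c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),         # 5 = i2+i5+i6
    score7, score7, score7, score4, score7, score7, score4)
  colnames(items) <- paste0("i", 1:7)
  data.frame(
    patient = sprintf("P%d", 1:9),
    onset_side = c("left", "left", "right", "right", "right",
                   "right", "left", "left", "right"),
    items,
    injection_time_s = c(7, 17, 2, 8, 4, 6, 10, 5, 3),
    seizure_duration_s = c(109, 62, 95, 73, 66, 19, 56, 35, 72),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic ROI cohort generator
#'
#' The `"reference"` configuration plants the statistical structure the
#' downstream analysis assumes, at the scale of the reference cohort:
#' nine patients, five perfusion-index levels (hypoperfused 0.53 +/- 0.06,
#' low-normal 0.85, normal 1.00, high-normal 1.08, hyperperfused
#' 1.31 +/- 0.08), a hypoperfused structure set (medulla, bilateral red
#' nucleus and substantia nigra, ipsilateral entorhinal area) and a
#' hyperperfused set (bilateral rectus gyrus, putamen and cingulate,
#' ipsilateral globus pallidus). The interictal-to-ictal change map raises
#' the hyperperfused set by 30 %, lowers the hypoperfused set by 20 % and
#' raises the ipsilateral middle temporal gyrus by 15 % — except in
#' high-SUDEP-risk patients (score > 5), whose ipsilateral putamen,
#' entorhinal area and middle temporal gyrus do not change, planting the
#' perfusion-invariance biomarker the screening stage is meant to recover.
#' Level draws are truncated at +/- 1.8 SD so planted hypoperfused values
#' stay within 0.42-0.64 and hyperperfused within 1.16-1.46.
#'
#' @param name Configuration name; `"reference"` is the only built-in.
#' @param n_patients Number of patients; when larger than nine, clinical rows
#'   are recycled cyclically with fresh patient ids.
#' @param seed Integer seed making the generated cohort fully deterministic.
#' @param noise_sd Gaussian observation noise on the PI scale (SD), applied
#'   independently per scan; generated PIs are floored at `pi_floor`.
#' @param level_sds Optional numeric(5) overriding the per-level SDs (order:
#'   hypo, low-normal, normal, high-normal, hyper); `c(0,0,0,0,0)` gives a
#'   noise-free cohort with exactly five planted values per interictal scan.
#' @param clinical Optional replacement clinical table (see
#'   [reference_clinical()] for the schema).
#' @param n_voxels Voxel count assigned to every structure (constant so that
#'   planted levels survive the leave-one-out PI reference exactly).
#' @param global_scale Counts per voxel at PI = 1.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(name = "reference", n_patients = NULL, seed = 42L,
                          noise_sd = NULL, level_sds = NULL, clinical = NULL,
                          n_voxels = 400L, global_scale = 100) {
  if (!identical(name, "reference")) {
    abort("unknown cohort configuration '%s'", name)
  }
  clin <- clinical %||% reference_clinical()
  n_patients <- n_patients %||% nrow(clin)
  if (n_patients < 2L) abort("n_patients must be >= 2")
  if (n_patients != nrow(clin)) {
    idx <- rep_len(seq_len(nrow(clin)), n_patients)
    clin <- clin[idx, , drop = FALSE]
    clin$patient <- sprintf("P%d", seq_len(n_patients))
    rownames(clin) <- NULL
  }
  levels <- data.frame(
    level = c("hypo", "low_normal", "normal", "high_normal", "hyper"),
    mean = c(0.53, 0.85, 1.00, 1.08, 1.31),
    sd = level_sds %||% c(0.06, 0, 0, 0, 0.08),
    stringsAsFactors = FALSE)
  if (any(levels$mean <= 0)) abort("level means must be > 0")
  if (any(levels$sd < 0)) abort("level sds must be >= 0")
  noise_sd <- noise_sd %||% 0.02
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  cfg <- list(
    name = name,
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    pi_levels = levels,
    hypo_structures = c("medulla",
                        "red_nucleus_ipsi", "red_nucleus_contra",
                        "substantia_nigra_ipsi", "substantia_nigra_contra",
                        "entorhinal_area_ipsi"),
    hyper_structures = c("rectus_gyrus_ipsi", "rectus_gyrus_contra",
                         "putamen_ipsi", "putamen_contra",
                         "globus_pallidus_ipsi",
                         "cingulate_gyrus_ipsi", "cingulate_gyrus_contra"),
    change_map = list(
      hyper_factor = 1.30,
      hypo_factor = 0.80,
      extra_factors = c(middle_temporal_gyrus_ipsi = 1.15),
      invariant_in_high_risk = c("putamen_ipsi", "entorhinal_area_ipsi",
                                 "middle_temporal_gyrus_ipsi")),
    noise_sd = noise_sd,
    pi_floor = 0.05,
    level_truncation_sd = 1.8,
    clinical = clin,
    n_voxels = as.integer(n_voxels),
    global_scale = global_scale)
  class(cfg) <- "cohort_config"
  cfg
}

# relative (ipsi/contra/midline) name of every atlas structure, side-independent
#' @noRd
relative_names <- function(atlas) {
  base <- structure_base_name(atlas$name)
  ifelse(atlas$hemisphere == "midline", atlas$name,
         paste0(base, ifelse(atlas$hemisphere == "left", "_ipsi", "_contra")))
  # note: which physical hemisphere is "ipsi" depends on the patient; this
  # canonical map is only used to assign levels/factors consistently, and is
  # re-oriented per patient by onset side in generate_roi_cohort().
}

# level name for each relative structure name; middle-level counts are chosen
# so the planted level vector averages exactly 1 over the 74 structures,
# because a global-reference PI vector always has voxel-weighted mean 1 --
# this is what makes the noise-free generator -> quantification round trip
# exact rather than approximate
#' @noRd
assign_levels <- function(cfg, rel_names) {
  lev <- rep(NA_character_, length(rel_names))
  lev[rel_names %in% cfg$hypo_structures] <- "hypo"
  lev[rel_names %in% cfg$hyper_structures] <- "hyper"
  mid <- which(is.na(lev))
  levtab <- cfg$pi_levels
  mu <- stats::setNames(levtab$mean, levtab$level)
  target <- length(rel_names) -
    sum(mu["hypo"]) * sum(lev == "hypo", na.rm = TRUE) -
    sum(mu["hyper"]) * sum(lev == "hyper", na.rm = TRUE)
  n_mid <- length(mid)
  best <- NULL; best_key <- c(Inf, -Inf)
  for (a in 0:n_mid) for (cc in 0:(n_mid - a)) {
    b <- n_mid - a - cc
    dev <- abs(mu["low_normal"] * a + mu["normal"] * b + mu["high_normal"] * cc - target)
    key <- c(round(dev, 12), min(a, b, cc))
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- c(a, b, cc); best_key <- key
    }
  }
  lev[mid] <- rep(c("low_normal", "normal", "high_normal"), times = best)
  stats::setNames(lev, rel_names)
}

# per-structure ictal/interictal multiplicative factor for one risk class
#' @noRd
change_factors <- function(cfg, rel_names, high_risk) {
  f <- stats::setNames(rep(1, length(rel_names)), rel_names)
  f[intersect(cfg$hyper_structures, rel_names)] <- cfg$change_map$hyper_factor
  f[intersect(cfg$hypo_structures, rel_names)] <- cfg$change_map$hypo_factor
  extra <- cfg$change_map$extra_factors
  f[intersect(names(extra), rel_names)] <- extra[intersect(names(extra), rel_names)]
  if (high_risk) {
    f[intersect(cfg$change_map$invariant_in_high_risk, rel_names)] <- 1
  }
  f
}

# truncated-normal level draw (truncation in units of sd)
#' @noRd
rtrunc_norm <- function(n, mean, sd, trunc_sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- mean - trunc_sd * sd; hi <- mean + trunc_sd * sd
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic ROI cohort
#'
#' Draws, for every patient and both scan states, a 74-structure ROI activity
#' table with the planted perfusion structure described in [cohort_config()].
#' Interictal PIs are drawn from each structure's planted level; ictal PIs
#' are the interictal values times the structure's change factor; observation
#' noise is added per scan; PIs are converted to counts per voxel by scaling
#' against the voxel-weighted global mean, so quantification with the
#' `"global"` PI reference recovers the planted values exactly when noise is
#' off. The whole cohort is a deterministic function of the seed.
#'
#' @param config A [cohort_config()].
#' @param atlas An `atlas_spec`.
#' @return A list with elements
#'   \describe{
#'     \item{tables}{long ROI activity table (`patient`, `state`,
#'       `structure_id`, `structure`, `n_voxels`, `mean_counts`).}
#'     \item{clinical}{the clinical table with `score` and `stratum` columns
#'       added from the SUDEP-7 scorer.}
#'     \item{truth}{long table of planted values: relative and catalogue
#'       structure names, level, pre-noise PI and change factor per
#'       patient/state.}
#'   }
#' @export
generate_roi_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "cohort_config"))
  rel <- relative_names(atlas)
  known <- c(config$hypo_structures, config$hyper_structures,
             names(config$change_map$extra_factors),
             config$change_map$invariant_in_high_risk)
  unknown <- setdiff(known, rel)
  if (length(unknown)) {
    abort("config names structures absent from atlas: %s",
          paste(unknown, collapse = ", "))
  }
  lev_of <- assign_levels(config, rel)
  levtab <- config$pi_levels
  clin <- config$clinical
  scored <- score_sudep7(clin)
  clin$score <- scored$score
  clin$stratum <- scored$stratum

  with_seed(config$seed, {
    tabs <- vector("list", 2L * config$n_patients)
    truth <- vector("list", 2L * config$n_patients)
    for (p in seq_len(config$n_patients)) {
      side <- clin$onset_side[p]
      actual <- resolve_lateral_names(rel, side)
      ids <- atlas$id[match(actual, atlas$name)]
      mu <- levtab$mean[match(lev_of, levtab$level)]
      sd <- levtab$sd[match(lev_of, levtab$level)]
      pi_int <- mapply(function(m, s) rtrunc_norm(1, m, s, config$level_truncation_sd),
                       mu, sd)
      f <- change_factors(config, rel, high_risk = clin$stratum[p] == "high")
      pi_ict <- pi_int * f[rel]
      for (state in c("interictal", "ictal")) {
        planted <- if (state == "interictal") pi_int else pi_ict
        obs <- planted
        if (config$noise_sd > 0) {
          obs <- obs + stats::rnorm(length(obs), 0, config$noise_sd)
        }
        obs <- pmax(obs, config$pi_floor)
        counts <- config$global_scale * obs / mean(obs)  # equal voxel weights
        k <- (p - 1L) * 2L + if (state == "interictal") 1L else 2L
        tabs[[k]] <- data.frame(
          patient = clin$patient[p], state = state,
          structure_id = ids, structure = actual,
          n_voxels = config$n_voxels, mean_counts = counts,
          stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(
          patient = clin$patient[p], state = state,
          structure = actual, structure_rel = rel,
          level = unname(lev_of),
          # planted level draw (x change factor for the ictal state) ...
          pi_level = unname(planted),
          # ... and its global-reference renormalisation: what a noise-free
          # quantification with denominator = "global" returns exactly
          pi_true = unname(planted / mean(planted)),
          change_factor = unname(f[rel]),
          stringsAsFactors = FALSE)
      }
    }
    list(tables = do.call(rbind, tabs),
         clinical = clin,
         truth = do.call(rbind, truth))
  })
}

#' Configuration for synthetic phantom volumes
#'
#' @param grid_shape Integer(3) volume dimensions in voxels.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum, mm.
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param poisson_scale Expected counts per voxel at PI = 1.
#' @param poisson Whether to Poisson-sample the blurred activity.
#' @param gap_voxels Empty voxels between neighbouring ROI blocks (0 makes
#'   blocks adjacent, maximising partial-volume cross-talk).
#' @param seed Integer seed for the Poisson stage.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L), psf_fwhm_mm = 8,
                           voxel_size_mm = 3, poisson_scale = 100,
                           poisson = FALSE, gap_voxels = 0L, seed = 1L) {
  if (psf_fwhm_mm < 0) abort("psf_fwhm_mm must be >= 0")
  if (poisson_scale <= 0) abort("poisson_scale must be > 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 psf_fwhm_mm = psf_fwhm_mm, voxel_size_mm = voxel_size_mm,
                 poisson_scale = poisson_scale, poisson = poisson,
                 gap_voxels = as.integer(gap_voxels), seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a blurred block phantom for the quantification stage
#'
#' Tiles one rectangular ROI per requested structure onto a 3-D grid (disjoint
#' blocks, optionally separated by a gap), sets the noiseless activity inside
#' each block to `true PI x poisson_scale`, convolves the volume with the
#' Gaussian PSF, and optionally Poisson-samples the result. The grey-matter
#' mask is the union of the blocks.
#'
#' @param config A [phantom_config()].
#' @param atlas An `atlas_spec`; label values are the catalogue ids of the
#'   structures named in `true_pi`.
#' @param true_pi Named numeric vector (or [perfusion_vector()]) of planted
#'   PI values, named by catalogue structure names.
#' @return List with 3-D arrays `activity`, `labels`, `gm_mask`, plus the
#'   block `placement` table.
#' @export
generate_phantom <- function(config, atlas, true_pi) {
  stopifnot(inherits(config, "phantom_config"))
  nm <- names(true_pi)
  ids <- atlas$id[match(nm, atlas$name)]
  if (anyNA(ids)) {
    abort("structure name(s) not in atlas: %s", paste(nm[is.na(ids)], collapse = ", "))
  }
  n <- length(true_pi)
  g <- config$grid_shape
  counts <- rep(ceiling(n^(1 / 3)), 3L)
  slot <- floor(g / counts)
  size <- slot - config$gap_voxels
  if (any(size < 1L)) {
    abort("grid %s too small to place %d disjoint ROI blocks",
          paste(g, collapse = "x"), n)
  }
  labels <- array(0L, g)
  placement <- data.frame(structure = nm, id = ids,
                          x0 = NA_integer_, y0 = NA_integer_, z0 = NA_integer_)
  k <- 0L
  for (iz in seq_len(counts[3])) for (iy in seq_len(counts[2])) for (ix in seq_len(counts[1])) {
    k <- k + 1L
    if (k > n) break
    x <- (ix - 1L) * slot[1] + seq_len(size[1])
    y <- (iy - 1L) * slot[2] + seq_len(size[2])
    z <- (iz - 1L) * slot[3] + seq_len(size[3])
    if (any(labels[x, y, z] != 0L)) abort("internal error: overlapping ROI placement")
    labels[x, y, z] <- ids[k]
    placement[k, c("x0", "y0", "z0")] <- c(x[1], y[1], z[1])
  }
  if (k < n) abort("grid too small to place all ROI blocks")
  activity <- array(0, g)
  for (j in seq_len(n)) {
    activity[labels == ids[j]] <- as.numeric(true_pi[j]) * config$poisson_scale
  }
  activity <- gaussian_blur(activity, config$psf_fwhm_mm, config$voxel_size_mm)
  if (config$poisson) {
    activity <- with_seed(config$seed, {
      array(stats::rpois(length(activity), pmax(activity, 0)), g)
    })
  }
  list(activity = activity, labels = labels,
       gm_mask = array(as.integer(labels != 0L), g),
       placement = placement)
}

#' Write a cohort to disk as plain CSV (plus NIfTI phantoms elsewhere)
#'
#' @param cohort Result of [generate_roi_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("roi_tables.csv", "clinical.csv", "truth.csv"))
  utils::write.csv(cohort$tables, paths[1], row.names = FALSE)
  utils::write.csv(cohort$clinical, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
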