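#' Construct a perfusion vector
#'
#' A perfusion vector holds one value per atlas structure for a single scan:
#' perfusion indexes for an `interictal` or `ictal` scan, or relative changes
#' for the derived `change` state.
#'
#' @param values Named numeric vector (names are structure names).
#' @param patient Patient identifier.
#' @param state One of `"interictal"`, `"ictal"`, `"change"`.
#' @return A named numeric vector of class `perfusion_vector` with
#'   `patient` and `state` attributes.
#' @export
perfusion_vector <- function(values, patient = NA_character_, state = "interictal") {
  if (!state %in% c("interictal", "ictal", "change")) {
    abort("unknown state '%s'", state)
  }
  if (is.null(names(values)) || anyNA(names(values))) {
    abort("perfusion vector values must be named by structure")
  }
  if (state != "change" && any(values <= 0)) {
    abort("perfusion indexes must be positive")
  }
  if (state == "change" && any(values <= -1)) {
    abort("relative changes must be > -1")
  }
  structure(as.numeric(values),
            names = names(values),
            patient = patient, state = state,
            class = "perfusion_vector")
}

#' @export
print.perfusion_vector <- function(x, ...) {
  cat(sprintf("<perfusion_vector> patient=%s state=%s (%d structures)\n",
              attr(x, "patient"), attr(x, "state"), length(x)))
  print(utils::head(stats::setNames(as.numeric(x), names(x))), ...)
  invisible(x)
}

#' Regional mean activity from co-registered volumes
#'
#' Computes, for every atlas structure, the mean tracer activity (counts per
#' voxel) over the voxels carrying that structure's label *and* lying inside
#' the grey-matter mask — the masking excludes ventricular and extracerebral
#' CSF from every mean. Structures left with no voxels after masking are
#' omitted from the table (recorded in the `absent` attribute), never reported
#' as zero activity.
#'
#' @param activity 3-D numeric array of reconstructed activity.
#' @param labels 3-D integer array of atlas label ids (0 = background) on the
#'   same grid.
#' @param gm_mask 3-D binary array (grey matter = 1) on the same grid.
#' @param atlas An `atlas_spec`.
#' @param patient,state Identifiers stored in the output table.
#' @return A ROI activity table: data frame with columns `patient`, `state`,
#'   `structure_id`, `structure`, `n_voxels`, `mean_counts`.
#' @export
compute_roi_means <- function(activity, labels, gm_mask, atlas,
                              patient = NA_character_, state = "interictal") {
  if (!identical(dim(activity), dim(labels)) ||
      !identical(dim(activity), dim(gm_mask))) {
    abort("activity, labels and gm_mask must share the same grid")
  }
  mask <- gm_mask != 0
  if (!any(mask)) abort("grey-matter mask is empty")
  lab <- as.integer(labels)
  lab[!mask] <- 0L
  act <- as.numeric(activity)
  present <- sort(intersect(unique(lab[lab > 0L]), atlas$id))
  if (!length(present)) abort("no atlas labels present inside the mask")
  idx <- lab %in% present
  sums <- tapply(act[idx], lab[idx], sum)
  ns <- tapply(rep(1L, sum(idx)), lab[idx], sum)
  ids <- as.integer(names(sums))
  out <- data.frame(
    patient = patient, state = state,
    structure_id = ids,
    structure = atlas$name[match(ids, atlas$id)],
    n_voxels = as.integer(ns),
    mean_counts = as.numeric(sums / ns),
    stringsAsFactors = FALSE)
  attr(out, "absent") <- setdiff(atlas$name, out$structure)
  out
}

#' Separable Gaussian blur of a 3-D volume
#'
#' Models the scanner point-spread function as an isotropic (or per-axis)
#' Gaussian, applied as three 1-D convolutions with zero padding at the
#' volume edges. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Full width at half maximum of the PSF in mm; scalar or
#'   length-3 for per-axis widths.
#' @param voxel_size_mm Voxel edge length in mm (isotropic).
#' @return Blurred array of the same dimensions.
#' @export
gaussian_blur <- function(vol, fwhm_mm, voxel_size_mm = 1) {
  if (length(dim(vol)) != 3L) abort("expected a 3-D array")
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) abort("fwhm must be >= 0")
  if (all(fwhm_mm == 0)) return(vol)
  for (axis in 1:3) {
    sigma <- fwhm_mm[axis] / (2 * sqrt(2 * log(2))) / voxel_size_mm
    if (sigma == 0) next
    r <- max(1L, ceiling(4 * sigma))
    kern <- stats::dnorm(seq(-r, r), sd = sigma)
    kern <- kern / sum(kern)
    vol <- convolve_axis(vol, kern, axis)
  }
  vol
}

# 1-D zero-padded convolution along one axis, via a banded matrix product
#' @noRd
convolve_axis <- function(vol, kern, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kern) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kern[off + r + 1L]
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  out <- K %*% matrix(v, nrow = n)
  dim(out) <- dv
  aperm(out, order(perm))
}

#' Region-based partial-volume correction (geometric transfer matrix)
#'
#' SPECT resolution mixes signal between neighbouring regions; at the ROI
#' level this is a linear contamination described by the geometric transfer
#' matrix `W`, where `W[i, j]` is the mean, over the voxels of region `i`, of
#' the PSF-blurred indicator of region `j`. Observed ROI means satisfy
#' `observed = W %*% true`, so the corrected means are the solution of that
#' linear system. With `fwhm = 0`, `W` is the identity and the input is
#' returned unchanged. Row sums of `W` never exceed 1 (blur only moves signal
#' out of the brain, never creates it).
#'
#' @param table ROI activity table from [compute_roi_means()] (its
#'   `structure_id`s must be labels present in `labels`).
#' @param labels 3-D integer label array.
#' @param gm_mask 3-D binary grey-matter mask on the same grid.
#' @param psf_fwhm_mm PSF full width at half maximum in mm.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param max_condition Condition-number threshold above which the system is
#'   considered ill-posed.
#' @return The table with `mean_counts` replaced by corrected means.
#' @export
pvc_region_gtm <- function(table, labels, gm_mask, psf_fwhm_mm,
                           voxel_size_mm = 1, max_condition = 1e8) {
  if (!is.finite(psf_fwhm_mm) || psf_fwhm_mm < 0) abort("psf_fwhm_mm must be finite and >= 0")
  if (nrow(table) < 2L) {
    abort("partial-volume correction needs >= 2 regions (cross-talk is a between-region system)")
  }
  if (psf_fwhm_mm == 0) return(table)
  if (!identical(dim(labels), dim(gm_mask))) abort("labels and gm_mask must share the same grid")
  mask <- gm_mask != 0
  ids <- table$structure_id
  lab <- as.integer(labels)
  lab[!mask] <- 0L
  m <- length(ids)
  W <- matrix(0, m, m)
  roi_idx <- lapply(ids, function(id) which(lab == id))
  if (any(lengths(roi_idx) == 0L)) {
    abort("structure id(s) absent from label volume: %s",
          paste(ids[lengths(roi_idx) == 0L], collapse = ", "))
  }
  for (j in seq_len(m)) {
    ind <- array(0, dim(labels))
    ind[roi_idx[[j]]] <- 1
    b <- gaussian_blur(ind, psf_fwhm_mm, voxel_size_mm)
    for (i in seq_len(m)) W[i, j] <- mean(b[roi_idx[[i]]])
  }
  cn <- kappa(W, exact = TRUE)
  if (!is.finite(cn) || cn > max_condition) {
    abort(paste0("geometric transfer matrix is ill-conditioned (condition number %.3g); ",
                 "use larger ROIs or a smaller PSF"), cn)
  }
  corrected <- solve(W, table$mean_counts)
  table$mean_counts <- as.numeric(corrected)
  table
}

#' Perfusion index of each atlas structure
#'
#' The perfusion index (PI) expresses each region's mean activity relative to
#' global grey-matter perfusion; values above 1 indicate relative
#' hyperperfusion. The reference is, by default, the mean activity of the
#' *rest* of the grey matter — a voxel-count-weighted leave-one-out mean that
#' excludes the region itself — with a `"global"` option that divides by the
#' whole-grey-matter mean instead. PIs are invariant to rescaling all
#' activities by a common factor, so they are comparable across scans with
#' different injected doses.
#'
#' @param table ROI activity table for a single scan (columns `structure`,
#'   `n_voxels`, `mean_counts`; one row per structure).
#' @param denominator `"rest"` (leave-one-out grey-matter mean, default) or
#'   `"global"` (whole grey-matter mean).
#' @return A [perfusion_vector()] named by structure.
#' @examples
#' tab <- data.frame(structure = c("a", "b", "c"), n_voxels = 10,
#'                   mean_counts = c(2, 1, 1))
#' perfusion_index(tab)            # 2.0, 0.667, 0.667
#' perfusion_index(tab, "global")  # 1.5, 0.75, 0.75
#' @export
perfusion_index <- function(table, denominator = c("rest", "global")) {
  denominator <- match.arg(denominator)
  if (nrow(table) < 2L) abort("perfusion index needs >= 2 structures")
  if (anyDuplicated(table$structure)) {
    abort("duplicate structure rows in scan table")
  }
  n <- if ("n_voxels" %in% names(table)) as.numeric(table$n_voxels) else rep(1, nrow(table))
  m <- as.numeric(table$mean_counts)
  if (any(!is.finite(m)) || any(m < 0)) abort("mean_counts must be finite and >= 0")
  if (any(n < 1)) abort("n_voxels must be >= 1 for included structures")
  Tsum <- sum(n * m); N <- sum(n)
  denom <- switch(denominator,
    global = rep(Tsum / N, nrow(table)),
    rest = (Tsum - n * m) / (N - n))
  if (any(denom <= 0)) abort("zero or negative reference activity; cannot form perfusion index")
  pi_vals <- m / denom
  perfusion_vector(stats::setNames(pi_vals, table$structure),
                   patient = if ("patient" %in% names(table)) table$patient[1] else NA_character_,
                   state = if ("state" %in% names(table)) table$state[1] else "interictal")
}

#' Relative interictal-to-ictal perfusion change
#'
#' For each structure, the change is the ictal PI minus the interictal PI,
#' expressed as a fraction of the interictal PI: 0 means the region's relative
#' perfusion was invariant across the transition, +0.30 a 30 % increase,
#' -0.20 a 20 % decrease.
#'
#' @param interictal,ictal [perfusion_vector()]s for the same patient covering
#'   the same structure set.
#' @return A `perfusion_vector` with state `"change"`.
#' @export
change_vector <- function(interictal, ictal) {
  if (!setequal(names(interictal), names(ictal))) {
    abort("interictal and ictal vectors cover different structure sets")
  }
  p1 <- attr(interictal, "patient"); p2 <- attr(ictal, "patient")
  if (!is.na(p1) && !is.na(p2) && !identical(p1, p2)) {
    abort("interictal and ictal vectors belong to different patients ('%s' vs '%s')", p1, p2)
  }
  ict <- as.numeric(ictal[names(interictal)])
  int <- as.numeric(interictal)
  perfusion_vector(stats::setNames((ict - int) / int, names(interictal)),
                   patient = p1 %||% p2, state = "change")
}

#' Read / write ROI and PI tables as CSV
#'
#' Long-format plumbing used by the pipeline: ROI tables as
#' `patient,state,structure,n_voxels,mean_counts`, perfusion vectors as
#' `patient,state,structure,value`.
#'
#' @param vectors A list of `perfusion_vector`s.
#' @return `pi_long()` returns a long data frame; `pi_vectors_from_long()`
#'   rebuilds the list of vectors.
#' @export
pi_long <- function(vectors) {
  do.call(rbind, lapply(vectors, function(v) {
    data.frame(patient = attr(v, "patient"), state = attr(v, "state"),
               structure = names(v), value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname pi_long
#' @param df Long data frame with columns `patient`, `state`, `structure`,
#'   `value`.
#' @export
pi_vectors_from_long <- function(df) {
  key <- interaction(df$patient, df$state, drop = TRUE)
  lapply(split(df, key), function(d) {
    perfusion_vector(stats::setNames(d$value, d$structure),
                     patient = d$patient[1], state = d$state[1])
  })
}
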