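#' Default SUDEP-7 item weights
#'
#' The inventory's published range is 0-10 under its mutual-exclusion rules
#' (item 2 scores 0 when item 1 is present; item 3 scores 0 when item 4 is
#' present), but the individual item weights are not published. The default
#' weights `(2, 1, 1, 2, 2, 2, 2)` for items 1-7 reach exactly that ceiling
#' (2 + 2 + 2 + 2 + 2 = 10 with items 1, 4, 5, 6, 7 present) and allow odd
#' totals; they are a package convention, configurable everywhere they are
#' used, and carry no claim of clinical validation.
#'
#' @return Integer vector of length 7.
#' @export
sudep7_default_weights <- function() c(2L, 1L, 1L, 2L, 2L, 2L, 2L)

#' Score the SUDEP-7 risk inventory
#'
#' The seven items are: 1 generalized tonic-clonic (GTC) seizures > 3 in the
#' last year; 2 GTC seizures > 0 in the last year; 3 any seizure > 0 in the
#' last year; 4 any seizure > 50 per month; 5 epilepsy duration >= 30 years;
#' 6 three or more antiepileptic drugs; 7 intellectual disability. Item 2
#' contributes 0 when item 1 is present, and item 3 contributes 0 when item 4
#' is present. Patients with a total score above 5 fall in the high-risk
#' stratum.
#'
#' @param items Either a logical vector of length 7 (one patient) or a data
#'   frame with logical columns `i1`..`i7` (one row per patient; other
#'   columns pass through untouched).
#' @param weights Per-item integer weights; see [sudep7_default_weights()].
#' @return Data frame with columns `score` (0-10) and `stratum`
#'   (`"high"` if score > 5, else `"low"`), preceded by a `patient` column
#'   when the input had one.
#' @examples
#' score_sudep7(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))  # 2+0+2+2+2 = 8
#' @export
score_sudep7 <- function(items, weights = sudep7_default_weights()) {
  if (length(weights) != 7L) abort("weights must have length 7")
  if (is.data.frame(items)) {
    cols <- paste0("i", 1:7)
    if (!all(cols %in% names(items))) {
      abort("clinical table must have logical columns i1..i7")
    }
    M <- as.matrix(items[cols])
  } else {
    if (length(items) != 7L) abort("items must have length 7")
    M <- matrix(items, nrow = 1, dimnames = list(NULL, paste0("i", 1:7)))
  }
  M <- M != 0
  eff <- M
  eff[, "i2"] <- M[, "i2"] & !M[, "i1"]
  eff[, "i3"] <- M[, "i3"] & !M[, "i4"]
  score <- as.integer(eff %*% as.numeric(weights))
  max_score <- max(weights[1], weights[2]) + max(weights[3], weights[4]) +
    sum(weights[5:7])
  if (max_score > 10L) {
    abort("weights allow scores above the inventory's 0-10 range")
  }
  out <- data.frame(score = score,
                    stratum = ifelse(score > 5L, "high", "low"),
                    stringsAsFactors = FALSE)
  if (is.data.frame(items) && "patient" %in% names(items)) {
    out <- cbind(items["patient"], out)
  }
  out
}

#' Maximum achievable SUDEP-7 score under the exclusion rules
#'
#' The best attainable total takes the larger of items 1/2 and of items 3/4
#' (each pair is mutually exclusive in its contribution) plus items 5-7.
#'
#' @inheritParams score_sudep7
#' @return Integer maximum score (10 under the default weights).
#' @export
sudep7_max_score <- function(weights = sudep7_default_weights()) {
  if (length(weights) != 7L) abort("weights must have length 7")
  as.integer(max(weights[1], weights[2]) + max(weights[3], weights[4]) +
               sum(weights[5:7]))
}

#' Screen perfusion-change features against the SUDEP-7 score
#'
#' For each structure, its change values across patients are divided into
#' `n_intervals` equal-width intervals over the structure's observed range;
#' empty intervals are dropped, and the one-way F statistic of the SUDEP-7
#' score across the occupied intervals (between-interval mean square over
#' within-interval mean square, df = occupied - 1 and n - occupied) measures
#' how strongly the structure's change pattern separates the outcome, without
#' assuming any shape of relationship. Because the number of occupied
#' intervals — and hence the F degrees of freedom — varies between
#' structures, raw F values are not comparable across structures; ranking is
#' therefore by the tail probability of each structure's F statistic (ties
#' broken by larger F), and the top-`top_k` or those with p below
#' `p_threshold` are marked selected.
#'
#' A structure with zero range, fewer than two occupied intervals, no
#' within-interval degrees of freedom, or zero residual variance has no valid
#' F; it is ranked after every valid structure and flagged.
#'
#' The binning is invariant to affine rescaling of a structure's change
#' values, because the interval edges rescale with the range.
#'
#' @param X Numeric matrix of change values, patients in rows, structures in
#'   columns (column names required).
#' @param y Numeric SUDEP-7 scores, one per patient.
#' @param n_intervals Number of equal-width intervals (>= 2). More intervals
#'   than half the number of patients would make most occupied bins
#'   singletons and starve the residual degrees of freedom, so the effective
#'   count is capped at `floor(n / 2)`.
#' @param top_k Number of top-ranked structures marked selected.
#' @param p_threshold Structures with p below this are also selected.
#' @return Data frame of class `screen_result`: `structure`, `F`, `df_between`,
#'   `df_within`, `p`, `valid`, `rank`, `selected`, ordered by rank.
#' @export
screen_features <- function(X, y, n_intervals = 10L, top_k = 3L,
                            p_threshold = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) abort("X must have structure column names")
  if (nrow(X) != length(y)) abort("X rows and y length differ")
  if (n_intervals < 2L) abort("n_intervals must be >= 2")
  n <- length(y)
  n_intervals <- max(2L, min(as.integer(n_intervals), n %/% 2L))
  one <- function(x) {
    rng <- range(x)
    if (!is.finite(diff(rng)) || diff(rng) == 0) {
      return(c(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
    }
    edges <- seq(rng[1], rng[2], length.out = n_intervals + 1L)
    bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    bin <- match(bin, sort(unique(bin)))  # drop empty intervals
    g <- max(bin)
    if (g < 2L || n - g < 1L) {
      return(c(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
    }
    gm <- tapply(y, bin, mean)
    ssb <- sum(tabulate(bin, g) * (gm - mean(y))^2)
    ssw <- sum((y - gm[bin])^2)
    df1 <- g - 1L; df2 <- n - g
    if (ssb <= 0) {  # outcome constant across bins: no signal by definition
      return(c(F = 0, df1 = df1, df2 = df2, p = 1))
    }
    if (ssw <= 0) {  # perfect separation: infinite F, smallest possible p
      return(c(F = Inf, df1 = df1, df2 = df2, p = 0))
    }
    Fv <- (ssb / df1) / (ssw / df2)
    c(F = Fv, df1 = df1, df2 = df2,
      p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  res <- t(apply(X, 2, one))
  out <- data.frame(structure = colnames(X),
                    F = res[, "F"],
                    df_between = as.integer(res[, "df1"]),
                    df_within = as.integer(res[, "df2"]),
                    p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$valid <- !is.na(out$F)
  # rank by p ascending (F-tail probability accounts for the per-structure
  # degrees of freedom), ties by F descending; invalid structures last
  ord <- order(ifelse(out$valid, out$p, Inf), -ifelse(out$valid, out$F, -Inf))
  out$rank <- integer(nrow(out)); out$rank[ord] <- seq_len(nrow(out))
  out$selected <- out$valid & (out$rank <= top_k |
                               (!is.na(out$p) & out$p < p_threshold))
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); the
#' statistic used to relate per-patient structure counts to SUDEP-7 scores.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    abort("correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Build the change-value matrix for screening
#'
#' @param change_vectors List of `perfusion_vector`s with state `"change"`,
#'   all covering the same structure set (seizure-onset-relative names).
#' @return Numeric matrix, patients in rows (named), structures in columns.
#' @export
change_matrix <- function(change_vectors) {
  if (!length(change_vectors)) abort("no change vectors supplied")
  structs <- names(change_vectors[[1]])
  rows <- lapply(change_vectors, function(v) {
    if (!setequal(names(v), structs)) {
      abort("change vectors cover different structure sets")
    }
    as.numeric(v[structs])
  })
  M <- do.call(rbind, rows)
  rownames(M) <- vapply(change_vectors, function(v) attr(v, "patient"), character(1))
  colnames(M) <- structs
  M
}
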