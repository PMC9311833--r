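#' Reference cohort cluster summary
#'
#' The per-patient, per-state summary of the extreme perfusion clusters
#' reported for the nine-patient reference cohort (see
#' [reference_clinical()]): for each scan state (and the
#' interictal-to-ictal change) the mean and SD of the perfusion index over
#' the hypoperfused and hyperperfused cluster members, with the `N/N_subc`
#' structure counts. Bundled as a plain-text fixture; used to recompute the
#' cohort-level descriptive statistics without access to the imaging data.
#'
#' @return Data frame with columns `patient`, `state`, `role`, `mean`, `sd`,
#'   `n`, `n_subcortical`.
#' @export
reference_cluster_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_cluster_summary.csv",
                              package = "sudepspect"),
                  stringsAsFactors = FALSE)
}

#' Cross-patient consistency of extreme perfusion sets
#'
#' Counts, for every structure, in how many patients it fell into the
#' hypoperfused (or hyperperfused / change-increase / change-decrease)
#' extreme cluster of a given state, and expresses the count as a percentage
#' of the cohort. This is the tabular form of a percent-match brain map.
#'
#' @param extreme_sets Data frame with columns `patient`, `state`, `role`
#'   (`hypo`/`hyper`), `structure`: one row per structure per patient's
#'   extreme set. For change-state vectors, role `hypo` is the decrease set
#'   and `hyper` the increase set.
#' @param n_patients Cohort size (denominator).
#' @param percent_style `"round"` (to one decimal) or `"truncate"` (drop
#'   digits past the first decimal, the convention used when 8/9 is printed
#'   as 88.8).
#' @return Data frame `structure`, `state`, `role`, `count`, `percent`,
#'   sorted by descending count within state/role.
#' @examples
#' sets <- data.frame(patient = c("P1", "P2", "P3"), state = "ictal",
#'                    role = "hypo", structure = "medulla")
#' match_frequencies(sets, n_patients = 3)
#' @export
match_frequencies <- function(extreme_sets, n_patients,
                              percent_style = c("round", "truncate")) {
  percent_style <- match.arg(percent_style)
  if (n_patients < 1L) abort("n_patients must be >= 1")
  if (nrow(extreme_sets) == 0L) {
    return(data.frame(structure = character(0), state = character(0),
                      role = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  dup <- duplicated(extreme_sets[c("patient", "state", "role", "structure")])
  extreme_sets <- extreme_sets[!dup, , drop = FALSE]
  agg <- stats::aggregate(list(count = extreme_sets$patient),
                          by = extreme_sets[c("structure", "state", "role")],
                          FUN = length)
  if (any(agg$count > n_patients)) {
    abort("a structure is counted in more patients than n_patients")
  }
  pct <- 100 * agg$count / n_patients
  agg$percent <- switch(percent_style,
                        round = round(pct, 1),
                        truncate = floor(pct * 10) / 10)
  agg <- agg[order(agg$state, agg$role, -agg$count, agg$structure), ]
  rownames(agg) <- NULL
  agg
}

#' Per-scan summary of the extreme clusters
#'
#' Builds the per-patient, per-state summary rows of the extreme clusters:
#' mean and sample SD of the member perfusion values, the number of member
#' structures and how many are subcortical, with the patient's injection
#' latency and seizure duration attached when a clinical table is given.
#' A single-member cluster has no sample SD; it is reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param solutions Named list of `cluster_solution`s, one per scan; names are
#'   `<patient>.<state>`.
#' @param vectors Named list of [perfusion_vector()]s aligned with
#'   `solutions`.
#' @param atlas An `atlas_spec`.
#' @param clinical Optional clinical table with `patient`,
#'   `injection_time_s`, `seizure_duration_s`.
#' @return Data frame with one row per scan and role: `patient`, `state`,
#'   `role`, `mean`, `sd`, `sd_defined`, `n`, `n_subcortical`, and clinical
#'   columns when available.
#' @export
summarize_clusters <- function(solutions, vectors, atlas, clinical = NULL) {
  if (!identical(names(solutions), names(vectors))) {
    abort("solutions and vectors must be aligned (same names, same order)")
  }
  rows <- lapply(names(solutions), function(key) {
    sol <- solutions[[key]]; vec <- vectors[[key]]
    ext <- label_extremes(sol, atlas)
    do.call(rbind, lapply(c("hypo", "hyper"), function(role) {
      members <- ext[[role]]
      vals <- as.numeric(vec[members])
      n <- length(members)
      data.frame(patient = attr(vec, "patient"), state = attr(vec, "state"),
                 role = role,
                 mean = if (n) mean(vals) else NA_real_,
                 sd = if (n > 1) stats::sd(vals) else 0,
                 sd_defined = n > 1,
                 n = n,
                 n_subcortical = ext$counts$n_subcortical[ext$counts$role == role],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (!is.null(clinical)) {
    keep <- intersect(c("patient", "injection_time_s", "seizure_duration_s"),
                      names(clinical))
    out <- merge(out, clinical[keep], by = "patient", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Descriptive statistics of a numeric sample
#'
#' Mean, sample SD (n - 1 denominator), standard error of the mean, median
#' (mean of the two middle order statistics for even n), minimum and maximum.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `n`, `mean`, `sd`, `se`, `median`, `min`, `max`.
#' @examples
#' describe_values(c(3, 5, 7, 7, 7, 4, 7, 7, 4))
#' @export
describe_values <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 1L || anyNA(x)) abort("values must be non-empty and free of NA")
  n <- length(x)
  s <- if (n > 1) stats::sd(x) else 0
  list(n = n, mean = mean(x), sd = s, se = s / sqrt(n),
       median = stats::median(x), min = min(x), max = max(x))
}
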