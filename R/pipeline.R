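#' Configuration for a full pipeline run
#'
#' Collects every tunable of the simulate -> quantify -> cluster -> summarize
#' -> screen pipeline in one serialisable object, so a run is reproducible
#' from its config and seed alone.
#'
#' @param seed Master seed; the cohort seed and per-scan clustering seeds are
#'   derived from it.
#' @param out_dir Output directory for stage outputs and the run report.
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param pi_denominator `"rest"` or `"global"` perfusion-index reference.
#' @param k_candidates,folds,improvement_threshold,n_restarts,engine
#'   K-selection and k-means parameters (see [select_k_vfold()]).
#' @param n_intervals,top_k,p_threshold Screening parameters (see
#'   [screen_features()]).
#' @param weights SUDEP-7 item weights.
#' @param percent_style Percent formatting for the match table.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 42L, out_dir = tempfile("sudepspect_run_"),
                       cohort = cohort_config("reference"),
                       pi_denominator = "rest",
                       k_candidates = 2:10, folds = 10L,
                       improvement_threshold = 0.05, n_restarts = 20L,
                       engine = "lloyd",
                       n_intervals = 10L, top_k = 3L, p_threshold = 0.05,
                       weights = sudep7_default_weights(),
                       percent_style = "round") {
  if (!pi_denominator %in% c("rest", "global")) {
    abort("unknown PI denominator mode '%s' (use 'rest' or 'global')", pi_denominator)
  }
  if (!engine %in% c("lloyd", "dp")) abort("unknown engine '%s'", engine)
  if (!percent_style %in% c("round", "truncate")) {
    abort("unknown percent style '%s'", percent_style)
  }
  stopifnot(inherits(cohort, "cohort_config"))
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
                 pi_denominator = pi_denominator,
                 k_candidates = as.integer(k_candidates),
                 folds = as.integer(folds),
                 improvement_threshold = improvement_threshold,
                 n_restarts = as.integer(n_restarts), engine = engine,
                 n_intervals = as.integer(n_intervals),
                 top_k = as.integer(top_k), p_threshold = p_threshold,
                 weights = as.integer(weights),
                 percent_style = percent_style),
            class = "run_config")
}

# split a long ROI table into per-scan tables, relabeled to ipsi/contra
#' @noRd
scan_tables <- function(tables, clinical, atlas) {
  key <- interaction(tables$patient, tables$state, drop = TRUE)
  out <- lapply(split(tables, key), function(d) {
    side <- clinical$onset_side[match(d$patient[1], clinical$patient)]
    relabel_ipsilateral(d, side, atlas)
  })
  names(out) <- vapply(out, function(d) paste(d$patient[1], d$state[1], sep = "."),
                       character(1))
  out
}

#' Cluster one perfusion vector: select K, fit, label extremes
#'
#' @param vec A [perfusion_vector()].
#' @param atlas An `atlas_spec`.
#' @param config A [run_config()] supplying the clustering parameters.
#' @param seed Seed for fold assignment and restarts.
#' @return List `trace` (K-selection), `solution`, `extremes`.
#' @export
cluster_scan <- function(vec, atlas, config = run_config(), seed = config$seed) {
  trace <- select_k_vfold(vec, k_candidates = config$k_candidates,
                          folds = config$folds,
                          improvement_threshold = config$improvement_threshold,
                          seed = seed, n_restarts = config$n_restarts,
                          engine = config$engine)
  sol <- if (config$engine == "dp") kmeans_1d_dp(vec, trace$chosen_k)
         else kmeans_1d(vec, trace$chosen_k, n_restarts = config$n_restarts,
                        seed = seed + 1L)
  ext <- if (trace$chosen_k >= 2L) label_extremes(sol, atlas) else NULL
  list(trace = trace, solution = sol, extremes = ext)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic cohort (or a supplied ROI
#' table): quantification to perfusion indexes, interictal-to-ictal change,
#' per-scan clustering with cross-validated K, extreme-cluster labeling,
#' cross-patient match frequencies, per-scan cluster summaries, cohort
#' descriptives, SUDEP-7 scoring, change-feature screening against the
#' SUDEP-7 score, and the rank correlation between hypoperfused-structure
#' counts and the score. All stage outputs are written as plain CSV/JSON
#' under `config$out_dir` together with `report.md` and the serialised
#' config; the run is deterministic given the config.
#'
#' @param config A [run_config()].
#' @param atlas An `atlas_spec`.
#' @param tables Optional pre-computed long ROI table (columns as produced by
#'   [generate_roi_cohort()]); when given, the simulate stage is skipped and
#'   `clinical` must be supplied too.
#' @param clinical Optional clinical table accompanying `tables`.
#' @return Invisibly, a list with all stage results (`pi`, `clusters`,
#'   `match_table`, `cluster_summary`, `descriptives`, `sudep7`, `screen`,
#'   `spearman`, `paths`).
#' @export
run_all <- function(config = run_config(), atlas = load_atlas_spec(),
                    tables = NULL, clinical = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  logline("run seed=%d engine=%s pi_denominator=%s", config$seed,
          config$engine, config$pi_denominator)

  if (is.null(tables)) {
    cohort <- stage("simulate", generate_roi_cohort(config$cohort, atlas))
    tables <- cohort$tables
    clinical <- cohort$clinical
  } else {
    if (is.null(clinical)) abort("clinical table required with pre-computed ROI tables")
    scored <- score_sudep7(clinical, config$weights)
    clinical$score <- scored$score
    clinical$stratum <- scored$stratum
  }
  logline("cohort: %d patients, %d table rows",
          length(unique(tables$patient)), nrow(tables))

  scans <- stage("relabel", scan_tables(tables, clinical, atlas))
  vectors <- stage("perfusion_index", lapply(scans, perfusion_index,
                                             denominator = config$pi_denominator))
  patients <- clinical$patient
  changes <- stage("change", {
    out <- lapply(patients, function(p) {
      change_vector(vectors[[paste0(p, ".interictal")]],
                    vectors[[paste0(p, ".ictal")]])
    })
    names(out) <- paste0(patients, ".change")
    out
  })
  all_vecs <- c(vectors, changes)

  clusters <- stage("cluster", {
    out <- vector("list", length(all_vecs))
    names(out) <- names(all_vecs)
    for (i in seq_along(all_vecs)) {
      out[[i]] <- cluster_scan(all_vecs[[i]], atlas, config,
                               seed = config$seed + 100L + i)
    }
    out
  })
  logline("clusters: chosen K = %s",
          paste(vapply(clusters, function(z) z$trace$chosen_k, integer(1)),
                collapse = ","))

  extreme_sets <- do.call(rbind, lapply(names(clusters), function(key) {
    ext <- clusters[[key]]$extremes
    if (is.null(ext)) return(NULL)
    v <- all_vecs[[key]]
    do.call(rbind, lapply(c("hypo", "hyper"), function(role) {
      if (!length(ext[[role]])) return(NULL)
      data.frame(patient = attr(v, "patient"), state = attr(v, "state"),
                 role = role, structure = ext[[role]], stringsAsFactors = FALSE)
    }))
  }))
  match_table <- stage("match", match_frequencies(extreme_sets,
                                                  n_patients = length(patients),
                                                  percent_style = config$percent_style))

  scan_keys <- names(vectors)  # interictal + ictal only for the PI summary
  summary_tab <- stage("summarize", summarize_clusters(
    lapply(clusters[scan_keys], `[[`, "solution"),
    all_vecs[scan_keys], atlas, clinical))

  descriptives <- stage("describe", list(
    sudep7_score = describe_values(clinical$score),
    injection_time_s = if ("injection_time_s" %in% names(clinical))
      describe_values(clinical$injection_time_s) else NULL,
    seizure_duration_s = if ("seizure_duration_s" %in% names(clinical))
      describe_values(clinical$seizure_duration_s) else NULL))

  screen <- stage("screen", {
    M <- change_matrix(changes)
    screen_features(M[clinical$patient, , drop = FALSE], clinical$score,
                    n_intervals = config$n_intervals, top_k = config$top_k,
                    p_threshold = config$p_threshold)
  })

  spearman <- stage("spearman", {
    hypo_counts <- vapply(patients, function(p) {
      ext <- clusters[[paste0(p, ".ictal")]]$extremes
      if (is.null(ext)) NA_integer_ else length(ext$hypo)
    }, integer(1))
    hypo_subc <- vapply(patients, function(p) {
      ext <- clusters[[paste0(p, ".ictal")]]$extremes
      if (is.null(ext)) NA_integer_
      else sum(structure_class(ext$hypo, atlas) == "subcortical")
    }, integer(1))
    list(
      ictal_hypo_n_vs_score = tryCatch(
        spearman_rho(hypo_counts, clinical$score), error = function(e) NA_real_),
      ictal_hypo_nsubc_vs_score = tryCatch(
        spearman_rho(hypo_subc, clinical$score), error = function(e) NA_real_))
  })

  paths <- write_run_outputs(config, tables, clinical, all_vecs, clusters,
                             match_table, summary_tab, descriptives, screen,
                             spearman)
  logline("done; outputs in %s", config$out_dir)
  invisible(list(pi = all_vecs, clusters = clusters, match_table = match_table,
                 cluster_summary = summary_tab, descriptives = descriptives,
                 sudep7 = clinical[c("patient", "score", "stratum")],
                 screen = screen, spearman = spearman, clinical = clinical,
                 tables = tables, paths = paths))
}

#' @noRd
write_run_outputs <- function(config, tables, clinical, vecs, clusters,
                              match_table, summary_tab, descriptives, screen,
                              spearman) {
  out <- config$out_dir
  p <- function(f) file.path(out, f)
  utils::write.csv(tables, p("roi_tables.csv"), row.names = FALSE)
  utils::write.csv(clinical, p("clinical.csv"), row.names = FALSE)
  utils::write.csv(pi_long(vecs), p("pi.csv"), row.names = FALSE)
  clus_df <- do.call(rbind, lapply(names(clusters), function(key) {
    sol <- clusters[[key]]$solution
    v <- vecs[[key]]
    data.frame(patient = attr(v, "patient"), state = attr(v, "state"),
               structure = names(sol$assignment),
               cluster = as.integer(sol$assignment),
               centroid = sol$centroids[sol$assignment],
               is_hypo = sol$assignment == sol$hypo_cluster & sol$k >= 2,
               is_hyper = sol$assignment == sol$hyper_cluster & sol$k >= 2,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(clus_df, p("clusters.csv"), row.names = FALSE)
  traces <- lapply(clusters, function(z) {
    tr <- z$trace
    list(k_candidates = tr$k_candidates, distortion = tr$distortion,
         chosen_k = tr$chosen_k)
  })
  jsonlite::write_json(traces, p("k_trace.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(match_table, p("match_table.csv"), row.names = FALSE)
  utils::write.csv(summary_tab, p("cluster_summary.csv"), row.names = FALSE)
  jsonlite::write_json(descriptives, p("descriptives.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(screen, p("screen.csv"), row.names = FALSE)
  utils::write.csv(clinical[c("patient", "score", "stratum")],
                   p("sudep7.csv"), row.names = FALSE)
  jsonlite::write_json(spearman, p("spearman.json"), auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$out_dir <- NULL  # a path, not part of the scientific configuration
  cfg$cohort <- unclass(cfg$cohort)
  cfg$cohort$clinical <- NULL  # written separately as clinical.csv
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  write_report(config, p, clinical, match_table, summary_tab, descriptives,
               screen, spearman, clusters)
  invisible(vapply(c("roi_tables.csv", "clinical.csv", "pi.csv", "clusters.csv",
                     "k_trace.json", "match_table.csv", "cluster_summary.csv",
                     "descriptives.json", "screen.csv", "sudep7.csv",
                     "spearman.json", "config.yaml", "report.md"),
                   function(f) p(f), character(1)))
}

#' @noRd
write_report <- function(config, p, clinical, match_table, summary_tab,
                         descriptives, screen, spearman, clusters) {
  hash <- unname(tools::md5sum(p("config.yaml")))
  ks <- vapply(clusters, function(z) z$trace$chosen_k, integer(1))
  d <- descriptives$sudep7_score
  lines <- c(
    "# Pipeline run report", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- config hash (md5 of config.yaml): %s", hash),
    sprintf("- package version: %s",
            as.character(utils::packageVersion("sudepspect"))), "",
    "## Cohort descriptives", "",
    sprintf("- SUDEP-7 score: mean %.2f (SD %.2f), SE %.2f, median %g, range %g-%g",
            d$mean, d$sd, d$se, d$median, d$min, d$max),
    if (!is.null(descriptives$injection_time_s)) {
      di <- descriptives$injection_time_s
      sprintf("- injection time (s): mean %.1f (SD %.1f), range %g-%g",
              di$mean, di$sd, di$min, di$max)
    },
    sprintf("- high-risk patients (score > 5): %d of %d",
            sum(clinical$stratum == "high"), nrow(clinical)), "",
    "## Selected K per scan", "",
    paste(sprintf("- %s: K = %d", names(ks), ks), collapse = "\n"), "",
    "## Match table (top rows)", "",
    utils::capture.output(print(utils::head(match_table, 12))), "",
    "## Cluster summary (per-scan extreme clusters)", "",
    utils::capture.output(print(summary_tab, digits = 3)), "",
    "## Screening (top structures)", "",
    utils::capture.output(print(utils::head(as.data.frame(screen), 8), digits = 3)), "",
    "## Rank correlations", "",
    sprintf("- ictal hypo structure count vs SUDEP-7: rho = %.3f",
            spearman$ictal_hypo_n_vs_score),
    sprintf("- ictal hypo subcortical count vs SUDEP-7: rho = %.3f",
            spearman$ictal_hypo_nsubc_vs_score))
  writeLines(unlist(lines), p("report.md"))
}
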