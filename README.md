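# sudepspect

Quantitative analysis of paired interictal/ictal brain-perfusion SPECT for
SUDEP risk stratification in drug-resistant focal epilepsy.

SUDEP — sudden unexpected death in epilepsy — is the leading cause of
premature death in drug-resistant epilepsy. Paired SPECT scans measure
regional cerebral blood flow between seizures (interictal) and at seizure
onset (ictal). This package implements an end-to-end, reproducible version
of a perfusion-pattern analysis for such data, aimed at researchers working
with atlas-quantified SPECT and clinical risk inventories:

- **Quantification.** Mean activity per structure of a 74-structure
  cortical/subcortical atlas, restricted to a grey-matter mask, with
  region-based (geometric-transfer-matrix) partial-volume correction.
  Each structure is reduced to a perfusion index
  `PI_s = A_s / A_ref`, the ratio of its mean activity to the rest-of-grey-
  matter mean; `PI > 1` marks relative hyperperfusion. Structures are re-keyed
  to ipsilateral/contralateral of the seizure onset zone so patients with
  different onset sides are comparable.
- **Change.** Relative interictal-to-ictal change
  `(PI_ictal − PI_interictal) / PI_interictal`, with 0 meaning invariant
  perfusion.
- **Pattern extraction.** Univariate k-means over each scan's 74 values,
  the number of clusters selected by v-fold cross-validation; the clusters
  with the lowest and highest centroid are the scan's hypo- and
  hyperperfused regions of interest. An exact dynamic-programming 1-D
  k-means solver ships alongside Lloyd's algorithm as an independent oracle
  and optional engine.
- **Cohort patterns.** Cross-patient match frequencies ("medulla in the
  hypoperfused set in 8/9 patients"), per-scan cluster summaries
  (mean ± SD, N/N-subcortical), and descriptive statistics.
- **Risk linkage.** SUDEP-7 inventory scoring (0–10, high risk above 5),
  binned-predictor F-statistic screening of change patterns against the
  SUDEP-7 score, and Spearman correlations of hypoperfused-structure counts
  with the score.
- **Synthetic cohorts.** A generator that plants known perfusion levels,
  change maps, a perfusion-invariance biomarker in high-risk patients, and
  blurred/noisy block phantoms — so every stage is testable without patient
  data.

## Worked example

Generate the noise-free reference cohort, quantify one scan, and extract its
perfusion pattern:

```r
library(sudepspect)

atlas  <- load_atlas_spec()                       # 74-structure catalogue
cfg    <- cohort_config("reference", seed = 42,
                        noise_sd = 0, level_sds = rep(0, 5))
cohort <- generate_roi_cohort(cfg, atlas)

scan <- subset(cohort$tables, patient == "P3" & state == "interictal")
scan <- relabel_ipsilateral(scan, "right", atlas) # onset side of P3
pi   <- perfusion_index(scan)

trace <- select_k_vfold(pi, seed = 7)
trace
#> <k_selection_trace> chosen K = 5 (10 folds, threshold 5%)
#>    K   distortion improvement
#> 1  2 1.445618e-02          NA
#> 2  3 5.086552e-03   0.6481401
#> 3  4 1.197263e-03   0.7646219
#> 4  5 5.086656e-32   1.0000000
#> 5  6 5.086656e-32   0.0000000
#> ...
```

The held-out distortion collapses to zero at K = 5: the scan contains
exactly five perfusion levels. Fit and label the extremes:

```r
sol <- kmeans_1d(pi, trace$chosen_k, seed = 7)
sol
#> <cluster_solution> k=5 (lloyd), inertia=8.62817e-30
#> centroids: 0.5266, 0.8483, 1, 1.081, 1.316
#> sizes:     6, 9, 27, 25, 7

ext <- label_extremes(sol, atlas)
ext$hypo
#> [1] "entorhinal_area_ipsi"    "red_nucleus_ipsi"
#> [3] "red_nucleus_contra"      "substantia_nigra_ipsi"
#> [5] "substantia_nigra_contra" "medulla"
ext$counts
#>    role n n_subcortical
#> 1  hypo 6             5
#> 2 hyper 7             3
```

The hypoperfused cluster (centroid PI 0.53) contains the brainstem and
mesial structures planted by the generator — medulla, red nucleus,
substantia nigra bilaterally and the ipsilateral entorhinal area — five of
its six members subcortical. The hyperperfused cluster (centroid 1.32)
holds the bilateral rectus gyrus, putamen, cingulate and ipsilateral globus
pallidus. Clinical descriptives come from the same cohort:

```r
d <- describe_values(score_sudep7(cohort$clinical)$score)
sprintf("SUDEP-7: median %g, SE %.2f", d$median, d$se)
#> [1] "SUDEP-7: median 7, SE 0.55"
```

`run_all(run_config(seed = 42, out_dir = "out"))` executes the whole
pipeline — quantification, change vectors, per-scan clustering, match
tables, summaries, SUDEP-7 scoring, screening — and writes each stage as
CSV/JSON plus a human-readable `report.md`. A thin command-line wrapper
lives at `inst/scripts/perfuse-sudep.R`
(`simulate`, `run` and `quantify` subcommands).

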