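# independent oracle: exhaustive enumeration of contiguous partitions of the
# sorted values (in 1-D the optimal k-means partition is contiguous)
brute_force_inertia <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (cc in cuts) {
    b <- c(cc, n); st <- c(1, head(b, -1) + 1)
    sse <- sum(mapply(function(i, j) {
      seg <- xs[i:j]; sum((seg - mean(seg))^2)
    }, st, b))
    if (sse < best) best <- sse
  }
  best
}

test_that("k = 1 has the closed-form solution", {
  x <- c(a = 1, b = 2, c = 6)
  sol <- kmeans_1d(x, 1, seed = 1)
  expect_equal(sol$centroids, 3)
  expect_equal(sol$inertia, sum((x - 3)^2))
  expect_identical(unname(sol$assignment), rep(1L, 3))
})

test_that("well-separated triplets are recovered exactly", {
  x <- c(s1 = 0.5, s2 = 0.52, s3 = 1.0, s4 = 1.02, s5 = 1.5, s6 = 1.52)
  for (sol in list(kmeans_1d(x, 3, seed = 4), kmeans_1d_dp(x, 3))) {
    expect_equal(sol$centroids, c(0.51, 1.01, 1.51))
    expect_identical(unname(sol$assignment), c(1L, 1L, 2L, 2L, 3L, 3L))
    expect_equal(sol$inertia, 6 * 0.01^2)
  }
})

test_that("DP solver matches exhaustive partition enumeration", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    k <- sample(2:min(4, n - 1), 1)
    expect_equal(kmeans_1d_dp(x, k)$inertia, brute_force_inertia(x, k),
                 tolerance = 1e-10)
  }
})

test_that("Lloyd with refinement attains the DP optimum on random instances", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    x <- switch(sample(3, 1), runif(n), rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4)))
    k <- sample(2:min(5, length(unique(x)) - 1), 1)
    dp <- kmeans_1d_dp(x, k)
    ll <- kmeans_1d(x, k, seed = i)
    expect_gte(ll$inertia, dp$inertia - 1e-9)       # never below the optimum
    expect_equal(ll$inertia, dp$inertia, tolerance = 1e-9)
  }
})

test_that("solutions are consistent objects and independent cross-checks agree", {
  set.seed(3)
  x <- setNames(rnorm(40), paste0("s", 1:40))
  sol <- kmeans_1d(x, 4, seed = 5)
  # inertia is recomputable from assignment and centroids
  expect_equal(sol$inertia, sum((x - sol$centroids[sol$assignment])^2))
  expect_identical(sol$hypo_cluster, 1L)
  expect_identical(sol$hyper_cluster, 4L)
  expect_true(all(tabulate(sol$assignment, 4) > 0))
  expect_identical(sol$centroids, sort(sol$centroids))
  # stats::kmeans as an independent implementation never beats it
  km <- stats::kmeans(x, centers = 4, nstart = 25)
  expect_lte(sol$inertia, km$tot.withinss + 1e-9)
  expect_error(kmeans_1d(c(1, 1, 2), 3), "distinct values")
})

test_that("cluster labels are invariant to structure order", {
  set.seed(8)
  x <- setNames(c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 7)), paste0("s", 1:60))
  sol1 <- kmeans_1d(x, 3, seed = 2)
  perm <- sample(60)
  sol2 <- kmeans_1d(x[perm], 3, seed = 99)
  expect_equal(sol1$centroids, sol2$centroids)
  expect_identical(sol1$assignment[names(x)], sol2$assignment[names(x)])
})

test_that("v-fold selection recovers planted K on separated levels", {
  # five noise-free levels, 74 values as in a scan
  x5 <- setNames(rep(c(0.53, 0.85, 1.00, 1.08, 1.31), c(6, 9, 27, 25, 7)),
                 paste0("s", 1:74))
  tr <- select_k_vfold(x5, seed = 11)
  expect_identical(tr$chosen_k, 5L)
  # two well-separated levels, candidates 2..8: distortion hits zero at K = 2
  x2 <- setNames(rep(c(0, 5), each = 30), paste0("s", 1:60))
  tr2 <- select_k_vfold(x2, k_candidates = 2:8, seed = 13)
  expect_identical(tr2$chosen_k, 2L)
  # one level only: the distortion curve is flat, smallest candidate wins
  x1 <- setNames(rep(1, 60), paste0("s", 1:60))
  tr1 <- select_k_vfold(x1, k_candidates = 2:8, seed = 15)
  expect_identical(tr1$chosen_k, 2L)
  # a continuous cloud keeps improving by > threshold at small K (the rule is
  # scale-free), but diminishing returns stop the scan well before k_max
  set.seed(14)
  xc <- setNames(rnorm(60, 1, 0.03), paste0("s", 1:60))
  trc <- select_k_vfold(xc, k_candidates = 2:8, seed = 15)
  expect_lte(trc$chosen_k, 5L)
  expect_true(all(tr$distortion >= 0))
  expect_true(tr$chosen_k %in% tr$k_candidates)
})

test_that("K recovery holds across planted K values", {
  centers_pool <- c(0.4, 0.8, 1.2, 1.6, 2.0, 2.4)
  for (K in 2:6) {
    sizes <- rep_len(c(15, 12, 10, 14, 11, 12)[1:K], K)
    x <- setNames(rep(centers_pool[1:K], sizes),
                  paste0("s", seq_len(sum(sizes))))
    tr <- select_k_vfold(x, k_candidates = 2:8, seed = 20 + K)
    expect_identical(tr$chosen_k, as.integer(K))
  }
})

test_that("extreme clusters are the lowest and highest centroids with class counts", {
  atlas <- test_atlas()
  vals <- c(medulla = 0.5, red_nucleus_L = 0.52, red_nucleus_R = 0.51,
            rectus_gyrus_L = 0.53,
            thalamus_L = 1.0, thalamus_R = 1.02,
            putamen_L = 1.3, putamen_R = 1.31)
  sol <- kmeans_1d(vals, 3, seed = 1)
  ext <- label_extremes(sol, atlas)
  expect_setequal(ext$hypo, c("medulla", "red_nucleus_L", "red_nucleus_R",
                              "rectus_gyrus_L"))
  expect_setequal(ext$hyper, c("putamen_L", "putamen_R"))
  # rectus gyrus is cortical, the rest of the hypo set subcortical
  expect_identical(ext$counts$n[ext$counts$role == "hypo"], 4L)
  expect_identical(ext$counts$n_subcortical[ext$counts$role == "hypo"], 3L)
  expect_identical(ext$counts$n_subcortical[ext$counts$role == "hyper"], 2L)
  sol1 <- kmeans_1d(vals, 1, seed = 1)
  expect_error(label_extremes(sol1, atlas), "no extreme")
})
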