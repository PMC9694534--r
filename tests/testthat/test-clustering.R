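make_blobs <- function(centers, n_per = 30, sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ],
                                                   each = n_per), sd = sd),
           nrow = n_per)
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("feature scaling standardises and drops constants", {
  p <- data.frame(fl1 = c(2, 4, 6), fl2 = c(0, 1, 5), fl3 = 1,
                  fl4 = c(10, 20, 40), fl5 = c(1, 2, 3),
                  size = c(1, 100, 200), af = c(5, 6, 7))
  expect_warning(x <- scale_features(p), "fl3")
  expect_false("fl3" %in% colnames(x))
  expect_equal(unname(colMeans(x)), rep(0, 6))
  expect_equal(unname(apply(x, 2, sd)), rep(1, 6))
  expect_error(scale_features(p[1, , drop = FALSE]), "insufficient")
})

test_that("k-means recovers separated point masses and is seed-deterministic", {
  x <- rbind(matrix(0, 20, 3), matrix(10, 20, 3))
  x <- x + matrix(rnorm(120, sd = 1e-6), 40, 3)
  m <- fit_kmeans(x, 2, seed = 4, restarts = 3)
  expect_equal(length(unique(m$cluster[1:20])), 1)
  expect_equal(length(unique(m$cluster[21:40])), 1)
  expect_false(m$cluster[1] == m$cluster[21])
  m2 <- fit_kmeans(x, 2, seed = 4, restarts = 3)
  expect_identical(m$cluster, m2$cluster)
  # the kept model attains the minimum objective across restarts
  expect_equal(m$tot_withinss, min(m$objectives))
  expect_error(fit_kmeans(x, 100, seed = 1), "exceeds")
})

test_that("CH index matches the brute-force dispersion ratio", {
  blobs <- make_blobs(matrix(c(0, 0, 5, 0, 0, 5), ncol = 2, byrow = TRUE),
                      n_per = 15, sd = 0.5, seed = 2)
  m <- fit_kmeans(blobs$x, 3, seed = 3, restarts = 5)
  expect_equal(m$ch, oracle_ch(blobs$x, m$cluster), tolerance = 1e-10)
  # all centroids at the grand mean: zero between-dispersion
  x0 <- matrix(rnorm(40), 20, 2)
  x_sym <- rbind(x0, -x0)  # cluster means at 0 = grand mean
  expect_equal(ch_index(x_sym, rep(1:2, each = 20)),
               oracle_ch(x_sym, rep(1:2, each = 20)))
  expect_equal(ch_index(rbind(x0, -x0), c(rep(1, 20), rep(2, 20))) *
                 0, 0)  # finite
})

test_that("CH selects the generative number of well-separated clusters", {
  blobs <- make_blobs(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), ncol = 3,
                             byrow = TRUE), n_per = 40, sd = 1, seed = 6)
  pick <- select_k(blobs$x, k_range = 2:6, seed = 10, restarts = 5)
  expect_equal(pick$best_k, 3)
  expect_true(all(is.finite(pick$ch)))
  # boundary: k = n - 1 on a tiny distinct-point set computes without error
  xs <- matrix(seq_len(12), ncol = 2)
  expect_silent(fit_kmeans(xs, 5, seed = 1, restarts = 2))
  expect_error(select_k(blobs$x, integer(0), seed = 1), "empty")
})

test_that("intra-category clustering separates generator classes", {
  sc <- default_scenario(seed = 99, days = 6)
  thr <- compute_thresholds(sc$forced_trigger, 3)
  cls <- classify_particles(sc$particles, thr)
  cls$truth_label <- sc$labels  # side information rides along in the test
  ic <- intra_category_cluster(cls, "total_pollen", k_range = 2:5,
                               seed = 21, restarts = 5)
  expect_equal(sum(ic$model$sizes), nrow(ic$particles))
  # majority label purity above chance: clusters should split tree from
  # grass/herb truth
  purity <- mean(vapply(split(ic$particles$truth_label, ic$particles$cluster),
                        function(l) max(table(l)) / length(l), numeric(1)))
  expect_gt(purity, 0.5)
  nothing <- filter_spec("nothing", perring = "AC", size_lo = 39.9)
  expect_error(intra_category_cluster(cls, nothing, seed = 1), "nothing")
})

test_that("cluster-taxon mapping finds the spore-tracking cluster", {
  sc <- default_scenario(seed = 55, days = 12)
  thr <- compute_thresholds(sc$forced_trigger, 3)
  cls <- classify_particles(sc$particles, thr)
  ic <- intra_category_cluster(cls, "fungal_AplusAB", k_range = 2:4,
                               seed = 22, restarts = 4)
  hirst <- rbind(sc$hirst,
                 data.frame(date = unique(sc$hirst$date),
                            taxon = "flatline", concentration = 7))
  mp <- map_clusters_to_taxa(ic$particles, hirst,
                             taxa = c("fungal", "flatline"),
                             flow = sc$flow, span = sc$span)
  expect_true("flatline" %in% mp$excluded)
  best <- mp$best_union$fungal
  expect_true(length(best$clusters) <= 2)
  r_single <- max(mp$r_table$r[mp$r_table$taxon == "fungal"]^2, na.rm = TRUE)
  expect_gte(best$r2, r_single - 1e-12)  # union never worse than best single
})
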