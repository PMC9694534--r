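#' Z-score scale the clustering features
#'
#' Standardises the seven clustering features (five fluorescence
#' intensities, optical size, asymmetry factor) to mean 0 and sd 1.
#' Constant features carry no clustering information and are dropped with
#' a warning.
#'
#' @param particles Particle data frame.
#' @param features Feature columns, default `fl1..fl5, size, af`.
#' @return Numeric matrix with attributes `center`, `scale`, `dropped`.
#' @export
scale_features <- function(particles,
                           features = c(wibs_channels(), "size", "af")) {
  if (nrow(particles) < 2) stop("insufficient data: need >= 2 particles")
  x <- as.matrix(particles[, features, drop = FALSE])
  sds <- apply(x, 2, sd)
  dropped <- features[sds == 0]
  if (length(dropped) > 0) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no non-constant features left")
  sc <- scale(x)
  out <- sc[, , drop = FALSE]
  attr(out, "center") <- attr(sc, "scaled:center")
  attr(out, "scale") <- attr(sc, "scaled:scale")
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between- to within-cluster dispersion, normalised by degrees
#' of freedom: `(B / (k - 1)) / (W / (n - k))` where B and W are the
#' between- and within-cluster sums of squared distances. Higher is
#' better; it is 0 when all centroids coincide with the grand mean.
#'
#' @param x Numeric matrix (observations x features).
#' @param cluster Integer cluster assignments (length nrow(x)).
#' @return The index (scalar).
#' @export
ch_index <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- sort(unique(cluster))
  k <- length(ids)
  if (k < 2) stop("Calinski-Harabasz index needs k >= 2")
  if (n <= k) stop("Calinski-Harabasz index needs n > k")
  grand <- colMeans(x)
  w <- 0
  b <- 0
  for (id in ids) {
    xi <- x[cluster == id, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, ci)^2)
    b <- b + nrow(xi) * sum((ci - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Fit k-means with restarts
#'
#' Runs `stats::kmeans` `restarts` times from random initialisations and
#' keeps the run with the smallest within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param x Scaled feature matrix (see [scale_features()]).
#' @param k Number of clusters, 2 <= k <= n.
#' @param seed Random seed (mandatory, for reproducibility).
#' @param restarts Number of random restarts, default 10.
#' @return Object of class `wibs_kmeans`: list with `k`, `cluster`,
#'   `centers` (in scaled space), `sizes`, `tot_withinss`, `betweenss`,
#'   `ch`, `objectives` (per restart), `seed`, and the scaling parameters
#'   of `x`.
#' @export
fit_kmeans <- function(x, k, seed, restarts = 10) {
  if (missing(seed)) stop("`seed` is required for reproducible clustering")
  n <- nrow(x)
  if (k > n) stop(sprintf("k = %d exceeds n = %d", k, n))
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  best <- NULL
  objectives <- numeric(restarts)
  for (i in seq_len(restarts)) {
    fit <- suppressWarnings(kmeans(x, centers = k, iter.max = 100,
                                   nstart = 1))
    objectives[i] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(k = k, cluster = best$cluster, centers = best$centers,
                 sizes = as.integer(best$size),
                 tot_withinss = best$tot.withinss,
                 betweenss = best$betweenss,
                 ch = if (k < n) ch_index(x, best$cluster) else NA_real_,
                 objectives = objectives, seed = seed,
                 scaling = list(center = attr(x, "center"),
                                scale = attr(x, "scale"),
                                dropped = attr(x, "dropped"))),
            class = "wibs_kmeans")
}

#' Select the number of clusters by the Calinski-Harabasz index
#'
#' Fits k-means over a range of k and returns the k that maximises the
#' index, together with the index per k and the winning model. Each k is
#' fitted under a seed derived deterministically from `seed`.
#'
#' @param x Scaled feature matrix.
#' @param k_range Candidate cluster counts, default 2:12.
#' @param seed Random seed.
#' @param restarts Restarts per k.
#' @return List with `best_k`, `ch` (named vector per k), `model`
#'   (the `wibs_kmeans` at `best_k`).
#' @export
select_k <- function(x, k_range = 2:12, seed, restarts = 10) {
  if (length(k_range) == 0) stop("empty k range")
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("k range must intersect [2, n-1]")
  models <- lapply(k_range, function(k) {
    fit_kmeans(x, k, seed = seed + k, restarts = restarts)
  })
  ch <- vapply(models, function(m) m$ch, numeric(1))
  names(ch) <- as.character(k_range)
  best <- which.max(ch)
  list(best_k = k_range[best], ch = ch, model = models[[best]])
}

#' Cluster within a pre-selected particle category
#'
#' Applies a proxy filter first (e.g. A+AB fungal-like particles, or the
#' high-FL2/FL3 pollen-like selection), then the scale - select-k - fit
#' pipeline on the subset. Clustering inside an already-meaningful
#' category refines it into sub-populations that can track individual
#' taxa better than the whole category does.
#'
#' @param classified Output of [classify_particles()].
#' @param preselection A `wibs_filter` or built-in proxy name.
#' @param k_range Candidate cluster counts.
#' @param seed Random seed.
#' @param restarts Restarts per k.
#' @return List with `particles` (the selected subset, plus a `cluster`
#'   column), `best_k`, `ch`, `model`.
#' @export
intra_category_cluster <- function(classified, preselection,
                                   k_range = 2:12, seed, restarts = 10) {
  sel <- apply_filter(classified, preselection)
  name <- attr(sel, "filter")
  if (nrow(sel) == 0) {
    stop(sprintf("empty subset: preselection '%s' matches no particles", name))
  }
  x <- scale_features(sel)
  pick <- select_k(x, k_range = k_range, seed = seed, restarts = restarts)
  sel$cluster <- pick$model$cluster
  list(particles = sel, best_k = pick$best_k, ch = pick$ch,
       model = pick$model)
}

#' Correlate per-cluster daily concentrations with Hirst taxa
#'
#' Builds a daily concentration series per cluster, computes the Pearson
#' correlation of each (cluster, taxon) pair, and greedily selects for
#' each taxon the union of clusters (size-capped) whose summed series
#' maximises linear R-squared. Taxa with zero variance over the paired
#' days have undefined correlation and are flagged and excluded.
#'
#' @param particles Clustered subset (with `timestamp` and `cluster`
#'   columns, e.g. from [intra_category_cluster()]).
#' @param hirst Taxon daily data frame.
#' @param taxa Taxa to map; default all in `hirst`.
#' @param flow WIBS flow, L/min.
#' @param span Optional campaign span for binning.
#' @param cap Maximum clusters per taxon union, default 2.
#' @return List with `r_table` (data frame `cluster, taxon, r, n`),
#'   `best_union` (per taxon: clusters, r2), `excluded` (taxa with
#'   undefined correlation).
#' @export
map_clusters_to_taxa <- function(particles, hirst, taxa = NULL,
                                 flow = 0.23, span = NULL, cap = 2) {
  if (is.null(taxa)) taxa <- unique(hirst$taxon)
  if (is.null(span)) span <- range(particles$timestamp)  # shared bins
  clusters <- sort(unique(particles$cluster))
  daily <- lapply(clusters, function(cl) {
    aggregate_concentration(particles[particles$cluster == cl, , drop = FALSE],
                            bin = "day", flow = flow, span = span,
                            selection = sprintf("cluster_%d", cl))
  })
  names(daily) <- as.character(clusters)
  excluded <- character()
  r_rows <- list()
  best_union <- list()
  for (tx in taxa) {
    h <- hirst[hirst$taxon == tx, , drop = FALSE]
    if (nrow(h) == 0) next
    pair_one <- function(series) {
      w <- data.frame(date = as.Date(series$bin_start),
                      wibs = series$concentration_m3)[!series$missing, ,
                                                      drop = FALSE]
      merge(w, data.frame(date = h$date, hirst = h$concentration),
            by = "date")
    }
    p0 <- pair_one(daily[[1]])
    if (nrow(p0) < 3 || sd(p0$hirst) == 0) {
      excluded <- c(excluded, tx)
      next
    }
    rs <- vapply(daily, function(series) {
      p <- pair_one(series)
      if (sd(p$wibs) == 0) NA_real_ else cor(p$wibs, p$hirst)
    }, numeric(1))
    r_rows[[tx]] <- data.frame(cluster = clusters, taxon = tx,
                               r = unname(rs), n = nrow(p0))
    # greedy union on summed daily series, capped
    union_r2 <- function(members) {
      conc <- Reduce(`+`, lapply(members, function(cl) {
        daily[[as.character(cl)]]$concentration_m3
      }))
      series <- daily[[1]]
      series$concentration_m3 <- conc
      p <- pair_one(series)
      if (sd(p$wibs) == 0) -Inf else cor(p$wibs, p$hirst)^2
    }
    current <- clusters[which.max(ifelse(is.na(rs), -Inf, rs^2))]
    current_r2 <- union_r2(current)
    while (length(current) < cap) {
      candidates <- setdiff(clusters, current)
      if (length(candidates) == 0) break
      gains <- vapply(candidates, function(cl) union_r2(c(current, cl)),
                      numeric(1))
      if (max(gains) > current_r2) {
        current <- c(current, candidates[which.max(gains)])
        current_r2 <- max(gains)
      } else break
    }
    best_union[[tx]] <- list(clusters = current, r2 = current_r2)
  }
  list(r_table = do.call(rbind, c(r_rows, list(make.row.names = FALSE))),
       best_union = best_union, excluded = excluded)
}
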