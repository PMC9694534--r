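# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (row loops, explicit lookup tables) so they can check
# the vectorised implementations without sharing code with them.

# Explicit 8-row Perring lookup keyed by the FL1-FL3 exceedance pattern,
# and 4-row chlorophyll lookup keyed by FL4-FL5. Written out in full,
# independent of the package's label construction.
oracle_perring <- function(e1, e2, e3) {
  key <- paste0(as.integer(e1), as.integer(e2), as.integer(e3))
  c("000" = "NonFluorescent", "100" = "A", "010" = "B", "001" = "C",
    "110" = "AB", "101" = "AC", "011" = "BC", "111" = "ABC")[[key]]
}

oracle_chloro <- function(e4, e5) {
  key <- paste0(as.integer(e4), as.integer(e5))
  c("00" = "None", "10" = "D", "01" = "E", "11" = "DE")[[key]]
}

# Row-by-row proxy filter check (conjunctive criteria, explicit bounds).
oracle_filter_keep <- function(row, spec) {
  ok <- TRUE
  if (!is.null(spec$perring)) {
    ok <- ok && as.character(row$perring_class) %in% spec$perring
  }
  if (!is.null(spec$chloro)) {
    ok <- ok && as.character(row$chloro_class) %in% spec$chloro
  }
  ok <- ok && if (spec$lo_strict) row$size > spec$size_lo else
    row$size >= spec$size_lo
  ok <- ok && if (spec$hi_strict) row$size < spec$size_hi else
    row$size <= spec$size_hi
  if (!is.null(spec$min_intensity)) {
    for (ch in names(spec$min_intensity)) {
      ok <- ok && row[[ch]] > spec$min_intensity[[ch]]
    }
  }
  ok
}

oracle_filter_count <- function(classified, spec) {
  sum(vapply(seq_len(nrow(classified)), function(i) {
    oracle_filter_keep(classified[i, , drop = FALSE], spec)
  }, logical(1)))
}

# Closed-form Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Calinski-Harabasz by explicit double loop over points.
oracle_ch <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- sort(unique(cluster))
  k <- length(ids)
  grand <- colMeans(x)
  w <- 0
  b <- 0
  for (id in ids) {
    rows <- which(cluster == id)
    centroid <- colMeans(x[rows, , drop = FALSE])
    for (i in rows) w <- w + sum((x[i, ] - centroid)^2)
    b <- b + length(rows) * sum((centroid - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# Euler-region counts by enumerating days x subsets.
oracle_euler <- function(days, groups) {
  combos <- list()
  for (m in seq_len(2^length(groups) - 1)) {
    members <- groups[bitwAnd(m, 2^(seq_along(groups) - 1)) > 0]
    count <- 0
    for (i in seq_len(nrow(days))) {
      high_set <- groups[vapply(groups, function(g) days[[g]][i], logical(1))]
      if (setequal(high_set, members)) count <- count + 1
    }
    combos[[paste(members, collapse = "+")]] <- count
  }
  combos
}

# --- fixture builders ---------------------------------------------------

# Particle table with given intensity rows (list of length-5 vectors) and
# default size/af/timestamps.
make_particles <- function(intensities, size = 5, af = 10,
                           start = as.POSIXct("2017-05-01 00:00:00",
                                              tz = "UTC")) {
  n <- length(intensities)
  m <- do.call(rbind, intensities)
  df <- data.frame(timestamp = start + seq_len(n) * 60,
                   size = rep_len(size, n), af = rep_len(af, n))
  for (i in 1:5) df[[paste0("fl", i)]] <- m[, i]
  df
}

# Threshold set with fixed per-channel thresholds (sd 0 around them is not
# used; mean/sd chosen so mean + k*sd equals the requested threshold).
make_thresholds <- function(thresholds = rep(100, 5), k = 3) {
  structure(list(
    channels = data.frame(channel = c("fl1", "fl2", "fl3", "fl4", "fl5"),
                          mean = thresholds, sd = 0,
                          threshold = thresholds),
    k = k, session = "fixture", n = 2L
  ), class = "wibs_thresholds")
}

# All 32 exceedance patterns as intensity rows against a threshold of 100:
# 150 = exceed, 50 = not.
make_truthtable_particles <- function() {
  rows <- lapply(0:31, function(m) {
    bits <- bitwAnd(m, 2^(0:4)) > 0
    ifelse(bits, 150, 50)
  })
  make_particles(rows)
}
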