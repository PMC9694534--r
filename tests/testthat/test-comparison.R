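daily_series <- function(values, start = as.Date("2017-05-01"),
                         selection = "wibs") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  out <- data.frame(bin_start = t0 + (seq_along(values) - 1) * 86400,
                    count = values, volume_m3 = 1,
                    concentration_m3 = values,
                    missing = is.na(values))
  attr(out, "flow") <- 0.23
  attr(out, "bin") <- "day"
  attr(out, "selection") <- selection
  class(out) <- c("wibs_concentration", "data.frame")
  out
}

hirst_series <- function(values, taxon, start = as.Date("2017-05-01")) {
  data.frame(date = start + seq_along(values) - 1, taxon = taxon,
             concentration = values)
}

test_that("pairing is an inner join on date with missing days excluded", {
  w <- daily_series(c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10))
  h <- hirst_series(seq(10, 100, by = 10), "fungal")
  p <- pair_series(w, h, "fungal")
  expect_equal(nrow(p), 9)  # one WIBS day missing
  h2 <- h[-c(4, 5), ]  # drop two days the WIBS side does have
  expect_equal(nrow(pair_series(w, h2, "fungal")), 7)  # 9 overlap - 2
  h_disjoint <- hirst_series(1:5, "fungal", start = as.Date("2018-01-01"))
  expect_error(pair_series(w, h_disjoint, "fungal"), "overlap")
})

test_that("perfect linear relations give |r| = 1 and R2 = 1", {
  w <- daily_series(1:10)
  up <- hirst_series(1:10, "x")
  res <- correlate_series(pair_series(w, up, "x"))
  expect_equal(res$r, 1)
  expect_equal(res$r2_linear, 1)
  down <- hirst_series(-2 * (1:10) + 5, "x")
  res2 <- correlate_series(pair_series(w, down, "x"))
  expect_equal(res2$r, -1)
  expect_equal(res2$r2_linear, 1)
})

test_that("r matches the closed-form Pearson arithmetic", {
  pairs <- data.frame(wibs = c(1, 2, 3), hirst = c(2, 3, 5))
  res <- correlate_series(pairs)
  expect_equal(res$r, oracle_pearson(c(1, 2, 3), c(2, 3, 5)))
  expect_equal(res$r, 3 / sqrt(2 * 14 / 3))  # hand arithmetic
  expect_equal(res$r2_linear, res$r^2, tolerance = 1e-10)
})

test_that("degenerate pairings are rejected", {
  expect_error(correlate_series(data.frame(wibs = c(1, 2),
                                           hirst = c(1, 2))),
               "insufficient")
  expect_error(correlate_series(data.frame(wibs = c(1, 1, 1),
                                           hirst = c(1, 2, 3))),
               "zero variance")
})

test_that("polynomial R2 is at least linear R2, and outlier dropping works", {
  set.seed(9)
  x <- runif(30, 0, 100)
  y <- 2 * x + rnorm(30, sd = 10)
  res <- correlate_series(data.frame(wibs = x, hirst = y))
  expect_gte(res$r2_poly, res$r2_linear - 1e-12)
  y2 <- y
  y2[1] <- y2[1] + 500  # gross outlier
  res_keep <- correlate_series(data.frame(wibs = x, hirst = y2))
  res_drop <- correlate_series(data.frame(wibs = x, hirst = y2),
                               drop_outliers = 1)
  expect_equal(res_drop$n, 29)
  expect_gt(res_drop$r2_linear, res_keep$r2_linear)
})

test_that("high days use strict exceedance and Euler regions enumerate days", {
  dates <- as.Date("2017-05-01") + 0:2
  mk <- function(taxon, v) data.frame(date = dates, taxon = taxon,
                                      concentration = v)
  # day1 all high, day2 none, day3 tree only; fungal day1 at the boundary
  hirst <- rbind(mk("grass", c(51, 50, 10)),
                 mk("herb", c(81, 10, 10)),
                 mk("tree", c(81, 10, 81)),
                 mk("fungal", c(2501, 2500, 100)))
  tab <- high_day_table(hirst)
  expect_equal(unname(tab$totals), c(1, 1, 2, 1))
  expect_equal(tab$combos$count[tab$combos$combo == "grass+herb+tree+fungal"], 1)
  expect_equal(tab$combos$count[tab$combos$combo == "tree"], 1)
  expect_equal(sum(tab$combos$count), 2)  # day2 is in no region
  # brute-force enumeration agrees on every region
  oracle <- oracle_euler(tab$days, c("grass", "herb", "tree", "fungal"))
  for (combo in names(oracle)) {
    expect_equal(tab$combos$count[tab$combos$combo == combo],
                 oracle[[combo]], info = combo)
  }
  # region counts sum to per-category totals
  for (g in names(tab$totals)) {
    in_g <- vapply(strsplit(tab$combos$combo, "\\+"),
                   function(m) g %in% m, logical(1))
    expect_equal(sum(tab$combos$count[in_g]), unname(tab$totals[g]))
  }
  expect_error(high_day_table(hirst[hirst$taxon != "herb", ]), "herb")
})
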