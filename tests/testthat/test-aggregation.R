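test_that("count-to-concentration conversion uses flow x duration", {
  t0 <- as.POSIXct("2017-05-01 10:00:00", tz = "UTC")
  p <- data.frame(timestamp = t0 + sort(runif(138, 0, 3599)),
                  size = 5, af = 10, fl1 = 0, fl2 = 0, fl3 = 0,
                  fl4 = 0, fl5 = 0)
  conc <- aggregate_concentration(p, bin = "hour", flow = 0.23,
                                  span = c(t0, t0 + 3600))
  # 138 particles / (0.23 L/min * 60 min) = 10 per L = 10,000 per m3
  expect_equal(conc$concentration_m3[1], 10000)
  expect_equal(conc$volume_m3[1], 0.0138)
})

test_that("zero counts are zero but unpowered bins are missing", {
  t0 <- as.POSIXct("2017-05-01 00:00:00", tz = "UTC")
  p <- data.frame(timestamp = t0 + 100, size = 5, af = 10,
                  fl1 = 0, fl2 = 0, fl3 = 0, fl4 = 0, fl5 = 0)
  uptime <- data.frame(start = t0, end = t0 + 2 * 3600)  # power until 02:00
  conc <- aggregate_concentration(p, bin = "hour", flow = 0.23,
                                  span = c(t0, t0 + 4 * 3600),
                                  uptime = uptime)
  expect_equal(conc$concentration_m3[2], 0)     # covered, empty: zero
  expect_true(conc$missing[3])                   # power loss: missing
  expect_true(is.na(conc$concentration_m3[3]))
  expect_error(aggregate_concentration(p, "day", flow = 0), "flow")
})

test_that("counts are conserved and concentrations are additive", {
  camp <- generate_campaign(default_class_specs(), days = 3, seed = 12)
  p <- camp$particles
  conc <- aggregate_concentration(p, "day", flow = 0.23, span = camp$span)
  expect_equal(sum(conc$count), nrow(p))
  # disjoint selections sum bin-wise to their union
  small <- p[p$size < 10, , drop = FALSE]
  large <- p[p$size >= 10, , drop = FALSE]
  c_small <- aggregate_concentration(small, "day", 0.23, span = camp$span)
  c_large <- aggregate_concentration(large, "day", 0.23, span = camp$span)
  expect_equal(c_small$concentration_m3 + c_large$concentration_m3,
               conc$concentration_m3)
  # halving flow doubles concentration
  c_half <- aggregate_concentration(p, "day", 0.115, span = camp$span)
  expect_equal(c_half$concentration_m3, 2 * conc$concentration_m3)
  # hourly series re-binned to days equals the daily series
  c_hour <- aggregate_concentration(p, "hour", 0.23, span = camp$span)
  daily_from_hourly <- tapply(c_hour$count,
                              as.Date(c_hour$bin_start), sum)
  expect_equal(as.vector(daily_from_hourly[as.character(as.Date(conc$bin_start))]),
               conc$count)
})

test_that("diurnal profile averages by hour then max-normalises", {
  t0 <- as.POSIXct("2017-05-01 00:00:00", tz = "UTC")
  # day 1 hour 6: 10 particles; day 2 hour 6: 20; elsewhere 0
  ts <- c(t0 + 6 * 3600 + seq_len(10) * 60,
          t0 + 86400 + 6 * 3600 + seq_len(20) * 60)
  p <- data.frame(timestamp = ts, size = 5, af = 10, fl1 = 0, fl2 = 0,
                  fl3 = 0, fl4 = 0, fl5 = 0)
  conc <- aggregate_concentration(p, "hour", 0.23,
                                  span = c(t0, t0 + 2 * 86400))
  prof <- diurnal_profile(conc)
  expect_equal(unname(prof[["6"]]), 1)
  expect_equal(unname(prof[setdiff(names(prof), "6")]),
               rep(0, 23), ignore_attr = TRUE)
  # constant series gives a flat profile of ones
  p2 <- data.frame(timestamp = t0 + seq(0, 2 * 86400 - 1800, by = 1800),
                   size = 5, af = 10, fl1 = 0, fl2 = 0, fl3 = 0,
                   fl4 = 0, fl5 = 0)
  conc2 <- aggregate_concentration(p2, "hour", 0.23,
                                   span = c(t0, t0 + 2 * 86400))
  expect_equal(unname(diurnal_profile(conc2)), rep(1, 24),
               ignore_attr = TRUE)
  expect_error(diurnal_profile(conc[1:5, ]), "full day")
})

test_that("size/AF summaries report per-class medians", {
  thr <- make_thresholds(rep(100, 5))
  abc <- c(150, 150, 150, 50, 50)
  p <- make_particles(list(abc, abc, abc, c(0, 0, 0, 0, 0)),
                      size = c(10, 15, 20, 3), af = c(20, 25, 30, 5))
  cls <- classify_particles(p, thr)
  s <- size_af_summary(cls)
  row <- s$summary[s$summary$class == "ABC", ]
  expect_equal(row$median_size, 15)
  expect_equal(row$median_af, 25)
  one <- s$summary[s$summary$class == "NonFluorescent", ]
  expect_equal(one$median_size, 3)
  expect_warning(size_af_summary(cls, classes = c("ABC", "AC")), "AC")
})
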