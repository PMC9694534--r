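test_that("forced-trigger generation is reproducible and well-calibrated", {
  ft1 <- generate_forced_trigger(100, seed = 3)
  ft2 <- generate_forced_trigger(100, seed = 3)
  expect_identical(ft1, ft2)
  # sd = 0 collapses to the mean, so thresholds equal the mean for any k
  ft0 <- generate_forced_trigger(50, noise_mean = 70, noise_sd = 0, seed = 1)
  expect_true(all(ft0$fl1 == 70))
  thr <- compute_thresholds(ft0, 9)
  expect_equal(thr$channels$threshold, rep(70, 5))
  # CLT bound on the sample mean at n = 1e4
  ft <- generate_forced_trigger(1e4, noise_mean = 50, noise_sd = 5, seed = 8)
  expect_lt(abs(mean(ft$fl1) - 50), 3 * 5 / sqrt(1e4))
  expect_error(generate_forced_trigger(1, seed = 1), "n >= 2")
})

test_that("campaign counts follow the thinned Poisson model", {
  spec <- class_spec("test", fl_mean = rep(500, 5), fl_sd = rep(50, 5),
                     size_meanlog = log(5), size_sdlog = 0.1,
                     af_mean = 10, af_sd = 2, diurnal = rep(1, 24),
                     conc_mean = 5000, conc_cv = 0, capture = 1)
  camp <- generate_campaign(list(spec), days = 20, seed = 17)
  lambda <- 5000 * 0.23 * 60 * 24 / 1000  # per-day expected count
  expect_true(all(abs(camp$truth$count - lambda) < 4 * sqrt(lambda)))
  expect_equal(nrow(camp$particles), sum(camp$truth$count))
  # thinning: capture 0.5 halves the expected detected count
  spec_half <- spec
  spec_half$capture <- 0.5
  camp_half <- generate_campaign(list(spec_half), days = 20, seed = 17)
  ratio <- mean(camp_half$truth$count) / mean(camp$truth$count)
  expect_lt(abs(ratio - 0.5), 0.05)
  expect_equal(camp_half$truth$captured_conc,
               camp_half$truth$true_conc * 0.5)
})

test_that("particle table carries no truth columns; labels align separately", {
  camp <- generate_campaign(default_class_specs(), days = 2, seed = 23)
  expect_setequal(names(camp$particles),
                  c("timestamp", "size", "af", paste0("fl", 1:5)))
  expect_equal(length(camp$labels), nrow(camp$particles))
  expect_setequal(unique(camp$labels),
                  names(default_class_specs())[vapply(
                    default_class_specs(),
                    function(s) any(camp$truth$count[camp$truth$class ==
                                                       s$name] > 0),
                    logical(1))])
  expect_true(!is.unsorted(camp$particles$timestamp))
})

test_that("zero concentration yields an empty stream and zero truth", {
  spec <- class_spec("nil", fl_mean = rep(100, 5), fl_sd = rep(10, 5),
                     size_meanlog = log(5), size_sdlog = 0.1,
                     af_mean = 10, af_sd = 2, diurnal = rep(1, 24),
                     conc_mean = 0, conc_cv = 0)
  camp <- generate_campaign(list(spec), days = 3, seed = 2)
  expect_equal(nrow(camp$particles), 0)
  expect_true(all(camp$truth$count == 0))
})

test_that("Hirst observation noise has the configured CV and is seed-stable", {
  truth <- data.frame(date = as.Date("2017-01-01") + 0:9,
                      class = "c", taxon = "Ascospores", group = "fungal",
                      true_conc = 100, captured_conc = 100,
                      expected_count = 1, count = 1)
  exact <- observe_hirst(truth, hirst_observation_spec(cv = 0), seed = 1)
  asco <- exact[exact$taxon == "Ascospores", ]
  expect_equal(asco$concentration, rep(100, 10))  # CV 0: exact
  o1 <- observe_hirst(truth, hirst_observation_spec(), seed = 5)
  o2 <- observe_hirst(truth, hirst_observation_spec(), seed = 5)
  expect_identical(o1, o2)
  # group aggregation: fungal equals the per-taxon sum
  expect_equal(o1$concentration[o1$taxon == "fungal"],
               o1$concentration[o1$taxon == "Ascospores"])
})

test_that("class spec validation names the offending field", {
  expect_error(class_spec("x", fl_mean = rep(1, 4), fl_sd = rep(1, 5),
                          size_meanlog = 0, size_sdlog = 1, af_mean = 1,
                          af_sd = 1, diurnal = rep(1, 24), conc_mean = 1,
                          conc_cv = 1), "length 5")
  expect_error(class_spec("x", fl_mean = rep(1, 5), fl_sd = rep(1, 5),
                          size_meanlog = 0, size_sdlog = 1, af_mean = 1,
                          af_sd = 1, diurnal = rep(1, 24), conc_mean = 1,
                          conc_cv = 1, capture = 1.2), "capture")
})

test_that("default scenario bundle is byte-identical under one seed", {
  s1 <- default_scenario(seed = 777, days = 3)
  s2 <- default_scenario(seed = 777, days = 3)
  expect_identical(s1$particles, s2$particles)
  expect_identical(s1$hirst, s2$hirst)
  expect_identical(s1$truth, s2$truth)
})
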