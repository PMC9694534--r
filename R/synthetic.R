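#' Specification of one synthetic particle class
#'
#' Describes the class-conditional distributions a synthetic campaign
#' draws from: per-channel fluorescence (truncated normal in detector
#' units), optical size (lognormal, um), asymmetry factor (truncated
#' normal), an hourly emission profile, the day-to-day concentration
#' process (lognormal around a mean with a given CV), and a capture
#' efficiency in (0, 1] modelling instrument undersampling of large
#' grains.
#'
#' @param name Class name.
#' @param fl_mean,fl_sd Length-5 numeric: per-channel intensity mean / sd.
#' @param size_meanlog,size_sdlog Lognormal parameters of optical size (um).
#' @param af_mean,af_sd Asymmetry factor mean / sd.
#' @param diurnal Length-24 non-negative weights (will be normalised to
#'   sum to 1): relative emission per hour of day.
#' @param conc_mean Mean true daily concentration, per m3.
#' @param conc_cv Day-to-day coefficient of variation of the true
#'   concentration (lognormal, mean-preserving).
#' @param capture Capture efficiency in (0, 1].
#' @param taxon Hirst taxon label this class is counted under, or NA if
#'   the class is not counted by microscopy (interferents, dust).
#' @param group Hirst comparison group (`fungal`, `tree`, `grass`,
#'   `herb`) or NA.
#' @return Object of class `wibs_class_spec`.
#' @export
class_spec <- function(name, fl_mean, fl_sd, size_meanlog, size_sdlog,
                       af_mean, af_sd, diurnal, conc_mean, conc_cv,
                       capture = 1, taxon = NA_character_,
                       group = NA_character_) {
  if (length(fl_mean) != 5 || length(fl_sd) != 5) {
    stop(sprintf("class %s: fl_mean and fl_sd must have length 5", name))
  }
  if (any(fl_sd < 0)) stop(sprintf("class %s: negative fl_sd", name))
  if (length(diurnal) != 24 || any(diurnal < 0) || sum(diurnal) == 0) {
    stop(sprintf("class %s: diurnal must be 24 non-negative weights", name))
  }
  if (conc_mean < 0 || conc_cv < 0) {
    stop(sprintf("class %s: conc_mean and conc_cv must be >= 0", name))
  }
  if (capture <= 0 || capture > 1) {
    stop(sprintf("class %s: capture efficiency must be in (0, 1]", name))
  }
  structure(list(name = name, fl_mean = fl_mean, fl_sd = fl_sd,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 af_mean = af_mean, af_sd = af_sd,
                 diurnal = diurnal / sum(diurnal),
                 conc_mean = conc_mean, conc_cv = conc_cv,
                 capture = capture, taxon = taxon, group = group),
            class = "wibs_class_spec")
}

# Hourly weight helpers: smooth unimodal bumps over hour-of-day.
diurnal_peak <- function(peak_hour, width = 2.5, baseline = 0.15) {
  h <- 0:23
  d <- pmin(abs(h - peak_hour), 24 - abs(h - peak_hour))  # circular distance
  w <- exp(-0.5 * (d / width)^2) + baseline
  w / sum(w)
}

#' Default synthetic class specifications
#'
#' Seven classes spanning the populations a semi-urban spring campaign
#' mixes: two fungal spore types (A/AB-like, small, early-morning
#' emission peak), three pollen groups (tree: large ABC+DE-like; grass:
#' large D-like, undersampled; herb: 10-15 um D-like), a weakly
#' fluorescent anthropogenic interferent, and non-fluorescent dust.
#' Intensities are in detector units against a forced-trigger background
#' of mean 50, sd 10 per channel (3-sigma threshold 80, 9-sigma 140):
#' the interferent sits between those two thresholds in FL1/FL2 so that
#' threshold escalation removes it.
#'
#' @return Named list of `wibs_class_spec`.
#' @export
default_class_specs <- function() {
  # dominant early-morning (04:00-06:00) peak plus a weaker evening rise
  morning <- 2 * diurnal_peak(5, width = 2.5, baseline = 0) +
    diurnal_peak(18, width = 3, baseline = 0.15)
  midday <- diurnal_peak(13, width = 3, baseline = 0.2)
  flat <- rep(1, 24)
  list(
    fungal_ascospore = class_spec(
      "fungal_ascospore",
      fl_mean = c(600, 115, 30, 30, 25), fl_sd = c(120, 15, 15, 15, 12),
      size_meanlog = log(3), size_sdlog = 0.25,
      af_mean = 18, af_sd = 5, diurnal = morning,
      conc_mean = 2500, conc_cv = 0.9, capture = 1,
      taxon = "Ascospores", group = "fungal"),
    fungal_cladosporium = class_spec(
      "fungal_cladosporium",
      fl_mean = c(650, 60, 30, 30, 25), fl_sd = c(130, 15, 15, 15, 12),
      size_meanlog = log(6), size_sdlog = 0.22,
      af_mean = 23, af_sd = 6, diurnal = morning,
      conc_mean = 1200, conc_cv = 0.9, capture = 1,
      taxon = "Cladosporium", group = "fungal"),
    tree_pollen = class_spec(
      "tree_pollen",
      fl_mean = c(900, 1800, 1700, 700, 600),
      fl_sd = c(150, 200, 200, 120, 120),
      size_meanlog = log(30), size_sdlog = 0.15,
      af_mean = 25, af_sd = 5, diurnal = midday,
      conc_mean = 120, conc_cv = 1.0, capture = 0.9,
      taxon = "Quercus", group = "tree"),
    grass_pollen = class_spec(
      "grass_pollen",
      fl_mean = c(40, 1600, 1500, 500, 55),
      fl_sd = c(15, 200, 180, 100, 18),
      size_meanlog = log(32), size_sdlog = 0.15,
      af_mean = 20, af_sd = 5, diurnal = midday,
      conc_mean = 60, conc_cv = 1.1, capture = 0.35,
      taxon = "Poaceae", group = "grass"),
    herb_pollen = class_spec(
      "herb_pollen",
      fl_mean = c(45, 1500, 1450, 450, 55),
      fl_sd = c(15, 180, 170, 90, 18),
      size_meanlog = log(12.5), size_sdlog = 0.08,
      af_mean = 22, af_sd = 5, diurnal = midday,
      conc_mean = 90, conc_cv = 1.0, capture = 0.9,
      taxon = "Urticaceae", group = "herb"),
    interferent_B = class_spec(
      "interferent_B",
      fl_mean = c(105, 118, 30, 25, 25), fl_sd = c(15, 15, 15, 12, 12),
      size_meanlog = log(3.5), size_sdlog = 0.3,
      af_mean = 30, af_sd = 8, diurnal = midday,
      conc_mean = 1200, conc_cv = 0.5, capture = 1),
    dust_nonfluorescent = class_spec(
      "dust_nonfluorescent",
      fl_mean = c(40, 40, 40, 40, 40), fl_sd = c(15, 15, 15, 15, 15),
      size_meanlog = log(4), size_sdlog = 0.4,
      af_mean = 35, af_sd = 10, diurnal = flat,
      conc_mean = 2500, conc_cv = 0.4, capture = 1)
  )
}

rnorm_trunc <- function(n, mean, sd, lo = 0, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate forced-trigger (particle-free) background records
#'
#' Independent per-channel draws from a normal truncated at zero,
#' emulating detector background while the instrument fires on empty
#' space.
#'
#' @param n Number of firings, >= 2.
#' @param noise_mean,noise_sd Length-5 (or scalar) per-channel background
#'   mean and sd, detector units.
#' @param seed Random seed.
#' @return Data frame with columns `fl1..fl5`.
#' @export
generate_forced_trigger <- function(n, noise_mean = rep(50, 5),
                                    noise_sd = rep(10, 5), seed) {
  if (n < 2) stop("need n >= 2 forced-trigger records")
  noise_mean <- rep(noise_mean, length.out = 5)
  noise_sd <- rep(noise_sd, length.out = 5)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  set.seed(seed)
  out <- lapply(1:5, function(i) rnorm_trunc(n, noise_mean[i], noise_sd[i]))
  names(out) <- wibs_channels()
  as.data.frame(out)
}

#' Generate a synthetic WIBS campaign with ground truth
#'
#' For each day and class: a true airborne concentration is drawn
#' (lognormal around the class mean with its day-to-day CV), thinned by
#' the capture efficiency, converted to an expected particle count via
#' the sampled volume (`flow` L/min over 24 h), and realised as a Poisson
#' count. Particles are then drawn from the class-conditional
#' distributions, with timestamps placed by the hourly emission weights.
#'
#' The particle table carries no truth columns; the true class labels are
#' returned separately (aligned to the rows), together with a truth table
#' of every per-day intermediate quantity.
#'
#' @param specs Named list of [class_spec()] objects.
#' @param days Number of campaign days, >= 1.
#' @param start First campaign day (Date).
#' @param flow WIBS sample flow, L/min.
#' @param seed Random seed.
#' @param config A [campaign_config()] for the instrument bounds.
#' @return List with `particles` (timestamp-sorted data frame), `labels`
#'   (character vector of true classes, aligned to `particles` rows),
#'   `truth` (data frame `date, class, taxon, group, true_conc,
#'   captured_conc, expected_count, count`), `span` (POSIXct length 2),
#'   and `flow`.
#' @export
generate_campaign <- function(specs, days = 50,
                              start = as.Date("2017-04-21"), flow = 0.23,
                              seed, config = campaign_config()) {
  if (length(specs) < 1) stop("need at least one class spec")
  if (days < 1) stop("need days >= 1")
  for (s in specs) {
    if (!inherits(s, "wibs_class_spec")) stop("invalid class spec")
  }
  set.seed(seed)
  day_secs <- 86400
  vol_m3_day <- flow * 60 * 24 / 1000  # L/min -> m3/day
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  dates <- start + seq_len(days) - 1
  truth <- list()
  parts <- list()
  labels <- list()
  for (s in specs) {
    # mean-preserving lognormal day effect with the configured CV
    slog <- sqrt(log(1 + s$conc_cv^2))
    true_conc <- s$conc_mean * rlnorm(days, meanlog = -slog^2 / 2,
                                      sdlog = slog)
    captured <- true_conc * s$capture
    expected <- captured * vol_m3_day
    count <- rpois(days, expected)
    truth[[s$name]] <- data.frame(date = dates, class = s$name,
                                  taxon = s$taxon, group = s$group,
                                  true_conc = true_conc,
                                  captured_conc = captured,
                                  expected_count = expected, count = count)
    total <- sum(count)
    if (total > 0) {
      day_idx <- rep(seq_len(days), count)
      hour <- sample(0:23, total, replace = TRUE, prob = s$diurnal)
      secs <- (day_idx - 1) * day_secs + hour * 3600 +
        runif(total, 0, 3600)
      fl <- lapply(1:5, function(i) {
        rnorm_trunc(total, s$fl_mean[i], s$fl_sd[i],
                    lo = 0, hi = config$saturation_ceiling)
      })
      names(fl) <- wibs_channels()
      size <- rlnorm(total, s$size_meanlog, s$size_sdlog)
      size <- pmin(pmax(size, 0.5), config$size_max)
      af <- rnorm_trunc(total, s$af_mean, s$af_sd)
      parts[[s$name]] <- data.frame(timestamp = t0 + secs, size = size,
                                    af = af, fl)
      labels[[s$name]] <- rep(s$name, total)
    }
  }
  particles <- do.call(rbind, parts)
  labels <- do.call(c, labels)
  if (is.null(particles)) {
    particles <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                            size = numeric(), af = numeric(),
                            fl1 = numeric(), fl2 = numeric(),
                            fl3 = numeric(), fl4 = numeric(),
                            fl5 = numeric())
    labels <- character()
  }
  ord <- order(particles$timestamp)
  particles <- particles[ord, , drop = FALSE]
  labels <- labels[ord]
  rownames(particles) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(particles = particles, labels = labels, truth = truth,
       span = c(t0, t0 + days * day_secs), flow = flow)
}

#' Hirst observation model parameters
#'
#' @param cv Counting-error coefficient of variation (multiplicative,
#'   mean-preserving lognormal). Default 0.30, the upper bound of the
#'   counting error of slide-transect extrapolation.
#' @param flow Hirst sampler flow, L/min (default 10; recorded only).
#' @param wind_factor Optional named numeric vector (by date, as
#'   character) of per-day multiplicative over/under-estimation factors.
#' @return Object of class `hirst_obs_spec`.
#' @export
hirst_observation_spec <- function(cv = 0.30, flow = 10, wind_factor = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (flow <= 0) stop("flow must be > 0")
  structure(list(cv = cv, flow = flow, wind_factor = wind_factor),
            class = "hirst_obs_spec")
}

#' Observe a campaign truth table through a Hirst-style counter
#'
#' Applies mean-preserving multiplicative lognormal counting noise with
#' the configured CV to each class's true daily concentration, then
#' aggregates to taxon labels and to the comparison groups (`fungal`,
#' `tree`, `grass`, `herb`) plus `total_pollen`. Classes without a taxon
#' label (interferents, dust) are not counted by microscopy and are
#' skipped.
#'
#' @param truth Truth table from [generate_campaign()].
#' @param spec A [hirst_observation_spec()].
#' @param seed Random seed.
#' @return Taxon daily data frame (`date,taxon,concentration`) containing
#'   per-taxon rows and group rows.
#' @export
observe_hirst <- function(truth, spec = hirst_observation_spec(), seed) {
  if (nrow(truth) == 0) stop("empty truth table")
  set.seed(seed)
  obs <- truth[!is.na(truth$taxon), , drop = FALSE]
  slog <- sqrt(log(1 + spec$cv^2))
  noise <- if (spec$cv > 0) {
    rlnorm(nrow(obs), meanlog = -slog^2 / 2, sdlog = slog)
  } else rep(1, nrow(obs))
  obs$concentration <- pmax(0, obs$true_conc * noise)
  if (!is.null(spec$wind_factor)) {
    f <- spec$wind_factor[as.character(obs$date)]
    f[is.na(f)] <- 1
    obs$concentration <- obs$concentration * f
  }
  per_taxon <- aggregate(concentration ~ date + taxon, data = obs, FUN = sum)
  grouped <- obs[!is.na(obs$group), , drop = FALSE]
  per_group <- aggregate(concentration ~ date + group, data = grouped,
                         FUN = sum)
  names(per_group)[names(per_group) == "group"] <- "taxon"
  pollen <- grouped[grouped$group %in% c("tree", "grass", "herb"), ,
                    drop = FALSE]
  out <- rbind(per_taxon, per_group)
  if (nrow(pollen) > 0) {
    total_pollen <- aggregate(concentration ~ date, data = pollen, FUN = sum)
    total_pollen$taxon <- "total_pollen"
    out <- rbind(out, total_pollen[, c("date", "taxon", "concentration")])
  }
  out <- out[order(out$date, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The default ~50-day synthetic scenario
#'
#' One reproducible bundle: a 5000-firing forced-trigger session
#' (background mean 50, sd 10 per channel), a 50-day campaign over the
#' seven default classes starting 2017-04-21 at 0.23 L/min, and the
#' paired Hirst observation (CV 0.30). Sub-seeds are derived from `seed`
#' so the whole bundle is reproducible from one integer.
#'
#' @param seed Random seed (default 2017).
#' @param days Number of days (default 50).
#' @param specs Class specifications (default [default_class_specs()]).
#' @return List with `forced_trigger`, `particles`, `labels`, `truth`,
#'   `hirst`, `span`, `flow`, `config`, `seed`.
#' @export
default_scenario <- function(seed = 2017, days = 50,
                             specs = default_class_specs()) {
  config <- campaign_config()
  ft <- generate_forced_trigger(5000, seed = seed)
  camp <- generate_campaign(specs, days = days, seed = seed + 1,
                            flow = config$wibs_flow, config = config)
  hirst <- observe_hirst(camp$truth, hirst_observation_spec(),
                         seed = seed + 2)
  list(forced_trigger = ft, particles = camp$particles,
       labels = camp$labels, truth = camp$truth, hirst = hirst,
       span = camp$span, flow = camp$flow, config = config, seed = seed)
}

#' Daily true concentration series per class or group from a truth table
#'
#' Convenience accessor: sums `true_conc` by day over a class, taxon or
#' group, returning a taxon-daily data frame comparable with the
#' pipeline's outputs.
#'
#' @param truth Truth table from [generate_campaign()].
#' @param what A class name, taxon label, or group label.
#' @return Data frame `date, taxon, concentration` (taxon = `what`).
#' @export
truth_series <- function(truth, what) {
  sel <- truth$class == what |
    (!is.na(truth$taxon) & truth$taxon == what) |
    (!is.na(truth$group) & truth$group == what)
  sub <- truth[sel, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("no truth rows for '%s'", what))
  agg <- aggregate(true_conc ~ date, data = sub, FUN = sum)
  data.frame(date = agg$date, taxon = what, concentration = agg$true_conc)
}
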