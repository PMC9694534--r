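#' Time-binned number concentrations for a particle selection
#'
#' Counts particles into regular time bins and converts counts to number
#' concentrations using the sampled air volume per bin:
#' `volume_m3 = flow [L/min] * bin duration [min] / 1000`, so
#' `concentration_m3 = count / volume_m3`. Bins without instrument uptime
#' are reported as missing (`NA`), never as zero: a day is reported only
#' when at least `coverage_min` of its duration was covered.
#'
#' @param particles Particle data frame with a `timestamp` column (any
#'   selection, classified or not).
#' @param bin `"day"` (calendar days, local time - matching Hirst daily
#'   segments) or `"hour"`.
#' @param flow WIBS sample flow, L/min.
#' @param span Optional length-2 POSIXct (or coercible) giving the period
#'   to bin over; defaults to the span of the data, rounded outward to
#'   whole bins. Pass the campaign span to make series over different
#'   selections share bins.
#' @param uptime Optional data frame of intervals `start,end` (POSIXct)
#'   during which the instrument was running; NULL = always running.
#' @param coverage_min Minimum covered fraction for a bin to be reported.
#' @param selection Name recorded with the series.
#' @return Data frame of class `wibs_concentration` with columns
#'   `bin_start, count, volume_m3, concentration_m3, missing` and
#'   attributes `flow`, `bin`, `selection`.
#' @export
aggregate_concentration <- function(particles, bin = c("day", "hour"),
                                    flow = 0.23, span = NULL, uptime = NULL,
                                    coverage_min = 0.75,
                                    selection = attr(particles, "filter")) {
  bin <- match.arg(bin)
  if (!is.numeric(flow) || flow <= 0) {
    stop("configuration error: flow must be > 0 L/min")
  }
  ts <- particles$timestamp
  if (is.null(span)) {
    if (length(ts) == 0) stop("empty selection and no `span` given")
    span <- range(ts)
  }
  span <- as.POSIXct(span, tz = "UTC")
  unit <- if (bin == "day") "day" else "hour"
  bin_secs <- if (bin == "day") 86400 else 3600
  start <- trunc(span[1], units = if (bin == "day") "days" else "hours")
  edges <- seq(from = start, by = unit, length.out =
                 ceiling(as.numeric(difftime(span[2], start, units = "secs")) /
                           bin_secs) + 1)
  if (length(edges) < 2) edges <- seq(from = start, by = unit, length.out = 2)
  idx <- findInterval(as.numeric(ts), as.numeric(edges),
                      rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= length(edges) - 1]
  counts <- tabulate(idx, nbins = length(edges) - 1)
  bin_start <- edges[-length(edges)]
  volume_m3 <- flow * (bin_secs / 60) / 1000
  coverage <- rep(1, length(bin_start))
  if (!is.null(uptime)) {
    u_start <- as.numeric(as.POSIXct(uptime$start, tz = "UTC"))
    u_end <- as.numeric(as.POSIXct(uptime$end, tz = "UTC"))
    b0 <- as.numeric(bin_start)
    b1 <- b0 + bin_secs
    coverage <- vapply(seq_along(b0), function(i) {
      ov <- pmin(b1[i], u_end) - pmax(b0[i], u_start)
      sum(pmax(0, ov)) / bin_secs
    }, numeric(1))
  }
  missing <- coverage < coverage_min
  out <- data.frame(bin_start = bin_start, count = counts,
                    volume_m3 = volume_m3,
                    concentration_m3 = ifelse(missing, NA_real_,
                                              counts / volume_m3),
                    missing = missing)
  attr(out, "flow") <- flow
  attr(out, "bin") <- bin
  attr(out, "selection") <- if (is.null(selection)) "particles" else selection
  class(out) <- c("wibs_concentration", "data.frame")
  out
}

#' Normalised diurnal profile from an hourly concentration series
#'
#' Averages concentration by hour of day (local time) across all covered
#' days, then normalises: by the maximum hourly mean (default; peak = 1)
#' or by the mean of the hourly means.
#'
#' @param series Hourly `wibs_concentration` covering at least one full
#'   day (24 hourly bins).
#' @param normalise `"max"` or `"mean"`.
#' @return Numeric vector of 24 values named "0".."23", with attribute
#'   `normalise`.
#' @export
diurnal_profile <- function(series, normalise = c("max", "mean")) {
  normalise <- match.arg(normalise)
  if (attr(series, "bin") != "hour") {
    stop("diurnal profile needs an hourly concentration series")
  }
  if (nrow(series) < 24) stop("insufficient data: need >= 1 full day")
  ok <- !series$missing
  if (!any(ok)) stop("insufficient data: all bins missing")
  hour <- as.integer(format(series$bin_start, "%H"))
  hourly_mean <- vapply(0:23, function(h) {
    v <- series$concentration_m3[ok & hour == h]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  denom <- if (normalise == "max") max(hourly_mean, na.rm = TRUE) else
    mean(hourly_mean, na.rm = TRUE)
  prof <- if (denom > 0) hourly_mean / denom else hourly_mean
  names(prof) <- as.character(0:23)
  attr(prof, "normalise") <- normalise
  prof
}

#' Per-class size and asymmetry-factor distribution summaries
#'
#' Median optical size, median asymmetry factor and a binned 2-D histogram
#' per class, for plotting size-vs-AF distributions of the fluorescent
#' particle types.
#'
#' @param classified Output of [classify_particles()].
#' @param by Grouping column: `"perring_class"` or `"chloro_class"`.
#' @param classes Optional classes to include; classes with no particles
#'   are omitted with a warning. Default: all observed classes.
#' @param size_breaks,af_breaks Histogram bin edges.
#' @return List with `summary` (data frame `class, n, median_size,
#'   median_af`) and `hist` (named list of count matrices, size x AF).
#' @export
size_af_summary <- function(classified, by = c("perring_class", "chloro_class"),
                            classes = NULL,
                            size_breaks = seq(0, 40, by = 2),
                            af_breaks = seq(0, 100, by = 5)) {
  by <- match.arg(by)
  f <- as.character(classified[[by]])
  observed <- unique(f)
  if (is.null(classes)) classes <- sort(observed)
  empty <- setdiff(classes, observed)
  if (length(empty) > 0) {
    warning(sprintf("omitting empty class(es): %s",
                    paste(empty, collapse = ", ")))
    classes <- setdiff(classes, empty)
  }
  summ <- do.call(rbind, lapply(classes, function(cl) {
    s <- classified[f == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(s), median_size = median(s$size),
               median_af = median(s$af))
  }))
  hists <- lapply(classes, function(cl) {
    s <- classified[f == cl, , drop = FALSE]
    size_bin <- cut(pmin(s$size, max(size_breaks)), size_breaks,
                    include.lowest = TRUE)
    af_bin <- cut(pmin(s$af, max(af_breaks)), af_breaks,
                  include.lowest = TRUE)
    table(size = size_bin, af = af_bin)
  })
  names(hists) <- classes
  list(summary = summ, hist = hists)
}
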