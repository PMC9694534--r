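#' Pair a daily WIBS concentration series with a Hirst taxon series
#'
#' Inner join on calendar date: only days present (and non-missing) on
#' both sides are kept, and the number of paired days is recorded.
#'
#' @param wibs Daily `wibs_concentration` series.
#' @param hirst Taxon daily data frame (`date,taxon,concentration`).
#' @param taxon Taxon/group label to take from `hirst`.
#' @return Data frame `date, wibs, hirst` with attribute `pair`.
#' @export
pair_series <- function(wibs, hirst, taxon) {
  if (attr(wibs, "bin") != "day") stop("WIBS series must be daily")
  h <- hirst[hirst$taxon == taxon, , drop = FALSE]
  if (nrow(h) == 0) stop(sprintf("no Hirst records for taxon '%s'", taxon))
  w <- data.frame(date = as.Date(wibs$bin_start),
                  wibs = wibs$concentration_m3)[!wibs$missing, , drop = FALSE]
  m <- merge(w, data.frame(date = h$date, hirst = h$concentration),
             by = "date")
  if (nrow(m) == 0) stop("no overlapping dates between WIBS and Hirst series")
  m <- m[order(m$date), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "pair") <- sprintf("%s vs %s",
                             attr(wibs, "selection") %||% "wibs", taxon)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation and regression between paired daily series
#'
#' Pearson correlation, linear regression R-squared (which equals r^2),
#' and polynomial regression R-squared of Hirst on WIBS values. Computed
#' on raw (untransformed) daily concentrations. Optionally drops the
#' largest-residual points of the linear fit before computing results
#' (for inspecting outlier influence); default off.
#'
#' @param pairs Output of [pair_series()] (or any data frame with `wibs`
#'   and `hirst` columns), n >= 3.
#' @param poly_degree Polynomial degree, default 2.
#' @param drop_outliers Number of largest-|residual| points to drop, default 0.
#' @return Object of class `wibs_comparison`: list with `pair`, `n`, `r`,
#'   `r2_linear`, `r2_poly`, `poly_degree`, `coef_linear`, `coef_poly`,
#'   `dropped`.
#' @export
correlate_series <- function(pairs, poly_degree = 2, drop_outliers = 0) {
  x <- pairs$wibs
  y <- pairs$hirst
  if (drop_outliers > 0) {
    if (drop_outliers >= length(x) - 2) stop("too many outliers to drop")
    res <- abs(resid(lm(y ~ x)))
    keep <- rank(-res, ties.method = "first") > drop_outliers
    x <- x[keep]
    y <- y[keep]
  }
  n <- length(x)
  if (n < 3) stop("insufficient data: need >= 3 paired days")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance in one of the series")
  }
  r <- cor(x, y)
  fit_lin <- lm(y ~ x)
  fit_poly <- lm(y ~ poly(x, degree = poly_degree, raw = TRUE))
  r2 <- function(fit) {
    tss <- sum((y - mean(y))^2)
    1 - sum(resid(fit)^2) / tss
  }
  structure(list(pair = attr(pairs, "pair") %||% "wibs vs hirst",
                 n = n, r = r,
                 r2_linear = r2(fit_lin), r2_poly = r2(fit_poly),
                 poly_degree = poly_degree,
                 coef_linear = coef(fit_lin), coef_poly = coef(fit_poly),
                 dropped = drop_outliers),
            class = "wibs_comparison")
}

#' @export
print.wibs_comparison <- function(x, ...) {
  cat(sprintf("%s: n = %d, r = %.3f, R2(linear) = %.3f, R2(poly %d) = %.3f\n",
              x$pair, x$n, x$r, x$r2_linear, x$poly_degree, x$r2_poly))
  invisible(x)
}

#' Threshold-escalation response of a proxy's Hirst agreement
#'
#' Recomputes thresholds at k = 3, 6, 9 from the same forced-trigger data,
#' re-classifies the particles, re-applies the named proxy (with its sigma
#' requirement set to each k), aggregates to daily concentrations and
#' correlates with the Hirst target series. Raising k suppresses weakly
#' fluorescent interferents, so agreement with the biological reference
#' typically improves or holds.
#'
#' @param particles Particle data frame.
#' @param forced_trigger Forced-trigger data frame.
#' @param hirst Taxon daily data frame.
#' @param taxon Hirst taxon/group to compare against.
#' @param proxy_name Name of a built-in proxy (its class/size/intensity
#'   rules are kept; only the sigma requirement tracks k).
#' @param flow WIBS flow, L/min.
#' @param span Optional campaign span passed to [aggregate_concentration()].
#' @return Named list (`"3"`, `"6"`, `"9"`) of `wibs_comparison` objects.
#' @export
sigma_escalation <- function(particles, forced_trigger, hirst, taxon,
                             proxy_name, flow = 0.23, span = NULL) {
  proxies <- builtin_proxies()
  if (!proxy_name %in% names(proxies)) {
    stop(sprintf("unknown proxy filter: %s", proxy_name))
  }
  base_spec <- proxies[[proxy_name]]
  out <- lapply(c(3, 6, 9), function(k) {
    thr <- compute_thresholds(forced_trigger, k = k)
    cls <- classify_particles(particles, thr)
    spec <- base_spec
    spec$sigma <- k
    sel <- apply_filter(cls, spec)
    conc <- aggregate_concentration(sel, bin = "day", flow = flow,
                                    span = span, selection =
                                      sprintf("%s@%dsigma", proxy_name, k))
    correlate_series(pair_series(conc, hirst, taxon))
  })
  names(out) <- c("3", "6", "9")
  out
}

#' High-day concentration thresholds
#'
#' Daily concentrations strictly exceeding these values flag a "high" day:
#' grass 50 grains/m3, herb 80 grains/m3, tree 80 grains/m3, fungal
#' 2500 spores/m3.
#'
#' @return Named list of thresholds.
#' @export
high_day_thresholds <- function() {
  list(grass = 50, herb = 80, tree = 80, fungal = 2500)
}

#' High-day flags and Euler co-occurrence counts
#'
#' Flags each day "high" per group when its concentration strictly exceeds
#' the group threshold, then counts days in every exact combination of
#' high groups (the regions of a four-set Euler diagram). Summing the
#' regions that contain a group recovers that group's high-day total.
#'
#' @param hirst Taxon daily data frame containing the four group series
#'   `grass`, `herb`, `tree`, `fungal`.
#' @param thresholds Named thresholds, see [high_day_thresholds()].
#' @return List with `days` (data frame `date` + one logical column per
#'   group), `combos` (data frame `combo, count` over all 15 non-empty
#'   combinations), and `totals` (named high-day totals per group).
#' @export
high_day_table <- function(hirst, thresholds = high_day_thresholds()) {
  groups <- names(thresholds)
  missing_groups <- setdiff(groups, unique(hirst$taxon))
  if (length(missing_groups) > 0) {
    stop(sprintf("missing group series: %s",
                 paste(missing_groups, collapse = ", ")))
  }
  sub <- hirst[hirst$taxon %in% groups, , drop = FALSE]
  wide <- stats::reshape(sub, idvar = "date", timevar = "taxon",
                         direction = "wide")
  names(wide) <- sub("^concentration\\.", "", names(wide))
  wide <- wide[complete.cases(wide[, groups]), , drop = FALSE]
  days <- data.frame(date = wide$date)
  for (g in groups) days[[g]] <- wide[[g]] > thresholds[[g]]
  combos <- do.call(rbind, lapply(seq_len(2^length(groups) - 1), function(m) {
    members <- groups[bitwAnd(m, 2^(seq_along(groups) - 1)) > 0]
    in_combo <- rep(TRUE, nrow(days))
    for (g in groups) {
      in_combo <- in_combo & (days[[g]] == (g %in% members))
    }
    data.frame(combo = paste(members, collapse = "+"), count = sum(in_combo))
  }))
  totals <- vapply(groups, function(g) sum(days[[g]]), numeric(1))
  list(days = days, combos = combos, totals = totals)
}
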