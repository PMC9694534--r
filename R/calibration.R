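#' Per-channel fluorescence thresholds from forced-trigger data
#'
#' In forced-trigger mode the instrument fires on particle-free air, so the
#' recorded intensities measure detector background. The fluorescence
#' threshold of each channel is the background mean plus `k` sample
#' standard deviations; a particle is called fluorescent in a channel when
#' its intensity strictly exceeds that threshold. `k = 3` is the standard
#' baseline; raising it to 6 or 9 suppresses weakly fluorescent
#' (typically anthropogenic) interferents.
#'
#' @param forced_trigger Data frame with columns `fl1..fl5` (forced-trigger
#'   intensities); at least two records.
#' @param k Threshold multiplier, one of 3, 6, 9.
#' @param session Optional session identifier (e.g. the calibration date).
#' @return An object of class `wibs_thresholds`: list with `channels`
#'   (data frame `channel, mean, sd, threshold`), `k`, `session`, `n`.
#' @export
compute_thresholds <- function(forced_trigger, k = 3, session = NULL) {
  if (!k %in% c(3, 6, 9)) stop("`k` must be one of 3, 6, 9")
  missing_cols <- setdiff(wibs_channels(), names(forced_trigger))
  if (length(missing_cols) > 0) {
    stop(sprintf("forced-trigger data missing channel(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(forced_trigger)
  if (n < 2) stop("insufficient data: need >= 2 forced-trigger records")
  intensities <- forced_trigger[, wibs_channels(), drop = FALSE]
  if (anyNA(intensities)) {
    stop("validation error: NaN/NA intensity in forced-trigger data")
  }
  mu <- vapply(intensities, mean, numeric(1))
  sigma <- vapply(intensities, sd, numeric(1))  # sample (n-1) sd
  structure(list(
    channels = data.frame(channel = wibs_channels(), mean = unname(mu),
                          sd = unname(sigma),
                          threshold = unname(mu + k * sigma)),
    k = k, session = session, n = n
  ), class = "wibs_thresholds")
}

#' @export
print.wibs_thresholds <- function(x, ...) {
  cat(sprintf("WIBS fluorescence thresholds (mean + %d sd, n = %d%s)\n",
              x$k, x$n,
              if (is.null(x$session)) "" else paste0(", session ", x$session)))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Combine daily forced-trigger sessions into one effective threshold set
#'
#' The instrument is put into forced-trigger mode daily to confirm that the
#' background does not drift. This combines the per-session threshold sets
#' into the set applied to the analysis period, and reports the relative
#' spread of each channel's threshold across sessions (the daily-stability
#' check).
#'
#' @param sessions List of `wibs_thresholds`, all computed at the same `k`.
#' @param policy `"mean"` (default): average per-channel background mean and
#'   sd across sessions and recompute the threshold. `"latest"`: use the
#'   last session as given.
#' @return A `wibs_thresholds` with an extra `spread` element: per-channel
#'   sd of the session thresholds divided by their mean (0 when identical
#'   or for a single session).
#' @export
aggregate_daily_thresholds <- function(sessions, policy = c("mean", "latest")) {
  policy <- match.arg(policy)
  if (length(sessions) < 1) stop("insufficient data: no threshold sessions")
  if (!all(vapply(sessions, inherits, logical(1), "wibs_thresholds"))) {
    stop("`sessions` must be a list of wibs_thresholds objects")
  }
  ks <- vapply(sessions, function(s) s$k, numeric(1))
  if (length(unique(ks)) != 1) {
    stop("all sessions must use the same sigma multiplier k")
  }
  thr_mat <- vapply(sessions, function(s) s$channels$threshold,
                    numeric(length(wibs_channels())))
  thr_mat <- matrix(thr_mat, nrow = length(wibs_channels()))
  spread <- if (length(sessions) == 1) {
    rep(0, length(wibs_channels()))
  } else {
    apply(thr_mat, 1, function(v) {
      m <- mean(v)
      if (m == 0) 0 else sd(v) / m
    })
  }
  out <- if (policy == "latest") {
    sessions[[length(sessions)]]
  } else {
    mu <- rowMeans(vapply(sessions, function(s) s$channels$mean,
                          numeric(length(wibs_channels()))))
    sigma <- rowMeans(vapply(sessions, function(s) s$channels$sd,
                             numeric(length(wibs_channels()))))
    structure(list(
      channels = data.frame(channel = wibs_channels(), mean = unname(mu),
                            sd = unname(sigma),
                            threshold = unname(mu + ks[1] * sigma)),
      k = ks[1], session = sprintf("mean of %d sessions", length(sessions)),
      n = sum(vapply(sessions, function(s) s$n, numeric(1)))
    ), class = "wibs_thresholds")
  }
  out$spread <- data.frame(channel = wibs_channels(),
                           relative_spread = unname(spread))
  out
}

#' Write / read a threshold set as YAML
#'
#' @param thresholds A `wibs_thresholds` object.
#' @param path File path.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "wibs_thresholds"))
  ch <- thresholds$channels
  per_channel <- lapply(seq_len(nrow(ch)), function(i) {
    list(mean = ch$mean[i], sd = ch$sd[i], threshold = ch$threshold[i])
  })
  names(per_channel) <- ch$channel
  yaml::write_yaml(list(k = thresholds$k,
                        session = thresholds$session,
                        n = thresholds$n,
                        channels = per_channel), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  vals <- yaml::read_yaml(path)
  ch <- vals$channels
  structure(list(
    channels = data.frame(
      channel = names(ch),
      mean = vapply(ch, function(x) x$mean, numeric(1)),
      sd = vapply(ch, function(x) x$sd, numeric(1)),
      threshold = vapply(ch, function(x) x$threshold, numeric(1)),
      row.names = NULL),
    k = vals$k, session = vals$session, n = vals$n
  ), class = "wibs_thresholds")
}
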