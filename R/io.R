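#' Campaign configuration
#'
#' Bundles the instrument and sampling constants used across the pipeline.
#' The WIBS sample flow and detector dynamic range are instrument settings
#' that published deployments rarely report; both are therefore explicit
#' configuration with documented defaults, and every concentration output
#' records the flow it was computed with.
#'
#' @param wibs_flow WIBS sample flow, L/min. Default 0.23.
#' @param hirst_flow Hirst volumetric sampler flow, L/min. Default 10.
#' @param saturation_ceiling Detector intensity ceiling, arbitrary units.
#'   Values at the ceiling are kept and flagged, never dropped. Default 2047.
#' @param size_max Maximum optical-equivalent diameter, micrometres.
#'   Default 40 (the WIBS-4+ sizes up to 30-40 um).
#' @param sigma_multiplier Fluorescence threshold multiplier k in
#'   mean + k * sd; one of 3, 6, 9.
#' @param timezone Label recorded with the configuration. Timestamps are
#'   treated as local campaign time and never converted.
#' @return A list of class `wibs_config`.
#' @export
campaign_config <- function(wibs_flow = 0.23, hirst_flow = 10,
                            saturation_ceiling = 2047, size_max = 40,
                            sigma_multiplier = 3, timezone = "local") {
  if (!is.numeric(wibs_flow) || wibs_flow <= 0) {
    stop("`wibs_flow` must be > 0 (L/min)")
  }
  if (!is.numeric(hirst_flow) || hirst_flow <= 0) {
    stop("`hirst_flow` must be > 0 (L/min)")
  }
  if (!is.numeric(saturation_ceiling) || saturation_ceiling <= 0) {
    stop("`saturation_ceiling` must be > 0")
  }
  if (!is.numeric(size_max) || size_max <= 0) stop("`size_max` must be > 0")
  if (!sigma_multiplier %in% c(3, 6, 9)) {
    stop("`sigma_multiplier` must be one of 3, 6, 9")
  }
  structure(list(wibs_flow = wibs_flow, hirst_flow = hirst_flow,
                 saturation_ceiling = saturation_ceiling,
                 size_max = size_max, sigma_multiplier = sigma_multiplier,
                 timezone = timezone),
            class = "wibs_config")
}

#' Write / read a campaign configuration as YAML
#'
#' @param config A `wibs_config` object.
#' @param path File path.
#' @return `read_campaign_config` returns a `wibs_config`.
#' @export
write_campaign_config <- function(config, path) {
  stopifnot(inherits(config, "wibs_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_campaign_config
#' @export
read_campaign_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(campaign_config, vals)
}

particle_columns <- function(with_timestamp = TRUE) {
  cols <- c("size", "af", wibs_channels())
  if (with_timestamp) cols <- c("timestamp", cols)
  cols
}

validate_particles <- function(df, config, file = "<data>",
                               require_timestamp = TRUE) {
  needed <- particle_columns(require_timestamp)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s) %s", file,
                 paste(missing_cols, collapse = ", ")))
  }
  fail <- function(what, rows) {
    stop(sprintf("validation error in %s: %s at row(s) %s", file, what,
                 paste(head(rows, 5), collapse = ", ")))
  }
  num_cols <- c("size", "af", wibs_channels())
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) fail(sprintf("non-finite %s", col), bad)
  }
  bad <- which(df$size <= 0 | df$size > config$size_max)
  if (length(bad) > 0) {
    fail(sprintf("size outside (0, %g] um", config$size_max), bad)
  }
  bad <- which(df$af < 0)
  if (length(bad) > 0) fail("negative asymmetry factor", bad)
  for (ch in wibs_channels()) {
    bad <- which(df[[ch]] < 0)
    if (length(bad) > 0) fail(sprintf("negative intensity in %s", ch), bad)
    bad <- which(df[[ch]] > config$saturation_ceiling)
    if (length(bad) > 0) {
      fail(sprintf("%s above saturation ceiling %g", ch,
                   config$saturation_ceiling), bad)
    }
  }
  # saturated events are kept, flagged, and classified normally
  df$saturated <- Reduce(`|`, lapply(wibs_channels(),
                                     function(ch) df[[ch]] >= config$saturation_ceiling))
  if (require_timestamp) {
    ts <- as.POSIXct(as.character(df$timestamp), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M",
                                    "%Y-%m-%d %H:%M",
                                    "%Y-%m-%d"))
    bad <- which(is.na(ts))
    if (length(bad) > 0) {
      stop(sprintf("format error in %s: unparseable timestamp at row(s) %s",
                   file, paste(head(bad, 5), collapse = ", ")))
    }
    df$timestamp <- ts
    df <- df[order(df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a single-particle event table
#'
#' Columns `timestamp,size,af,fl1,fl2,fl3,fl4,fl5`: ISO-8601 timestamp
#' (local campaign time), optical-equivalent diameter (um), asymmetry
#' factor, and five fluorescence intensities in detector units. Records
#' are validated against the configured instrument bounds and returned
#' sorted by timestamp; no row is ever dropped silently - any invalid
#' row aborts the read with its row index.
#'
#' @param path CSV file path.
#' @param config A [campaign_config()].
#' @return A data frame of validated particle records (plus a `saturated`
#'   flag column), ordered by timestamp.
#' @export
read_particles <- function(path, config = campaign_config()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- validate_particles(df, config, file = path, require_timestamp = TRUE)
  message(sprintf("read %d particle record(s) from %s", nrow(df), path))
  df
}

#' Read a forced-trigger (particle-free) event table
#'
#' Same schema as [read_particles()] but the timestamp column is optional:
#' forced-trigger firings measure detector background, not particles.
#'
#' @inheritParams read_particles
#' @return A data frame with the five intensity columns (and timestamp,
#'   size, af if present in the file).
#' @export
read_forced_trigger <- function(path, config = campaign_config()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(wibs_channels(), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  for (ch in wibs_channels()) {
    bad <- which(!is.finite(df[[ch]]) | df[[ch]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("validation error in %s: invalid intensity in %s at row(s) %s",
                   path, ch, paste(head(bad, 5), collapse = ", ")))
    }
  }
  message(sprintf("read %d forced-trigger record(s) from %s", nrow(df), path))
  df
}

#' Write a particle event table
#'
#' @param particles Particle data frame.
#' @param path Output CSV path.
#' @export
write_particles <- function(particles, path) {
  out <- particles[, intersect(particle_columns(TRUE), names(particles)),
                   drop = FALSE]
  if ("timestamp" %in% names(out)) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a Hirst-style daily taxon concentration table
#'
#' Columns `date,taxon,concentration`: calendar day, taxon or group label
#' (e.g. Poaceae, Ascospores, or grass/herb/tree/fungal), and daily
#' concentration in grains or spores per cubic metre. At most one record
#' per (date, taxon) is allowed.
#'
#' @param path CSV file path.
#' @return Data frame with `date` (Date), `taxon` (character),
#'   `concentration` (numeric, >= 0).
#' @export
read_taxon_daily <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("date", "taxon", "concentration"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warning(sprintf("empty taxon table: %s", path))
    return(data.frame(date = as.Date(character()), taxon = character(),
                      concentration = numeric()))
  }
  dates <- as.Date(df$date)
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    stop(sprintf("format error in %s: unparseable date at row(s) %s", path,
                 paste(head(bad, 5), collapse = ", ")))
  }
  df$date <- dates
  df$concentration <- suppressWarnings(as.numeric(df$concentration))
  bad <- which(!is.finite(df$concentration) | df$concentration < 0)
  if (length(bad) > 0) {
    stop(sprintf("validation error in %s: concentration must be finite and >= 0 at row(s) %s",
                 path, paste(head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$date, df$taxon)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("validation error in %s: duplicate (date, taxon) record: %s",
                 path, dup))
  }
  df[order(df$date, df$taxon), c("date", "taxon", "concentration"),
     drop = FALSE]
}

#' @rdname read_taxon_daily
#' @param series Taxon daily series data frame.
#' @param path Output CSV path.
#' @export
write_taxon_daily <- function(series, path) {
  out <- series[, c("date", "taxon", "concentration"), drop = FALSE]
  out$date <- format(as.Date(out$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
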