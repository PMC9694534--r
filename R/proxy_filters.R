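#' Construct a particle selection rule
#'
#' A filter combines, conjunctively: a set of allowed Perring classes, a
#' set of allowed chlorophyll classes, a size window, optional per-channel
#' minimum intensities (strict `>`, in raw detector units), and the sigma
#' multiplier the classification must have been made at.
#'
#' Boundary conventions (centralised here because prose bounds like
#' "greater than 25 um" or "10-15 um" are ambiguous at the endpoint):
#' `lo_strict`/`hi_strict` say whether the size bounds are strict; the
#' built-in proxies use strict bounds for "greater/less than" phrasing and
#' closed bounds for ranges.
#'
#' @param name Filter name.
#' @param perring Allowed Perring classes (character vector) or NULL = any.
#' @param chloro Allowed chlorophyll classes or NULL = any.
#' @param size_lo,size_hi Size window in micrometres.
#' @param lo_strict,hi_strict Are the respective bounds strict inequalities?
#' @param min_intensity Named numeric vector of per-channel minimum
#'   intensities (e.g. `c(fl2 = 1300, fl3 = 1300)`), or NULL.
#' @param sigma Sigma multiplier the classification must use, or NA = any.
#' @return Object of class `wibs_filter`.
#' @export
filter_spec <- function(name, perring = NULL, chloro = NULL,
                        size_lo = 0, size_hi = Inf,
                        lo_strict = FALSE, hi_strict = FALSE,
                        min_intensity = NULL, sigma = NA) {
  if (size_lo >= size_hi) stop("size window must have lo < hi")
  if (!is.null(min_intensity)) {
    if (is.null(names(min_intensity)) ||
        !all(names(min_intensity) %in% wibs_channels())) {
      stop("`min_intensity` must be named by channel (fl1..fl5)")
    }
    if (any(min_intensity < 0)) stop("intensity minima must be >= 0")
  }
  if (!is.null(perring) && !all(perring %in% perring_levels())) {
    stop("unknown Perring class in `perring`")
  }
  if (!is.null(chloro) && !all(chloro %in% chloro_levels())) {
    stop("unknown chlorophyll class in `chloro`")
  }
  has_criterion <- !is.null(perring) || !is.null(chloro) ||
    size_lo > 0 || is.finite(size_hi) || !is.null(min_intensity)
  if (!has_criterion) stop("filter must have at least one criterion")
  structure(list(name = name, perring = perring, chloro = chloro,
                 size_lo = size_lo, size_hi = size_hi,
                 lo_strict = lo_strict, hi_strict = hi_strict,
                 min_intensity = min_intensity, sigma = sigma),
            class = "wibs_filter")
}

#' Built-in bioaerosol proxy filters
#'
#' Named particle selections used throughout the analysis. All fungal and
#' pollen proxies include the 2 um comparison floor (the Hirst method is
#' inefficient below ~2 um, so sub-2-um particles are removed before any
#' WIBS-vs-Hirst comparison):
#'
#' \describe{
#'   \item{comparison_floor}{size >= 2 um, any class, any sigma.}
#'   \item{fungal_A9}{Perring A at 9 sigma, size >= 2 um.}
#'   \item{fungal_AplusAB}{Perring A or AB at 3 sigma, size >= 2 um.}
#'   \item{ascospore}{A or AB, 2 um <= size < 5 um, 3 sigma.}
#'   \item{cladosporium}{A, 2 um <= size < 10 um, 3 sigma.}
#'   \item{total_pollen}{size > 2 um with FL2 > 1300 and FL3 > 1300
#'     (raw detector units), 3 sigma.}
#'   \item{tree_pollen}{ABC, size > 25 um, 3 sigma.}
#'   \item{herb_pollen}{chlorophyll class D, 10 um <= size <= 15 um, 3 sigma.}
#'   \item{grass_pollen}{chlorophyll class D, size > 10 um, 3 sigma.}
#' }
#'
#' The herb (10-15 um) and grass (> 10 um) windows overlap by construction:
#' a 12 um D-type particle satisfies both. Both proxies are kept as
#' defined; the overlap is a property of the rules, not an error.
#'
#' @return Named list of `wibs_filter` objects.
#' @export
builtin_proxies <- function() {
  list(
    comparison_floor = filter_spec("comparison_floor", size_lo = 2),
    fungal_A9 = filter_spec("fungal_A9", perring = "A", size_lo = 2,
                            sigma = 9),
    fungal_AplusAB = filter_spec("fungal_AplusAB", perring = c("A", "AB"),
                                 size_lo = 2, sigma = 3),
    ascospore = filter_spec("ascospore", perring = c("A", "AB"),
                            size_lo = 2, size_hi = 5, hi_strict = TRUE,
                            sigma = 3),
    cladosporium = filter_spec("cladosporium", perring = "A",
                               size_lo = 2, size_hi = 10, hi_strict = TRUE,
                               sigma = 3),
    total_pollen = filter_spec("total_pollen", size_lo = 2, lo_strict = TRUE,
                               min_intensity = c(fl2 = 1300, fl3 = 1300),
                               sigma = 3),
    tree_pollen = filter_spec("tree_pollen", perring = "ABC",
                              size_lo = 25, lo_strict = TRUE, sigma = 3),
    herb_pollen = filter_spec("herb_pollen", chloro = "D",
                              size_lo = 10, size_hi = 15, sigma = 3),
    grass_pollen = filter_spec("grass_pollen", chloro = "D",
                               size_lo = 10, lo_strict = TRUE, sigma = 3)
  )
}

#' Apply a selection rule to classified particles
#'
#' All criteria are conjunctive; applying the same filter twice returns
#' the same subset (idempotence). The classification must have been made
#' at the sigma multiplier the filter requires.
#'
#' @param classified Output of [classify_particles()].
#' @param spec A `wibs_filter` (or the name of a built-in proxy).
#' @return The selected subset, attributes preserved plus `filter` = name.
#' @export
apply_filter <- function(classified, spec) {
  if (is.character(spec)) {
    proxies <- builtin_proxies()
    if (!spec %in% names(proxies)) {
      stop(sprintf("unknown proxy filter: %s", spec))
    }
    spec <- proxies[[spec]]
  }
  stopifnot(inherits(spec, "wibs_filter"))
  cls_sigma <- attr(classified, "sigma")
  if (!is.na(spec$sigma)) {
    if (is.null(cls_sigma) || cls_sigma != spec$sigma) {
      stop(sprintf(
        "configuration error: filter '%s' requires classification at %g sigma (got %s)",
        spec$name, spec$sigma,
        if (is.null(cls_sigma)) "none" else format(cls_sigma)))
    }
  }
  keep <- rep(TRUE, nrow(classified))
  if (!is.null(spec$perring)) {
    keep <- keep & classified$perring_class %in% spec$perring
  }
  if (!is.null(spec$chloro)) {
    keep <- keep & classified$chloro_class %in% spec$chloro
  }
  keep <- keep & if (spec$lo_strict) classified$size > spec$size_lo else
    classified$size >= spec$size_lo
  keep <- keep & if (spec$hi_strict) classified$size < spec$size_hi else
    classified$size <= spec$size_hi
  if (!is.null(spec$min_intensity)) {
    for (ch in names(spec$min_intensity)) {
      keep <- keep & classified[[ch]] > spec$min_intensity[[ch]]
    }
  }
  out <- classified[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sigma") <- cls_sigma
  attr(out, "fluorescence_basis") <- attr(classified, "fluorescence_basis")
  attr(out, "filter") <- spec$name
  out
}
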