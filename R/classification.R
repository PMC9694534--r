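#' Perring and chlorophyll class labels
#'
#' Perring classes are the mutually exclusive labels determined by which of
#' FL1-FL3 a particle exceeds: one letter per exceeded channel (A = FL1,
#' B = FL2, C = FL3), `NonFluorescent` when none. The chlorophyll-band
#' labels come from FL4/FL5 the same way (D = FL4, E = FL5, `None` when
#' neither).
#'
#' @return Character vector of levels.
#' @export
perring_levels <- function() {
  c("NonFluorescent", "A", "B", "C", "AB", "AC", "BC", "ABC")
}

#' @rdname perring_levels
#' @export
chloro_levels <- function() {
  c("None", "D", "E", "DE")
}

#' Classify particles by fluorescence-threshold exceedance
#'
#' Each particle's five intensities are compared (strict `>`) to the
#' per-channel thresholds. The FL1-FL3 exceedance pattern determines the
#' Perring class and the FL4-FL5 pattern the chlorophyll class,
#' independently. A particle counts as fluorescent when it exceeds in any
#' channel of the chosen basis: all five (`"fl12345"`, default) or the
#' traditional first three (`"fl123"`).
#'
#' @param particles Particle data frame (see [read_particles()]).
#' @param thresholds A [compute_thresholds()] result covering all five
#'   channels.
#' @param fluorescence_basis `"fl12345"` or `"fl123"`.
#' @return The particle data frame with added logical columns
#'   `exceed_fl1..exceed_fl5` and `fluorescent`, factor columns
#'   `perring_class` and `chloro_class`, and attributes `sigma` (the
#'   multiplier used) and `fluorescence_basis`.
#' @export
classify_particles <- function(particles, thresholds,
                               fluorescence_basis = c("fl12345", "fl123")) {
  fluorescence_basis <- match.arg(fluorescence_basis)
  stopifnot(inherits(thresholds, "wibs_thresholds"))
  ch <- thresholds$channels
  missing_ch <- setdiff(wibs_channels(), ch$channel)
  if (length(missing_ch) > 0) {
    stop(sprintf("thresholds missing channel(s): %s",
                 paste(missing_ch, collapse = ", ")))
  }
  thr <- ch$threshold[match(wibs_channels(), ch$channel)]
  names(thr) <- wibs_channels()
  out <- particles
  for (c in wibs_channels()) {
    out[[paste0("exceed_", c)]] <- particles[[c]] > thr[[c]]
  }
  letters3 <- c(exceed_fl1 = "A", exceed_fl2 = "B", exceed_fl3 = "C")
  lab <- rep("", nrow(out))
  for (col in names(letters3)) {
    lab <- paste0(lab, ifelse(out[[col]], letters3[[col]], ""))
  }
  lab[lab == ""] <- "NonFluorescent"
  out$perring_class <- factor(lab, levels = perring_levels())
  lab45 <- paste0(ifelse(out$exceed_fl4, "D", ""),
                  ifelse(out$exceed_fl5, "E", ""))
  lab45[lab45 == ""] <- "None"
  out$chloro_class <- factor(lab45, levels = chloro_levels())
  basis_cols <- if (fluorescence_basis == "fl123") {
    paste0("exceed_", wibs_channels()[1:3])
  } else {
    paste0("exceed_", wibs_channels())
  }
  out$fluorescent <- Reduce(`|`, out[basis_cols])
  attr(out, "sigma") <- thresholds$k
  attr(out, "fluorescence_basis") <- fluorescence_basis
  out
}

#' Summarise a classified particle collection
#'
#' Per-class counts and fractions (of all particles and of the fluorescent
#' fraction) for both taxonomies, plus the overall fluorescent fraction.
#'
#' @param classified Output of [classify_particles()].
#' @return List with elements `perring` and `chloro` (data frames
#'   `class, count, frac_total, frac_fluorescent`), `fluorescent_fraction`,
#'   `n`, `sigma`, and `fluorescence_basis`.
#' @export
classification_summary <- function(classified) {
  n <- nrow(classified)
  if (n == 0) {
    warning("empty particle collection: empty summary")
    empty <- data.frame(class = character(), count = integer(),
                        frac_total = numeric(), frac_fluorescent = numeric())
    return(list(perring = empty, chloro = empty,
                fluorescent_fraction = NA_real_, n = 0L,
                sigma = attr(classified, "sigma"),
                fluorescence_basis = attr(classified, "fluorescence_basis")))
  }
  n_fluor <- sum(classified$fluorescent)
  tab <- function(f, fluorescent_only_levels = NULL) {
    counts <- table(f)
    cls <- names(counts)
    in_fluor <- tapply(classified$fluorescent, f, sum)
    data.frame(class = cls, count = as.integer(counts),
               frac_total = as.numeric(counts) / n,
               frac_fluorescent = if (n_fluor > 0) {
                 as.numeric(in_fluor) / n_fluor
               } else rep(NA_real_, length(cls)),
               row.names = NULL)
  }
  list(perring = tab(classified$perring_class),
       chloro = tab(classified$chloro_class),
       fluorescent_fraction = n_fluor / n,
       n = n,
       sigma = attr(classified, "sigma"),
       fluorescence_basis = attr(classified, "fluorescence_basis"))
}
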