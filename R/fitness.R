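#' Reproductive fitness of a well
#'
#' Reproductive fitness (RF) is the number of viable progeny per parent worm
#' in a well: `progeny_count / parent_count`. Wells whose parent count falls
#' outside the quality window (2-12 parents, endpoints included) are set to
#' not-determined (`NA`): outside that window the progeny count no longer
#' scales linearly with the number of parents, so the per-parent rate is
#' unreliable.
#'
#' @param parent_count Integer vector of adult (parent) counts, >= 0.
#' @param progeny_count Integer vector of larval (progeny) counts, >= 0.
#' @param window Length-2 numeric, the inclusive parent-count quality window.
#' @return Numeric vector of RF values; `NA` marks not-determined wells.
#' @examples
#' compute_rf(c(5, 1, 12), c(40, 30, 0))
#' @export
compute_rf <- function(parent_count, progeny_count, window = c(2, 12)) {
  if (any(parent_count < 0, na.rm = TRUE) || any(progeny_count < 0, na.rm = TRUE)) {
    stop("parent_count and progeny_count must be non-negative", call. = FALSE)
  }
  stopifnot(length(window) == 2L, window[1] <= window[2])
  in_window <- !is.na(parent_count) & !is.na(progeny_count) &
    parent_count >= window[1] & parent_count <= window[2]
  ifelse(in_window, progeny_count / parent_count, NA_real_)
}

#' Per-plate sample-median normalization
#'
#' Removes plate-to-plate effects by dividing every measurement on a physical
#' assay plate (one library plate x strain x technical replicate) by the
#' median RF across the defined sample wells of that plate. Control wells are
#' measurements too and are divided by the same sample median; they never
#' contribute to it. `NA` (not-determined) values stay `NA`.
#'
#' A plate with no defined sample well, or whose sample median is zero, cannot
#' be normalized: every value on it becomes `NA` and a warning is raised.
#' Plates with fewer than `min_samples` defined sample wells are normalized
#' but flagged with a warning, since the median becomes unstable.
#'
#' @param rf Numeric vector of raw RF values for one physical plate.
#' @param sample Logical vector, `TRUE` for wells whose content is "sample".
#' @param min_samples Minimum number of defined sample wells below which a
#'   warning is raised (default 10).
#' @return Numeric vector of normalized RF values, with the sample median used
#'   attached as attribute `"sample_median"` (`NA` if unnormalizable).
#' @examples
#' normalize_plate(c(2, 4, 6, 8, 10), rep(TRUE, 5), min_samples = 1)
#' @export
normalize_plate <- function(rf, sample, min_samples = 10) {
  stopifnot(length(rf) == length(sample), is.logical(sample))
  s <- rf[sample & !is.na(rf)]
  unnormalizable <- function(msg) {
    warning(msg, call. = FALSE)
    structure(rep(NA_real_, length(rf)), sample_median = NA_real_)
  }
  if (length(s) == 0L) {
    return(unnormalizable("no defined sample wells; plate unnormalizable, all values set to ND"))
  }
  med <- stats::median(s)
  if (med == 0) {
    return(unnormalizable("sample median is zero; plate unnormalizable, all values set to ND"))
  }
  if (length(s) < min_samples) {
    warning(sprintf("only %d defined sample wells (minimum %d); plate median may be unstable",
                    length(s), min_samples), call. = FALSE)
  }
  structure(rf / med, sample_median = med)
}

#' Average the two technical replicates of a well
#'
#' Arithmetic mean of the two normalized technical-replicate RFs. When one
#' replicate is not determined, the value of the single replicate that worked
#' is used; when both are not determined, the result is not determined.
#'
#' @param rf_r1,rf_r2 Numeric vectors of normalized RF values, one per
#'   technical replicate (`NA` = not determined).
#' @return Numeric vector of replicate-averaged RF values.
#' @examples
#' summarize_technical(c(0.8, NA, NA), c(1.2, 0.9, NA))
#' @export
summarize_technical <- function(rf_r1, rf_r2) {
  m <- rowMeans(cbind(rf_r1, rf_r2), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  unname(m)
}

#' Mutant/wild-type reproductive fitness ratio
#'
#' Ratio of the strain-averaged, normalized RFs of the two strains for the
#' same RNAi clone. The default orientation puts the mutant strain in the
#' numerator, so that RNAi clones that enhance lethality specifically in the
#' mutant give ratios below 1 (and classify as enhancers under the `<= 0.5`
#' rule), while clones that suppress lethality give ratios above 1. The
#' opposite orientation is available via `orientation`; it simply maps every
#' defined ratio r to 1/r.
#'
#' @param rf_mut,rf_wt Numeric vectors of strain-averaged normalized RF.
#' @param orientation `"mut_over_wt"` (default) or `"wt_over_mut"`.
#' @return Numeric vector of ratios; `NA` when either input is `NA` or the
#'   denominator is zero.
#' @examples
#' compute_rf_ratio(c(0.5, 1.0), c(1.0, 0.0))
#' @export
compute_rf_ratio <- function(rf_mut, rf_wt,
                             orientation = c("mut_over_wt", "wt_over_mut")) {
  orientation <- match.arg(orientation)
  num <- if (orientation == "mut_over_wt") rf_mut else rf_wt
  den <- if (orientation == "mut_over_wt") rf_wt else rf_mut
  ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
}

#' Lethality implied by normalized wild-type fitness
#'
#' On a normalized scale where 1 is the typical (plate-median) fitness,
#' lethality in the wild-type background is `1 - rf`, clamped to `[0, 1]`.
#' Clones whose knockdown kills more than 90% of wild-type progeny are later
#' excluded from ratio-based classification, because a ratio of two
#' near-zero fitness values is unreliable.
#'
#' @param rf_wt_normalized Numeric vector of normalized wild-type strain RF.
#' @return Numeric vector of lethality fractions in `[0, 1]`; `NA` propagates.
#' @examples
#' compute_lethality(c(0.05, 1.0, 1.4))
#' @export
compute_lethality <- function(rf_wt_normalized) {
  pmin(pmax(1 - rf_wt_normalized, 0), 1)
}
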