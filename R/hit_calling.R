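#' Primary-screen classification
#'
#' Classifies a clone from its RF ratio using the primary-screen thresholds:
#' enhancer when the ratio is at or below `enhancer_max` (default 0.5, i.e. at
#' least a 50% increase in lethality in the mutant), suppressor when at or
#' above `suppressor_min` (default 1.5). Both thresholds are inclusive. Clones
#' whose knockdown causes more than `exclusion_lethality` (default 0.9,
#' strict) lethality in the wild-type strain are excluded before any
#' ratio-based call, since their ratio is unreliable. A not-determined ratio
#' (with no exclusion in force) yields `"ND"`.
#'
#' @param rf_ratio Numeric vector of mutant/wild-type RF ratios (`NA` = ND).
#' @param lethality_wt Numeric vector of wild-type lethality fractions
#'   (`NA` = ND).
#' @param enhancer_max Inclusive upper ratio bound for enhancers.
#' @param suppressor_min Inclusive lower ratio bound for suppressors.
#' @param exclusion_lethality Strict lethality bound above which a clone is
#'   excluded.
#' @return Character vector with values `"enhancer"`, `"suppressor"`,
#'   `"no_effect"`, `"excluded"`, or `"ND"`.
#' @examples
#' classify_primary(c(0.5, 0.3, 1.0), c(0.2, 0.95, 0.0))
#' @export
classify_primary <- function(rf_ratio, lethality_wt,
                             enhancer_max = 0.5,
                             suppressor_min = 1.5,
                             exclusion_lethality = 0.9) {
  stopifnot(length(rf_ratio) == length(lethality_wt))
  out <- rep("ND", length(rf_ratio))
  excl <- !is.na(lethality_wt) & lethality_wt > exclusion_lethality
  out[excl] <- "excluded"
  def <- !excl & !is.na(rf_ratio)
  out[def & rf_ratio <= enhancer_max] <- "enhancer"
  out[def & rf_ratio >= suppressor_min] <- "suppressor"
  out[def & rf_ratio > enhancer_max & rf_ratio < suppressor_min] <- "no_effect"
  out
}

#' Secondary-screen classification at a percentage cut-off
#'
#' Classifies a clone at a lethality-increase cut-off expressed in percent: a
#' 45% cut-off calls an enhancer when the RF ratio is strictly below 0.55
#' (`1 - 45/100`). The suppressor side is symmetric: strictly above
#' `1 + cutoff/100`. Unlike the primary-screen rule, both inequalities are
#' strict. Not-determined ratios yield `"ND"`.
#'
#' @param rf_ratio Numeric vector of RF ratios (`NA` = ND).
#' @param cutoff_percent Single percentage in (0, 100).
#' @return Character vector with values `"enhancer"`, `"suppressor"`,
#'   `"no_effect"`, or `"ND"`.
#' @examples
#' classify_at_cutoff(c(0.54, 0.55, 1.50), 45)
#' @export
classify_at_cutoff <- function(rf_ratio, cutoff_percent) {
  stopifnot(length(cutoff_percent) == 1L, cutoff_percent > 0, cutoff_percent < 100)
  lo <- 1 - cutoff_percent / 100
  hi <- 1 + cutoff_percent / 100
  out <- rep("ND", length(rf_ratio))
  def <- !is.na(rf_ratio)
  out[def & rf_ratio < lo] <- "enhancer"
  out[def & rf_ratio > hi] <- "suppressor"
  out[def & rf_ratio >= lo & rf_ratio <= hi] <- "no_effect"
  out
}

#' Calibrate the secondary-screen cut-off from control ratios
#'
#' Evaluates a grid of candidate lethality-increase cut-offs against the RF
#' ratios of the negative controls (empty vector and hil-5, no expected
#' effect) and the positive controls (dli-1, enhanced lethality specific to
#' the mutant). At each cut-off c, the predicted false-positive rate is the
#' percentage of negative controls falling strictly below the enhancer
#' threshold `1 - c/100`, and the predicted false-negative rate is the
#' percentage of positive controls at or above it. The chosen cut-off is the
#' grid point where the two predictions are most similar (ties resolved
#' toward the smaller, more sensitive cut-off).
#'
#' @param neg_ratios Numeric vector of negative-control RF ratios.
#' @param pos_ratios Numeric vector of positive-control RF ratios.
#' @param grid Numeric vector of candidate cut-offs in percent
#'   (default `c(40, 45, 50, 55, 60, 65, 70)`).
#' @return An object of class `cutoff_calibration`: a list with `table` (a
#'   tibble with columns `cutoff`, `fp_percent`, `fn_percent`),
#'   `chosen_cutoff`, and the control counts used.
#' @examples
#' calibrate_cutoff(c(1.0, 0.9, 1.1, 0.5), c(0.3, 0.4, 0.6), grid = c(40, 45, 50))
#' @export
calibrate_cutoff <- function(neg_ratios, pos_ratios, grid = seq(40, 70, by = 5)) {
  stopifnot(length(grid) >= 1L, all(grid > 0), all(grid < 100))
  grid <- sort(unique(grid))
  n_dropped <- sum(is.na(neg_ratios)) + sum(is.na(pos_ratios))
  neg <- neg_ratios[!is.na(neg_ratios)]
  pos <- pos_ratios[!is.na(pos_ratios)]
  if (n_dropped > 0) {
    message(sprintf("calibrate_cutoff: dropped %d not-determined control ratio(s)", n_dropped))
  }
  if (length(neg) == 0L || length(pos) == 0L) {
    stop("calibration requires at least one defined ratio in each control set",
         call. = FALSE)
  }
  thr <- 1 - grid / 100
  fp <- vapply(thr, function(t) 100 * mean(neg < t), numeric(1))
  fn <- vapply(thr, function(t) 100 * mean(pos >= t), numeric(1))
  structure(
    list(
      table = tibble::tibble(cutoff = grid, fp_percent = fp, fn_percent = fn),
      chosen_cutoff = grid[which.min(abs(fp - fn))],
      n_neg = length(neg),
      n_pos = length(pos),
      n_dropped = n_dropped
    ),
    class = "cutoff_calibration"
  )
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("Cut-off calibration from %d negative and %d positive control ratios",
              x$n_neg, x$n_pos))
  if (x$n_dropped > 0) cat(sprintf(" (%d ND dropped)", x$n_dropped))
  cat("\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("Chosen cut-off: %g%% (enhancer threshold: ratio < %.2f)\n",
              x$chosen_cutoff, 1 - x$chosen_cutoff / 100))
  invisible(x)
}

# The 7 non-empty regions of a 3-set Venn diagram, in canonical order.
venn_regions3 <- function() {
  c("E1", "E2", "E3", "E1&E2", "E1&E3", "E2&E3", "E1&E2&E3")
}

# Region label for the experiments in which a clone was called enhancer;
# NA when it never was.
region_label <- function(experiments) {
  if (length(experiments) == 0L) return(NA_character_)
  paste(paste0("E", sort(experiments)), collapse = "&")
}

#' Replicate-agreement hit calling over three experiments
#'
#' Given per-clone classifications from three independent biological
#' replicates, accepts as final hits the clones classified as enhancer in at
#' least `min_agreement` (default 2) of the three experiments. Not-determined
#' entries count as non-enhancer: a final hit needs positive evidence. Clones
#' that are enhancer in at least one experiment are partitioned into the 7
#' non-empty regions of the three-set Venn diagram (`"E1"`, `"E1&E2"`, ...),
#' whose counts sum to the size of that union.
#'
#' @param classifications A data frame with columns `clone`, `experiment`
#'   (integer 1-3), and `classification`; exactly one row per clone per
#'   experiment.
#' @param min_agreement Minimum number of enhancer calls for a final hit.
#' @return A list with `agreement` (tibble: `clone`, `n_enhancer`,
#'   `venn_region`, `final_status`) and `venn` (tibble: `region`, `count`,
#'   all 7 regions always present).
#' @examples
#' cl <- tibble::tibble(
#'   clone = rep(c("a", "b"), each = 3),
#'   experiment = rep(1:3, 2),
#'   classification = c("enhancer", "enhancer", "no_effect",
#'                      "enhancer", "ND", "no_effect")
#' )
#' summarize_replicates(cl)
#' @export
summarize_replicates <- function(classifications, min_agreement = 2) {
  stopifnot(all(c("clone", "experiment", "classification") %in% names(classifications)))
  n_per <- table(classifications$clone)
  bad <- names(n_per)[n_per != 3L]
  dup <- unique(classifications[duplicated(classifications[c("clone", "experiment")]), ][["clone"]])
  bad <- union(bad, dup)
  if (length(bad) > 0) {
    stop("each clone must have exactly one classification per experiment 1-3; offending clone(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  agreement <- classifications |>
    dplyr::group_by(.data$clone) |>
    dplyr::summarise(
      n_enhancer = sum(.data$classification == "enhancer"),
      venn_region = region_label(.data$experiment[.data$classification == "enhancer"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      final_status = dplyr::if_else(.data$n_enhancer >= min_agreement,
                                    "final_hit", "not_reproducible")
    )
  venn <- tibble::tibble(region = venn_regions3()) |>
    dplyr::left_join(
      dplyr::count(dplyr::filter(agreement, !is.na(.data$venn_region)),
                   .data$venn_region, name = "count"),
      by = c(region = "venn_region")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  list(agreement = agreement, venn = venn)
}

#' Collapse final-hit clones to unique target genes
#'
#' Bacterial RNAi clones occasionally share a primary target (two library
#' wells carrying the same targeting sequence), so the final list of genes
#' can be shorter than the final list of clones. Clones are ordered by
#' (plate, well) and the first clone per gene is kept.
#'
#' @param clones A data frame with columns `plate`, `well`, and `gene_id`.
#' @return A tibble with one row per unique gene: `gene_id`, the `plate` and
#'   `well` of its first clone, and `n_clones`.
#' @export
collapse_to_genes <- function(clones) {
  stopifnot(all(c("plate", "well", "gene_id") %in% names(clones)))
  clones <- tibble::as_tibble(clones)
  unmapped <- is.na(clones$gene_id) | clones$gene_id == ""
  if (any(unmapped)) {
    w <- clones[unmapped, ]
    stop("clone(s) without a gene mapping: ",
         paste(sprintf("%s:%s", w$plate, w$well), collapse = ", "), call. = FALSE)
  }
  clones <- clones[order(clones$plate, clones$well), ]
  counts <- table(clones$gene_id)
  out <- clones[!duplicated(clones$gene_id), c("gene_id", "plate", "well")]
  out$n_clones <- as.integer(counts[out$gene_id])
  tibble::as_tibble(out)
}
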