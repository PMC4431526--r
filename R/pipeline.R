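#' Pipeline configuration
#'
#' Thresholds and options shared by [run_primary()] and [run_secondary()].
#' Defaults follow the screen's published analysis: primary enhancer bound
#' 0.5 and suppressor bound 1.5 (both inclusive), exclusion above 90%
#' wild-type lethality, candidate cut-off grid 40-70% in steps of 5, final
#' hits requiring agreement in at least 2 of 3 biological replicates, and a
#' 2-12 parent-count quality window.
#'
#' @param enhancer_max,suppressor_min,exclusion_lethality Primary-screen
#'   thresholds (see [classify_primary()]).
#' @param cutoff_grid Candidate secondary cut-offs in percent, strictly
#'   increasing.
#' @param min_agreement Replicates required to call a final hit.
#' @param min_samples Minimum defined sample wells per plate for a stable
#'   median (see [normalize_plate()]).
#' @param parent_window Inclusive parent-count quality window.
#' @param orientation RF-ratio orientation (see [compute_rf_ratio()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(enhancer_max = 0.5,
                            suppressor_min = 1.5,
                            exclusion_lethality = 0.9,
                            cutoff_grid = seq(40, 70, by = 5),
                            min_agreement = 2,
                            min_samples = 10,
                            parent_window = c(2, 12),
                            orientation = c("mut_over_wt", "wt_over_mut")) {
  orientation <- match.arg(orientation)
  stopifnot(enhancer_max > 0, suppressor_min > 0, exclusion_lethality > 0,
            all(diff(cutoff_grid) > 0), min_agreement >= 1, min_samples >= 1,
            length(parent_window) == 2, parent_window[1] <= parent_window[2])
  structure(list(
    enhancer_max = enhancer_max, suppressor_min = suppressor_min,
    exclusion_lethality = exclusion_lethality, cutoff_grid = cutoff_grid,
    min_agreement = min_agreement, min_samples = min_samples,
    parent_window = parent_window, orientation = orientation
  ), class = "pipeline_config")
}

#' Per-clone fitness summaries from raw well measurements
#'
#' The shared stage chain: per-well RF with the parent-count quality window,
#' per-physical-plate sample-median normalization (one physical plate = one
#' library plate x strain x biological x technical replicate),
#' technical-replicate averaging, strain pairing, RF ratio, and wild-type
#' lethality. Every input clone appears exactly once per biological
#' replicate in the output, possibly with ND values — nothing is dropped.
#'
#' @param wells Tibble of well measurements (see [read_screen_table()]).
#' @param config A [pipeline_config()].
#' @return A tibble of clone results: `plate`, `well`, `content`, `gene_id`,
#'   `bio_rep`, `rf_wt`, `rf_mut`, `rf_ratio`, `lethality_wt`.
#' @export
screen_fitness <- function(wells, config = pipeline_config()) {
  normalized <- wells |>
    dplyr::mutate(rf = compute_rf(.data$parent_count, .data$progeny_count,
                                  window = config$parent_window)) |>
    dplyr::group_by(.data$plate, .data$strain, .data$bio_rep, .data$tech_rep) |>
    dplyr::mutate(rf_norm = as.numeric(normalize_plate(
      .data$rf, .data$content == "sample", min_samples = config$min_samples))) |>
    dplyr::ungroup()

  by_strain <- normalized |>
    dplyr::select("plate", "well", "content", "gene_id", "strain",
                  "bio_rep", "tech_rep", "rf_norm") |>
    tidyr::pivot_wider(names_from = "tech_rep", values_from = "rf_norm",
                       names_prefix = "r")
  rep_cols <- grep("^r[0-9]+$", names(by_strain), value = TRUE)
  by_strain$rf_avg <- if (length(rep_cols) == 2L) {
    summarize_technical(by_strain[[rep_cols[1]]], by_strain[[rep_cols[2]]])
  } else if (length(rep_cols) == 1L) {
    by_strain[[rep_cols[1]]]
  } else {
    m <- rowMeans(as.matrix(by_strain[rep_cols]), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  by_strain <- dplyr::select(by_strain, "plate", "well", "content", "gene_id",
                             "strain", "bio_rep", "rf_avg")

  by_strain |>
    tidyr::pivot_wider(names_from = "strain", values_from = "rf_avg") |>
    dplyr::rename(rf_wt = "wild_type", rf_mut = "mutant") |>
    dplyr::mutate(
      rf_ratio = compute_rf_ratio(.data$rf_mut, .data$rf_wt,
                                  orientation = config$orientation),
      lethality_wt = compute_lethality(.data$rf_wt)
    ) |>
    dplyr::select("plate", "well", "content", "gene_id", "bio_rep",
                  "rf_wt", "rf_mut", "rf_ratio", "lethality_wt") |>
    dplyr::arrange(.data$plate, .data$well, .data$bio_rep)
}

#' Run the primary screen
#'
#' Full primary-screen chain on raw well measurements: fitness summaries via
#' [screen_fitness()], then the inclusive 0.5/1.5 threshold classification
#' with the >90% wild-type-lethality exclusion. The selection list contains
#' the sample clones classified enhancer or suppressor (excluded and ND
#' clones never enter it); controls are classified but not selected.
#'
#' @param wells Tibble of well measurements.
#' @param config A [pipeline_config()].
#' @param verbose Print the stage log as messages.
#' @return A list with `results` (clone results + `classification`),
#'   `selection` (subset of sample clones taken forward), and `log`
#'   (named counts per stage).
#' @export
run_primary <- function(wells, config = pipeline_config(), verbose = FALSE) {
  if (nrow(wells) == 0L) {
    warning("no well measurements supplied; returning empty results", call. = FALSE)
    empty <- tibble::tibble(
      plate = integer(0), well = character(0), content = character(0),
      gene_id = character(0), bio_rep = integer(0), rf_wt = numeric(0),
      rf_mut = numeric(0), rf_ratio = numeric(0), lethality_wt = numeric(0),
      classification = character(0)
    )
    return(list(results = empty, selection = empty,
                log = c(wells_read = 0L, nd_wells = 0L, clones = 0L)))
  }
  results <- screen_fitness(wells, config) |>
    dplyr::mutate(classification = classify_primary(
      .data$rf_ratio, .data$lethality_wt,
      enhancer_max = config$enhancer_max,
      suppressor_min = config$suppressor_min,
      exclusion_lethality = config$exclusion_lethality))
  selection <- results |>
    dplyr::filter(.data$content == "sample",
                  .data$classification %in% c("enhancer", "suppressor"))
  log <- c(
    wells_read = nrow(wells),
    nd_wells = sum(is.na(compute_rf(wells$parent_count, wells$progeny_count,
                                    window = config$parent_window))),
    clones = nrow(results),
    table(factor(results$classification, levels = CLASS_LEVELS)),
    selected = nrow(selection)
  )
  if (verbose) {
    message(paste(sprintf("%s: %d", names(log), log), collapse = "; "))
  }
  list(results = results, selection = selection, log = log)
}

#' Run the secondary screen
#'
#' Full secondary-screen chain on raw well measurements from three
#' independent biological replicates: fitness summaries, control-based
#' cut-off calibration on the pooled negative (empty vector, hil-5) and
#' positive (dli-1) control ratios, per-experiment classification at the
#' chosen cut-off, replicate-agreement hit calling (enhancer in at least
#' `min_agreement` of 3 experiments), and collapsing of final-hit clones to
#' unique target genes.
#'
#' @param wells Tibble of well measurements spanning 3 biological replicates.
#' @param config A [pipeline_config()].
#' @param verbose Print the stage log as messages.
#' @return A list with `calibration` (a [calibrate_cutoff()] object),
#'   `per_experiment` (clone results + `classification` at the chosen
#'   cut-off), `agreement` and `venn` (from [summarize_replicates()]),
#'   `final_clones`, `final_genes`, and `log`.
#' @export
run_secondary <- function(wells, config = pipeline_config(), verbose = FALSE) {
  n_bio <- length(unique(wells$bio_rep))
  if (n_bio != 3L) {
    stop(sprintf("secondary screen requires exactly 3 biological replicates, found %d", n_bio),
         call. = FALSE)
  }
  results <- screen_fitness(wells, config)

  calibration <- calibrate_cutoff(
    neg_ratios = results$rf_ratio[results$content == "neg_control"],
    pos_ratios = results$rf_ratio[results$content == "pos_control"],
    grid = config$cutoff_grid
  )

  per_experiment <- results |>
    dplyr::mutate(classification = classify_at_cutoff(
      .data$rf_ratio, calibration$chosen_cutoff))

  samples <- per_experiment |>
    dplyr::filter(.data$content == "sample") |>
    dplyr::mutate(clone = paste0(.data$plate, ":", .data$well))
  reps <- summarize_replicates(
    dplyr::select(samples, "clone", experiment = "bio_rep", "classification"),
    min_agreement = config$min_agreement
  )

  final_clones <- samples |>
    dplyr::distinct(.data$clone, .data$plate, .data$well, .data$gene_id) |>
    dplyr::inner_join(
      dplyr::filter(reps$agreement, .data$final_status == "final_hit"),
      by = "clone"
    ) |>
    dplyr::arrange(.data$plate, .data$well)
  final_genes <- collapse_to_genes(final_clones)

  log <- c(
    wells_read = nrow(wells),
    clones = length(unique(samples$clone)),
    chosen_cutoff = calibration$chosen_cutoff,
    enhancer_calls = sum(samples$classification == "enhancer"),
    final_clones = nrow(final_clones),
    final_genes = nrow(final_genes)
  )
  if (verbose) {
    message(paste(sprintf("%s: %g", names(log), log), collapse = "; "))
  }
  list(calibration = calibration, per_experiment = per_experiment,
       agreement = reps$agreement, venn = reps$venn,
       final_clones = final_clones, final_genes = final_genes, log = log)
}
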