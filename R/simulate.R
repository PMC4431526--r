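#' Configuration for a synthetic screen
#'
#' Bundles the generative model parameters for [generate_screen()]. The
#' defaults emulate the structure of a genome-wide 96-well liquid-culture
#' RNAi screen: about seven L1 larvae dispensed per well, a baseline brood of
#' 30 detected progeny per parent over the assay window, two GFP-marked
#' strains assayed side by side, two technical and three biological
#' replicates, and controls occupying column 1 of every plate (empty vector
#' and hil-5 as negatives, plk-1 as a full-lethality RNAi-efficacy control,
#' dli-1 as the mutant-specific positive control).
#'
#' @param n_plates Number of library plates.
#' @param genes_per_plate Number of sample wells per plate (max 88; columns
#'   2-12).
#' @param enhancer_fraction Fraction of genes planted as enhancers.
#' @param enhancer_effect Length-2 range; planted enhancer mutant/wild-type
#'   ratio multipliers are drawn uniformly from it (must lie in (0, 0.5]).
#' @param suppressor_fraction Fraction of genes planted as suppressors.
#' @param suppressor_effect Length-2 range (> 1) for suppressor multipliers.
#' @param lethal_fraction Fraction of genes lethal in both strains (planted to
#'   exercise the high-lethality exclusion rule); their wild-type viability is
#'   drawn uniformly from `lethal_viability`.
#' @param lethal_viability Length-2 viability range for broadly lethal genes.
#' @param baseline_brood Expected detected progeny per parent for an
#'   unaffected well.
#' @param dispersion Negative-binomial size parameter for progeny counts
#'   (smaller = more overdispersed; variance = mu + mu^2/size).
#' @param plate_effect_sd Log-scale standard deviation of the multiplicative
#'   plate effect, drawn once per physical assay plate.
#' @param parent_mean Poisson mean of dispensed L1 larvae per well.
#' @param parent_range Length-2 truncation bounds for the parent count; the
#'   default (0-15) deliberately leaves some wells outside the 2-12 quality
#'   window.
#' @param n_bio_reps,n_tech_reps Numbers of biological and technical
#'   replicates.
#' @param seed Integer RNG seed; identical seeds give identical screens.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(n_plates = 10,
                          genes_per_plate = 88,
                          enhancer_fraction = 0.05,
                          enhancer_effect = c(0.1, 0.4),
                          suppressor_fraction = 0.02,
                          suppressor_effect = c(1.6, 2.5),
                          lethal_fraction = 0.02,
                          lethal_viability = c(0.02, 0.08),
                          baseline_brood = 30,
                          dispersion = 10,
                          plate_effect_sd = 0.15,
                          parent_mean = 7,
                          parent_range = c(0, 15),
                          n_bio_reps = 3,
                          n_tech_reps = 2,
                          seed = 1L) {
  cfg <- list(
    n_plates = as.integer(n_plates), genes_per_plate = as.integer(genes_per_plate),
    enhancer_fraction = enhancer_fraction, enhancer_effect = enhancer_effect,
    suppressor_fraction = suppressor_fraction, suppressor_effect = suppressor_effect,
    lethal_fraction = lethal_fraction, lethal_viability = lethal_viability,
    baseline_brood = baseline_brood, dispersion = dispersion,
    plate_effect_sd = plate_effect_sd, parent_mean = parent_mean,
    parent_range = parent_range, n_bio_reps = as.integer(n_bio_reps),
    n_tech_reps = as.integer(n_tech_reps), seed = as.integer(seed)
  )
  err <- function(msg) stop("invalid screen configuration: ", msg, call. = FALSE)
  fr <- c(cfg$enhancer_fraction, cfg$suppressor_fraction, cfg$lethal_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) err("fractions must lie in [0,1] and sum to at most 1")
  if (cfg$n_plates < 1) err("n_plates must be >= 1")
  if (cfg$genes_per_plate < 1 || cfg$genes_per_plate > 88) err("genes_per_plate must be in 1..88")
  if (length(cfg$enhancer_effect) != 2 || any(cfg$enhancer_effect <= 0) ||
      any(cfg$enhancer_effect > 0.5) || diff(cfg$enhancer_effect) < 0) {
    err("enhancer_effect must be an increasing range within (0, 0.5]")
  }
  if (length(cfg$suppressor_effect) != 2 || any(cfg$suppressor_effect <= 1) ||
      diff(cfg$suppressor_effect) < 0) {
    err("suppressor_effect must be an increasing range above 1")
  }
  if (cfg$baseline_brood <= 0 || cfg$dispersion <= 0) err("baseline_brood and dispersion must be positive")
  if (cfg$plate_effect_sd < 0) err("plate_effect_sd must be non-negative")
  if (cfg$parent_mean <= 0) err("parent_mean must be positive")
  if (length(cfg$parent_range) != 2 || cfg$parent_range[1] < 0 ||
      diff(cfg$parent_range) < 0) {
    err("parent_range must be an increasing non-negative range")
  }
  if (cfg$n_bio_reps < 1 || cfg$n_tech_reps < 1) err("replicate counts must be >= 1")
  structure(cfg, class = "screen_config")
}

# Control roster for column 1 of every plate (wells A1-H1).
control_roster <- function() {
  tibble::tibble(
    well = sprintf("%s01", LETTERS[1:8]),
    content = c("neg_control", "neg_control", "neg_control", "neg_control",
                "lethality_control", "lethality_control",
                "pos_control", "pos_control"),
    gene_id = c("L4440", "L4440", "hil-5", "hil-5",
                "plk-1", "plk-1", "dli-1", "dli-1")
  )
}

# Poisson truncated to [lo, hi] by inverse-CDF sampling (vectorized,
# deterministic under a fixed RNG state).
rtrunc_pois <- function(n, lambda, lo, hi) {
  plo <- stats::ppois(lo - 1, lambda)
  phi <- stats::ppois(hi, lambda)
  stats::qpois(plo + stats::runif(n) * (phi - plo), lambda)
}

#' Generate a synthetic screen with known ground truth
#'
#' Simulates per-well parent and progeny counts for a complete screen. Parent
#' counts are truncated Poisson; the expected progeny of a well is
#' `parent_count * baseline_brood * wt_viability * strain_multiplier *
#' plate_effect`, and the observed count is negative-binomial around that
#' mean. Planted effects act multiplicatively on the mutant strain only
#' (matching the ratio statistic the pipeline estimates). Plate effects are
#' log-normal and drawn independently for every physical assay plate
#' (plate x strain x biological x technical replicate). Control wells follow
#' the column-1 roster: negatives have multiplier 1 in both strains, plk-1
#' has viability 0 in both, and each plate's dli-1 wells carry a
#' mutant-specific multiplier drawn from the same distribution as planted
#' enhancers.
#'
#' @param config A [screen_config()] object.
#' @return A list of class `synthetic_screen` with `wells` (tibble of
#'   per-well measurements: `plate`, `well`, `strain`, `bio_rep`, `tech_rep`,
#'   `content`, `gene_id`, `parent_count`, `progeny_count`), `truth` (tibble:
#'   `gene_id`, `label`, `wt_viability`, `mut_over_wt_ratio`), `dli1_effect`
#'   (per-plate positive-control multiplier), and `config`.
#' @examples
#' scr <- generate_screen(screen_config(n_plates = 1, n_bio_reps = 1, seed = 7))
#' head(scr$wells)
#' @export
generate_screen <- function(config) {
  if (!inherits(config, "screen_config")) {
    stop("config must be created with screen_config()", call. = FALSE)
  }
  set.seed(config$seed)

  # Ground truth: per-gene label, wild-type viability, mutant multiplier.
  n_genes <- config$n_plates * config$genes_per_plate
  sample_wells <- as.vector(outer(LETTERS[1:8], 2:12,
                                  function(r, c) sprintf("%s%02d", r, c)))
  layout <- tidyr::crossing(plate = seq_len(config$n_plates),
                            well = sample_wells[seq_len(config$genes_per_plate)])
  gene_ids <- sprintf("g%02d%s", layout$plate, layout$well)

  n_enh <- round(config$enhancer_fraction * n_genes)
  n_sup <- round(config$suppressor_fraction * n_genes)
  n_let <- round(config$lethal_fraction * n_genes)
  label <- rep("neutral", n_genes)
  idx <- sample.int(n_genes, n_enh + n_sup + n_let)
  label[idx[seq_len(n_enh)]] <- "enhancer"
  if (n_sup > 0) label[idx[n_enh + seq_len(n_sup)]] <- "suppressor"
  lethal_idx <- if (n_let > 0) idx[n_enh + n_sup + seq_len(n_let)] else integer(0)

  mult <- rep(1, n_genes)
  mult[label == "enhancer"] <- stats::runif(n_enh, config$enhancer_effect[1],
                                            config$enhancer_effect[2])
  mult[label == "suppressor"] <- stats::runif(n_sup, config$suppressor_effect[1],
                                              config$suppressor_effect[2])
  viability <- rep(1, n_genes)
  viability[lethal_idx] <- stats::runif(n_let, config$lethal_viability[1],
                                        config$lethal_viability[2])
  truth <- tibble::tibble(gene_id = gene_ids, label = label,
                          wt_viability = viability, mut_over_wt_ratio = mult)

  # Positive-control effect: one draw per plate, shared across replicates,
  # from the planted-enhancer distribution so control-based FP/FN prediction
  # transfers to the samples.
  dli1_effect <- stats::runif(config$n_plates, config$enhancer_effect[1],
                              config$enhancer_effect[2])

  plate_map <- dplyr::bind_rows(
    dplyr::mutate(layout, content = "sample",
                  gene_id = gene_ids,
                  wt_viability = truth$wt_viability,
                  strain_mult = truth$mut_over_wt_ratio),
    tidyr::crossing(plate = seq_len(config$n_plates), control_roster()) |>
      dplyr::mutate(
        wt_viability = dplyr::if_else(.data$gene_id == "plk-1", 0, 1),
        strain_mult = dplyr::if_else(.data$gene_id == "dli-1",
                                     dli1_effect[.data$plate], 1)
      )
  )

  wells <- tidyr::crossing(
    plate_map,
    strain = STRAIN_LEVELS,
    bio_rep = seq_len(config$n_bio_reps),
    tech_rep = seq_len(config$n_tech_reps)
  )

  # One multiplicative effect per physical assay plate.
  phys <- tidyr::crossing(plate = seq_len(config$n_plates),
                          strain = STRAIN_LEVELS,
                          bio_rep = seq_len(config$n_bio_reps),
                          tech_rep = seq_len(config$n_tech_reps))
  phys$plate_effect <- stats::rlnorm(nrow(phys), 0, config$plate_effect_sd)
  wells <- dplyr::left_join(wells, phys,
                            by = c("plate", "strain", "bio_rep", "tech_rep"))

  n <- nrow(wells)
  wells$parent_count <- rtrunc_pois(n, config$parent_mean,
                                    config$parent_range[1], config$parent_range[2])
  mu <- wells$parent_count * config$baseline_brood * wells$wt_viability *
    ifelse(wells$strain == "mutant", wells$strain_mult, 1) * wells$plate_effect
  wells$progeny_count <- stats::rnbinom(n, size = config$dispersion, mu = mu)

  wells <- wells |>
    dplyr::select("plate", "well", "strain", "bio_rep", "tech_rep",
                  "content", "gene_id", "parent_count", "progeny_count") |>
    dplyr::arrange(.data$plate, .data$well, .data$strain,
                   .data$bio_rep, .data$tech_rep)

  structure(list(wells = wells, truth = truth,
                 dli1_effect = dli1_effect, config = config),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(paste0("Synthetic screen: %d plate(s), %d gene(s), ",
                     "%d bio x %d tech replicates, %d wells\n"),
              x$config$n_plates, nrow(x$truth),
              x$config$n_bio_reps, x$config$n_tech_reps, nrow(x$wells)))
  cat(sprintf("Planted: %d enhancer(s), %d suppressor(s), %d broadly lethal\n",
              sum(x$truth$label == "enhancer"),
              sum(x$truth$label == "suppressor"),
              sum(x$truth$wt_viability < 1)))
  invisible(x)
}

#' Score recovered hits against the planted truth
#'
#' @param called Character vector of called hit gene ids.
#' @param truth Truth tibble from [generate_screen()] (columns `gene_id`,
#'   `label`, `mut_over_wt_ratio`).
#' @param bins Breakpoints for the effect-size breakdown of sensitivity.
#' @return A list with `sensitivity` (true positives / planted enhancers),
#'   `fdr` (false positives / called, 0 when nothing is called), counts, and
#'   `breakdown`, a tibble of per-effect-size-bin sensitivity.
#' @examples
#' tr <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                      label = c("enhancer", "enhancer", "neutral"),
#'                      mut_over_wt_ratio = c(0.2, 0.4, 1))
#' evaluate_recovery(c("a", "c"), tr)
#' @export
evaluate_recovery <- function(called, truth, bins = seq(0, 0.5, by = 0.1)) {
  missing <- setdiff(called, truth$gene_id)
  if (length(missing) > 0) {
    stop("called gene(s) absent from truth: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  enh <- truth$gene_id[truth$label == "enhancer"]
  tp <- intersect(called, enh)
  fp <- setdiff(called, enh)
  planted <- truth[truth$label == "enhancer", ]
  breakdown <- planted |>
    dplyr::mutate(bin = cut(.data$mut_over_wt_ratio, breaks = bins,
                            include.lowest = TRUE),
                  recovered = .data$gene_id %in% tp) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_planted = dplyr::n(),
                     n_recovered = sum(.data$recovered),
                     sensitivity = mean(.data$recovered), .groups = "drop")
  list(
    sensitivity = if (length(enh) > 0) length(tp) / length(enh) else NA_real_,
    fdr = if (length(called) > 0) length(fp) / length(called) else 0,
    n_called = length(called), n_planted = length(enh),
    n_tp = length(tp), n_fp = length(fp),
    breakdown = breakdown
  )
}
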