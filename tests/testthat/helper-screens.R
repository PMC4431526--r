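# Small in-code fixtures shared across test files.

# A tiny hand-laid plate: 8 control wells in column 1 plus a few sample
# wells, both strains, chosen replicate structure.
tiny_wells <- function(n_samples = 4, bio_reps = 1, tech_reps = 2,
                       parent = 5, brood = 30) {
  roster <- tibble::tibble(
    well = sprintf("%s01", LETTERS[1:8]),
    content = c(rep("neg_control", 4), rep("lethality_control", 2),
                rep("pos_control", 2)),
    gene_id = c("L4440", "L4440", "hil-5", "hil-5", "plk-1", "plk-1",
                "dli-1", "dli-1")
  )
  samples <- tibble::tibble(
    well = sprintf("%s02", LETTERS[seq_len(n_samples)]),
    content = "sample",
    gene_id = paste0("gene", seq_len(n_samples))
  )
  tidyr::crossing(
    dplyr::bind_rows(roster, samples),
    strain = c("wild_type", "mutant"),
    bio_rep = seq_len(bio_reps),
    tech_rep = seq_len(tech_reps)
  ) |>
    dplyr::mutate(
      plate = 1L,
      parent_count = parent,
      progeny_count = ifelse(.data$gene_id == "plk-1", 0L,
                             as.integer(parent * brood))
    ) |>
    dplyr::select("plate", "well", "strain", "bio_rep", "tech_rep",
                  "content", "gene_id", "parent_count", "progeny_count")
}

# Independent brute-force oracle for cut-off calibration: explicit loops,
# no shared code with calibrate_cutoff().
oracle_fp_fn <- function(neg, pos, cutoff) {
  thr <- 1 - cutoff / 100
  n_fp <- 0
  for (r in neg) if (!is.na(r) && r < thr) n_fp <- n_fp + 1
  n_fn <- 0
  for (r in pos) if (!is.na(r) && r >= thr) n_fn <- n_fn + 1
  c(fp = 100 * (n_fp / sum(!is.na(neg))), fn = 100 * (n_fn / sum(!is.na(pos))))
}
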