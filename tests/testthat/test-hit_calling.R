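test_that("primary classification uses inclusive thresholds and the lethality exclusion", {
  expect_equal(classify_primary(0.50, 0.2), "enhancer")    # boundary included
  expect_equal(classify_primary(1.50, 0.2), "suppressor")  # boundary included
  expect_equal(classify_primary(0.3, 0.95), "excluded")    # >90% wt lethality
  expect_equal(classify_primary(0.3, 0.9), "enhancer")     # exclusion is strict
  expect_equal(classify_primary(1.0, 0.0), "no_effect")
  expect_equal(classify_primary(NA, 0.2), "ND")
  expect_equal(classify_primary(NA, 0.95), "excluded")     # exclusion precedes ratio
  expect_equal(classify_primary(0.4, NA), "enhancer")      # no exclusion evidence
})

test_that("secondary classification at a cut-off uses strict, symmetric thresholds", {
  expect_equal(classify_at_cutoff(0.54, 45), "enhancer")
  expect_equal(classify_at_cutoff(0.55, 45), "no_effect")  # strictly below only
  expect_equal(classify_at_cutoff(1.45, 45), "no_effect")
  expect_equal(classify_at_cutoff(1.50, 45), "suppressor") # 1.50 > 1.45
  expect_equal(classify_at_cutoff(NA, 45), "ND")
  expect_equal(classify_at_cutoff(c(0.39, 0.40, 1.61), 60),
               c("enhancer", "no_effect", "suppressor"))
  expect_error(classify_at_cutoff(0.5, 0))
  expect_error(classify_at_cutoff(0.5, 100))
})

test_that("boundary semantics differ between the two screens exactly as specified", {
  # primary rule is inclusive at 0.5; 45% secondary rule is strict at 0.55
  expect_equal(classify_primary(0.5, 0), "enhancer")
  expect_equal(classify_at_cutoff(0.55, 45), "no_effect")
})

test_that("cut-off calibration matches hand-computed control rates", {
  cal <- calibrate_cutoff(c(1.0, 0.9, 1.1, 0.5), c(0.3, 0.4, 0.6),
                          grid = c(40, 45, 50))
  row45 <- cal$table[cal$table$cutoff == 45, ]
  expect_equal(row45$fp_percent, 25)              # only 0.5 < 0.55
  expect_equal(row45$fn_percent, 100 / 3)         # only 0.6 >= 0.55
  expect_identical(
    unname(oracle_fp_fn(c(1.0, 0.9, 1.1, 0.5), c(0.3, 0.4, 0.6), 45)),
    c(row45$fp_percent, row45$fn_percent)
  )
})

test_that("separable controls give zero error rates and the tie breaks to the smaller cut-off", {
  cal <- calibrate_cutoff(neg_ratios = c(1.0, 1.1, 1.3, 2.0),
                          pos_ratios = c(0.05, 0.1, 0.2))
  expect_true(all(cal$table$fp_percent == 0))
  expect_true(all(cal$table$fn_percent == 0))
  expect_equal(cal$chosen_cutoff, 40)
})

test_that("singleton grids and degenerate control sets behave as declared", {
  expect_equal(calibrate_cutoff(c(0.2, 1.4), c(0.9), grid = 45)$chosen_cutoff, 45)
  expect_message(cal <- calibrate_cutoff(c(1, NA), c(0.2, NA)), "dropped 2")
  expect_equal(cal$n_dropped, 2)
  expect_error(suppressMessages(calibrate_cutoff(c(NA, NA), c(0.2))),
               "at least one defined ratio")
})

test_that("calibration equals the brute-force oracle and is monotone over random control sets", {
  set.seed(11)
  grid <- seq(40, 70, by = 5)
  for (i in 1:25) {
    neg <- stats::rlnorm(sample(5:60, 1), 0, 0.4)
    pos <- stats::rlnorm(sample(5:60, 1), log(0.3), 0.5)
    cal <- calibrate_cutoff(neg, pos, grid = grid)
    for (j in seq_along(grid)) {
      o <- oracle_fp_fn(neg, pos, grid[j])
      expect_equal(cal$table$fp_percent[j], unname(o["fp"]))
      expect_equal(cal$table$fn_percent[j], unname(o["fn"]))
    }
    expect_true(all(diff(cal$table$fp_percent) <= 0))
    expect_true(all(diff(cal$table$fn_percent) >= 0))
    expect_true(cal$chosen_cutoff %in% grid)
  }
})

test_that("raising the cut-off can only shrink the enhancer set", {
  set.seed(23)
  ratios <- stats::rlnorm(300, 0, 0.6)
  grid <- seq(40, 70, by = 5)
  sets <- lapply(grid, function(g) which(classify_at_cutoff(ratios, g) == "enhancer"))
  for (j in seq_along(grid)[-1]) {
    expect_true(all(sets[[j]] %in% sets[[j - 1]]))
  }
})

test_that("replicate agreement applies the 2-of-3 rule with ND as non-evidence", {
  cl <- tibble::tibble(
    clone = rep(c("a", "b", "c", "d"), each = 3),
    experiment = rep(1:3, 4),
    classification = c("enhancer", "enhancer", "no_effect",   # a: 2 of 3
                       "enhancer", "ND", "no_effect",         # b: 1 of 3
                       "enhancer", "enhancer", "enhancer",    # c: 3 of 3
                       "no_effect", "no_effect", "suppressor")# d: 0 of 3
  )
  out <- summarize_replicates(cl)
  ag <- out$agreement[match(c("a", "b", "c", "d"), out$agreement$clone), ]
  expect_equal(ag$final_status,
               c("final_hit", "not_reproducible", "final_hit", "not_reproducible"))
  expect_equal(ag$venn_region, c("E1&E2", "E1", "E1&E2&E3", NA))
  expect_equal(sum(out$venn$count), 3)  # clones enhancer in >= 1 experiment
  expect_equal(out$venn$count[out$venn$region == "E1&E2"], 1L)
})

test_that("replicate agreement rejects malformed classification sets", {
  bad <- tibble::tibble(clone = c("a", "a"), experiment = 1:2,
                        classification = c("enhancer", "enhancer"))
  expect_error(summarize_replicates(bad), "exactly one classification")
  dup <- tibble::tibble(clone = rep("a", 3), experiment = c(1, 1, 2),
                        classification = rep("enhancer", 3))
  expect_error(summarize_replicates(dup), "exactly one classification")
})

test_that("venn region counts partition the union of per-experiment enhancer sets", {
  set.seed(5)
  for (i in 1:10) {
    n <- 40
    cl <- tibble::tibble(
      clone = rep(sprintf("c%02d", seq_len(n)), each = 3),
      experiment = rep(1:3, n),
      classification = sample(c("enhancer", "no_effect", "ND"), 3 * n,
                              replace = TRUE, prob = c(0.3, 0.6, 0.1))
    )
    out <- summarize_replicates(cl)
    in_union <- tapply(cl$classification == "enhancer", cl$clone, any)
    expect_equal(sum(out$venn$count), sum(in_union))
    # per-experiment totals recoverable from the regions
    for (e in 1:3) {
      from_regions <- sum(out$venn$count[grepl(paste0("E", e), out$venn$region)])
      direct <- sum(cl$classification == "enhancer" & cl$experiment == e)
      expect_equal(from_regions, direct)
    }
  }
})

test_that("clones sharing a primary target collapse to one gene, in (plate, well) order", {
  clones <- tibble::tibble(
    plate = c(12L, 12L, 1L),
    well = c("H02", "F04", "B08"),
    gene_id = c("ztf-19", "ztf-19", "myo-1")
  )
  out <- collapse_to_genes(clones)
  expect_equal(nrow(out), 2)
  expect_equal(out$gene_id, c("myo-1", "ztf-19"))       # stable (plate, well) order
  expect_equal(out$well[out$gene_id == "ztf-19"], "F04") # first clone of the pair
  expect_equal(out$n_clones, c(1L, 2L))
  expect_equal(nrow(collapse_to_genes(clones[0, ])), 0)
  expect_error(
    collapse_to_genes(tibble::tibble(plate = 1L, well = "A02", gene_id = NA)),
    "without a gene mapping"
  )
})

test_that("38 clones with one duplicated target collapse to 37 genes", {
  clones <- tibble::tibble(
    plate = rep(1:13, length.out = 38),
    well = sprintf("%s%02d", rep(LETTERS[1:8], length.out = 38),
                   rep(2:11, length.out = 38)),
    gene_id = c(sprintf("gene%02d", 1:37), "gene01")
  )
  expect_equal(nrow(collapse_to_genes(clones)), 37)
})
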