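test_that("well coordinates normalize to row letter + zero-padded column", {
  expect_equal(normalize_well(c("B8", "B08", "b8", " A1 ", "H12")),
               c("B08", "B08", "B08", "A01", "H12"))
  expect_equal(well_column("B08"), 8L)
  expect_equal(well_row("B08"), "B")
  expect_error(normalize_well("I01"), "invalid well")
  expect_error(normalize_well("B13"), "invalid well")
  expect_error(normalize_well("B0"), "invalid well")
})

test_that("raw count tables round-trip through the CSV schema", {
  scr <- generate_screen(screen_config(n_plates = 1, n_bio_reps = 1, seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_counts(scr$wells, path)
  back <- read_screen_table(path, schema = "raw_counts")
  expect_equal(as.data.frame(back), as.data.frame(scr$wells))
})

test_that("data-record tables round-trip, including ND tokens", {
  scr <- generate_screen(screen_config(n_plates = 1, n_bio_reps = 1,
                                       lethal_fraction = 0.05, seed = 22))
  prim <- suppressWarnings(run_primary(scr$wells))
  expect_true(any(is.na(prim$results$rf_ratio)))   # plk-1 wells at least
  path <- withr::local_tempfile(fileext = ".csv")
  write_data_record(prim$results, path)
  back <- read_screen_table(path, schema = "data_record")
  expect_equal(as.data.frame(back), as.data.frame(prim$results),
               tolerance = 1e-12)
  # ND written as a literal token, not as an empty or zero cell
  lines <- readLines(path)
  expect_true(any(grepl(",ND,", lines, fixed = TRUE)))
})

test_that("schema violations are reported by column name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Plate,Well,Description,GenID,Raw_r1,Raw_r2",
               "1,B08,sample,R06C7.10,5,41"), path)
  expect_error(read_screen_table(path, schema = "raw_counts"), "GeneID")
  expect_error(read_screen_table(path, schema = "data_record"), "GeneID")
})

test_that("description tokens map to content classes and bad tokens fail loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Plate,Well,Strain,BioRep,TechRep,Description,GeneID,ParentCount,ProgenyCount",
    "1,B08,wild_type,1,1,sample,R06C7.10,5,41",
    "1,A01,wild_type,1,1,neg,L4440,6,200",
    "1,G01,wild_type,1,1,pos,dli-1,7,150",
    "1,E01,wild_type,1,1,other,plk-1,7,0"
  ), path)
  tab <- read_screen_table(path, schema = "raw_counts")
  expect_equal(tab$content, c("sample", "neg_control", "pos_control",
                              "lethality_control"))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Plate,Well,Strain,BioRep,TechRep,Description,GeneID,ParentCount,ProgenyCount",
    "1,B08,wild_type,1,1,mystery,x,5,41"
  ), bad)
  expect_error(read_screen_table(bad, schema = "raw_counts"), "mystery")
})

test_that("unparseable numeric cells become ND, never zero, and none are invented", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Plate,Well,Strain,BioRep,TechRep,Description,GeneID,ParentCount,ProgenyCount",
    "1,B02,wild_type,1,1,sample,g1,5,41",
    "1,B03,wild_type,1,1,sample,g2,nd,33",
    "1,B04,wild_type,1,1,sample,g3,7,#VALUE!",
    "1,B05,wild_type,1,1,sample,g4,ND,ND"
  ), path)
  tab <- suppressWarnings(read_screen_table(path, schema = "raw_counts"))
  expect_equal(tab$parent_count, c(5, NA, 7, NA))
  expect_equal(tab$progeny_count, c(41, 33, NA, NA))
  # parser never invents counts: defined values out <= numeric cells in
  expect_lte(sum(!is.na(tab$parent_count)) + sum(!is.na(tab$progeny_count)), 4)
})

test_that("duplicated well records are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Plate,Well,Strain,BioRep,TechRep,Description,GeneID,ParentCount,ProgenyCount",
    "1,B02,wild_type,1,1,sample,g1,5,41",
    "1,B2,wild_type,1,1,sample,g1,5,41"
  ), path)
  expect_error(read_screen_table(path, schema = "raw_counts"), "duplicated")
})

test_that("tab-delimited tables are detected from the header line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("Plate\tWell\tStrain\tBioRep\tTechRep\tDescription\tGeneID\tParentCount\tProgenyCount",
      "1\tB08\twild_type\t1\t1\tsample\tR06C7.10\t5\t41"),
    collapse = "\n"), path)
  tab <- read_screen_table(path, schema = "raw_counts")
  expect_equal(tab$gene_id, "R06C7.10")
  expect_equal(tab$progeny_count, 41)
})

test_that("layout validation flags misplaced controls, misplaced samples, and unpaired strains", {
  wells <- tiny_wells()
  expect_equal(nrow(validate_layout(wells)), 0)

  stray <- wells
  stray$well[stray$gene_id == "dli-1" & stray$well == "G01"] <- "D05"
  rep1 <- validate_layout(stray)
  expect_true(any(rep1$issue == "control outside column 1" & rep1$well == "D05"))

  misplaced <- wells
  misplaced$content[misplaced$well == "A01"] <- "sample"
  expect_true(any(validate_layout(misplaced)$issue == "sample in a control slot"))

  unpaired <- wells[!(wells$well == "B02" & wells$strain == "mutant"), ]
  rep3 <- validate_layout(unpaired)
  expect_true(any(rep3$issue == "unpaired strain" & rep3$well == "B02"))
})
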