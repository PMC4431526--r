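# Column headings of the two on-disk schemas. "raw_counts" is the long
# per-well format produced by the simulator (one row per well x strain x
# replicate); "data_record" is the wide per-clone summary layout used for
# deposited results (one row per clone per experiment, both strains side by
# side, RF columns averaged over technical replicates).
SCHEMA_COLUMNS <- list(
  raw_counts = c("Plate", "Well", "Strain", "BioRep", "TechRep",
                 "Description", "GeneID", "ParentCount", "ProgenyCount"),
  data_record = c("Plate", "Well", "Description", "GeneID", "BioRep",
                  "RF_wt", "RF_mut", "RFratio", "Lethality_wt",
                  "Classification")
)

# Parse a numeric column; the ND token (case-insensitive) and anything
# unparseable become NA, never zero.
parse_nd_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[toupper(x) == ND_TOKEN | x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

format_nd <- function(x, digits = 15) {
  out <- ifelse(is.na(x), ND_TOKEN, format(x, digits = digits, trim = TRUE,
                                           scientific = FALSE))
  out
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

check_schema <- function(found, schema) {
  expected <- SCHEMA_COLUMNS[[schema]]
  missing <- setdiff(expected, found)
  if (length(missing) > 0) {
    stop(sprintf("schema '%s': missing mandatory column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

content_from_description <- function(description) {
  d <- tolower(trimws(description))
  map <- setNames(names(DESCRIPTION_TOKENS), DESCRIPTION_TOKENS)
  bad <- !d %in% names(map)
  if (any(bad)) {
    stop("unknown Description token(s): ",
         paste(unique(description[bad]), collapse = ", "),
         " (expected sample/neg/pos/other)", call. = FALSE)
  }
  unname(map[d])
}

description_from_content <- function(content) {
  unname(DESCRIPTION_TOKENS[content])
}

#' Read a plate-structured screen table
#'
#' Reads a CSV or TSV screen table (delimiter auto-detected from the header
#' line) in one of two schemas. `"raw_counts"` holds one row per well x
#' strain x replicate with parent and progeny counts and yields per-well
#' measurements; `"data_record"` holds one row per clone per experiment with
#' replicate-averaged RF values, the RF ratio and the classification, and
#' yields clone results. In both, the Description column uses the tokens
#' `sample`, `neg` (negative control), `pos` (positive control) and `other`
#' (embryonic-lethality control), and `ND` (any case) marks not-determined
#' numeric cells; unparseable numeric cells also become ND, never zero.
#'
#' @param path Path to the file.
#' @param schema `"raw_counts"` or `"data_record"`.
#' @return A tibble of well measurements (`plate`, `well`, `strain`,
#'   `bio_rep`, `tech_rep`, `content`, `gene_id`, `parent_count`,
#'   `progeny_count`) or clone results (`plate`, `well`, `content`,
#'   `gene_id`, `bio_rep`, `rf_wt`, `rf_mut`, `rf_ratio`, `lethality_wt`,
#'   `classification`).
#' @export
read_screen_table <- function(path, schema = c("raw_counts", "data_record")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  check_schema(names(raw), schema)
  raw <- tibble::as_tibble(raw)

  if (schema == "raw_counts") {
    out <- tibble::tibble(
      plate = as.integer(raw$Plate),
      well = normalize_well(raw$Well),
      strain = raw$Strain,
      bio_rep = as.integer(raw$BioRep),
      tech_rep = as.integer(raw$TechRep),
      content = content_from_description(raw$Description),
      gene_id = raw$GeneID,
      parent_count = parse_nd_numeric(raw$ParentCount),
      progeny_count = parse_nd_numeric(raw$ProgenyCount)
    )
    bad_strain <- !out$strain %in% STRAIN_LEVELS
    if (any(bad_strain)) {
      stop("unknown Strain value(s): ",
           paste(unique(out$strain[bad_strain]), collapse = ", "),
           " (expected wild_type/mutant)", call. = FALSE)
    }
    key <- out[c("plate", "well", "strain", "bio_rep", "tech_rep")]
  } else {
    out <- tibble::tibble(
      plate = as.integer(raw$Plate),
      well = normalize_well(raw$Well),
      content = content_from_description(raw$Description),
      gene_id = raw$GeneID,
      bio_rep = as.integer(raw$BioRep),
      rf_wt = parse_nd_numeric(raw$RF_wt),
      rf_mut = parse_nd_numeric(raw$RF_mut),
      rf_ratio = parse_nd_numeric(raw$RFratio),
      lethality_wt = parse_nd_numeric(raw$Lethality_wt),
      classification = raw$Classification
    )
    bad_class <- !out$classification %in% CLASS_LEVELS
    if (any(bad_class)) {
      stop("unknown Classification value(s): ",
           paste(unique(out$classification[bad_class]), collapse = ", "),
           call. = FALSE)
    }
    key <- out[c("plate", "well", "bio_rep")]
  }
  dup <- duplicated(key)
  if (any(dup)) {
    w <- out[dup, ]
    stop("duplicated record(s) for: ",
         paste(utils::head(sprintf("plate %s well %s", w$plate, w$well), 5),
               collapse = "; "), call. = FALSE)
  }
  out
}

#' Write well measurements in the raw-counts schema
#'
#' @param wells Tibble of well measurements (see [read_screen_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_counts <- function(wells, path) {
  df <- data.frame(
    Plate = wells$plate,
    Well = wells$well,
    Strain = wells$strain,
    BioRep = wells$bio_rep,
    TechRep = wells$tech_rep,
    Description = description_from_content(wells$content),
    GeneID = wells$gene_id,
    ParentCount = format_nd(wells$parent_count),
    ProgenyCount = format_nd(wells$progeny_count),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write clone results in the data-record schema
#'
#' Writes one row per clone per experiment with the replicate-averaged
#' normalized RF of each strain, the RF ratio, the wild-type lethality and
#' the classification. Not-determined values are written as the token `ND`.
#' A table written with this function reads back identically with
#' `read_screen_table(path, schema = "data_record")`.
#'
#' @param results Tibble of clone results carrying classifications (see
#'   [read_screen_table()] for columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_data_record <- function(results, path) {
  stopifnot("classification" %in% names(results))
  df <- data.frame(
    Plate = results$plate,
    Well = results$well,
    Description = description_from_content(results$content),
    GeneID = results$gene_id,
    BioRep = results$bio_rep,
    RF_wt = format_nd(results$rf_wt),
    RF_mut = format_nd(results$rf_mut),
    RFratio = format_nd(results$rf_ratio),
    Lethality_wt = format_nd(results$lethality_wt),
    Classification = results$classification,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate the plate layout of a set of well measurements
#'
#' Checks the structural conventions of the screen layout: control wells
#' (negative, positive, lethality) live in column 1 (wells A1-H1), sample
#' wells live outside column 1, and every (plate, well, biological replicate,
#' technical replicate) is assayed in both strains. Violations are reported,
#' not raised: a conforming layout yields an empty report.
#'
#' @param wells Tibble of well measurements.
#' @return A tibble with columns `plate`, `well`, `issue`; zero rows iff the
#'   layout conforms.
#' @export
validate_layout <- function(wells) {
  col <- well_column(wells$well)
  issues <- list(
    tibble::tibble(
      plate = wells$plate[wells$content != "sample" & col != 1L],
      well = wells$well[wells$content != "sample" & col != 1L],
      issue = "control outside column 1"
    ),
    tibble::tibble(
      plate = wells$plate[wells$content == "sample" & col == 1L],
      well = wells$well[wells$content == "sample" & col == 1L],
      issue = "sample in a control slot"
    )
  )
  pairing <- wells |>
    dplyr::distinct(.data$plate, .data$well, .data$bio_rep, .data$tech_rep,
                    .data$strain) |>
    dplyr::group_by(.data$plate, .data$well, .data$bio_rep, .data$tech_rep) |>
    dplyr::summarise(n_strains = dplyr::n_distinct(.data$strain),
                     .groups = "drop") |>
    dplyr::filter(.data$n_strains < 2L) |>
    dplyr::distinct(.data$plate, .data$well) |>
    dplyr::mutate(issue = "unpaired strain")
  out <- dplyr::bind_rows(c(issues, list(pairing)))
  dplyr::distinct(out) |> dplyr::arrange(.data$plate, .data$well, .data$issue)
}
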