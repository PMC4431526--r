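#' Normalize 96-well coordinates
#'
#' Accepts coordinates with or without a zero-padded column ("B8" and "B08"
#' both refer to row B, column 8) and returns the canonical zero-padded form.
#' Rows run A-H and columns 1-12.
#'
#' @param well Character vector of well coordinates.
#' @return Character vector of canonical coordinates such as `"B08"`.
#' @examples
#' normalize_well(c("B8", "b08", "A1"))
#' @export
normalize_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  m <- regmatches(w, regexec("^([A-H])0?([1-9][0-9]?)$", w))
  ok <- lengths(m) == 3L
  col <- rep(NA_integer_, length(w))
  row <- rep(NA_character_, length(w))
  row[ok] <- vapply(m[ok], `[`, character(1), 2L)
  col[ok] <- as.integer(vapply(m[ok], `[`, character(1), 3L))
  ok <- ok & !is.na(col) & col >= 1L & col <= 12L
  if (!all(ok)) {
    bad <- unique(w[!ok])
    stop("invalid well coordinate(s): ", paste(bad, collapse = ", "),
         " (expected row A-H, column 1-12)", call. = FALSE)
  }
  sprintf("%s%02d", row, col)
}

#' @rdname normalize_well
#' @export
well_column <- function(well) {
  as.integer(substr(normalize_well(well), 2L, 3L))
}

#' @rdname normalize_well
#' @export
well_row <- function(well) {
  substr(normalize_well(well), 1L, 1L)
}
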