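#' Normalize and parse 96-well plate addresses
#'
#' Well addresses come in mixed conventions from plate software ("A1",
#' "a01", ...). [normalize_well()] canonicalizes to an uppercase row letter
#' A--H followed by the column number 1--12 without leading zeros;
#' [parse_well()] returns zero-based row/column indices.
#'
#' @param well character vector of well addresses.
#' @return `normalize_well()`: character vector of canonical addresses.
#'   `parse_well()`: data.frame with columns `row` (0--7) and `col` (0--11).
#' @examples
#' normalize_well(c("a01", "H12"))
#' parse_well("B3")
#' @export
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-H])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid well address(es): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 12L)) {
    stop("well column out of range 1-12: ",
         paste(unique(well[col < 1L | col > 12L]), collapse = ", "),
         call. = FALSE)
  }
  paste0(row, col)
}

#' @rdname normalize_well
#' @export
parse_well <- function(well) {
  w <- normalize_well(well)
  data.frame(row = match(substr(w, 1L, 1L), LETTERS[1:8]) - 1L,
             col = as.integer(substring(w, 2L)) - 1L)
}

# canonical well order: A1..A12, B1..B12, ..., H12
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Role tokens recognized in plate layouts
#' @keywords internal
screen_roles <- function() {
  c("experimental", "empty_vector", "up_control", "down_control", "unused")
}
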