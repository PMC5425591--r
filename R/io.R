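#' Read a COPAS per-object table
#'
#' Reads a tab-delimited export of per-worm sorter reads, one row per
#' object, with (case-insensitive) columns `plate`, `well`, `TOF`, `EXT`
#' and `green`. Extra columns are ignored. Rows whose EXT or green signal
#' is missing, non-numeric, zero or negative cannot enter the size
#' normalization and are rejected -- never silently dropped: the returned
#' data frame carries a `"rejected"` attribute listing the file line number
#' and reason for every rejected row.
#'
#' @param path path to the table.
#' @param sep field separator (tab by default).
#' @param col_map optional named character vector mapping the canonical
#'   names `plate`, `well`, `tof`, `ext`, `green` to the column names used
#'   in the file, for non-standard exports.
#' @return data.frame with columns `plate`, `well` (canonicalized), `tof`,
#'   `ext`, `green`; attribute `"rejected"` is a data.frame of rejected
#'   line numbers and reasons.
#' @seealso [read_plate_layout()], [normalize_well()]
#' @export
read_copas_table <- function(path, sep = "\t", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty COPAS table: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  names(raw) <- tolower(names(raw))
  wanted <- c("plate", "well", "tof", "ext", "green")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- tolower(col_map[[canon]])
      if (!src %in% names(raw)) {
        stop("mapped column not found in file: ", col_map[[canon]],
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- tolower(canon)
    }
  }
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols)) {
    stop("COPAS table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[wanted]
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.frame(plate = character(), well = character(),
                      tof = numeric(), ext = numeric(), green = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tof <- num(raw$tof); ext <- num(raw$ext); green <- num(raw$green)
  # +1 for the header row: line numbers refer to the file
  line <- seq_len(n) + 1L
  reason <- rep(NA_character_, n)
  reason[is.na(green) | green <= 0] <- "non-numeric or non-positive green"
  reason[is.na(ext) | ext <= 0] <- "non-numeric or non-positive EXT"
  reason[is.na(tof) | tof < 0] <- "non-numeric or negative TOF"
  keep <- is.na(reason)
  out <- data.frame(plate = raw$plate[keep],
                    well = normalize_well(raw$well[keep]),
                    tof = tof[keep], ext = ext[keep], green = green[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(line = line[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Read a plate layout (plate map)
#'
#' Reads a CSV with columns `plate`, `well`, `clone_id`, `role`,
#' `repeat_index` assigning each well its RNAi clone and role. Roles must
#' be one of `experimental`, `empty_vector`, `up_control`, `down_control`,
#' `unused`. Each (plate, well) pair may appear only once. The expected
#' control design -- two empty-vector wells, one up-regulated and one
#' down-regulated control per experimental plate -- is checked and
#' deviations are reported as a warning (attribute `"design_check"`), not
#' an error.
#'
#' @param path path to the layout CSV.
#' @return data.frame layout with canonicalized wells; attribute
#'   `"design_check"` is a per-plate data.frame of control counts.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lay <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(lay) <- tolower(names(lay))
  wanted <- c("plate", "well", "clone_id", "role", "repeat_index")
  missing_cols <- setdiff(wanted, names(lay))
  if (length(missing_cols)) {
    stop("plate layout is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lay <- lay[wanted]
  bad_role <- setdiff(unique(lay$role), screen_roles())
  if (length(bad_role)) {
    stop("unknown role token(s) in layout: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  lay$well <- normalize_well(lay$well)
  lay$repeat_index <- as.integer(lay$repeat_index)
  if (anyNA(lay$repeat_index) || any(lay$repeat_index < 1L)) {
    stop("repeat_index must be a positive integer", call. = FALSE)
  }
  key <- paste(lay$plate, lay$well)
  if (anyDuplicated(key)) {
    stop("duplicate well assignment(s) in layout: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  validate_layout(lay)
}

# design check shared by the reader and the generator
validate_layout <- function(lay) {
  chk <- do.call(rbind, lapply(split(lay, lay$plate), function(p) {
    data.frame(plate = p$plate[1L],
               n_empty_vector = sum(p$role == "empty_vector"),
               n_up_control = sum(p$role == "up_control"),
               n_down_control = sum(p$role == "down_control"),
               n_experimental = sum(p$role == "experimental"),
               stringsAsFactors = FALSE)
  }))
  rownames(chk) <- NULL
  off <- chk$n_empty_vector != 2L | chk$n_up_control != 1L |
    chk$n_down_control != 1L
  if (any(off)) {
    warning("plate(s) deviate from the expected control design ",
            "(2 empty_vector, 1 up_control, 1 down_control): ",
            paste(chk$plate[off], collapse = ", "), call. = FALSE)
  }
  attr(lay, "design_check") <- chk
  lay
}

#' Write and re-read a hit table
#'
#' The hit table is a tab-delimited file with one row per scored clone and
#' a stable column order (`clone_id`, `direction`, `mean_rz`,
#' `secondary_p`, `counterscreen_p`, `call`), sorted by direction, then
#' decreasing `|mean_rz|`, then `clone_id` so ties are deterministic.
#' Reals are written with 6 significant digits; `write_hit_table()`
#' followed by `read_hit_table()` reproduces the records at that precision.
#'
#' @param hits data.frame of hit records (as produced by the hit-calling
#'   stage).
#' @param path output path.
#' @return `write_hit_table()` returns `path` invisibly; `read_hit_table()`
#'   returns the hit data.frame.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("clone_id", "direction", "mean_rz", "secondary_p",
            "counterscreen_p", "call")
  missing_cols <- setdiff(cols, names(hits))
  if (length(missing_cols)) {
    stop("hit table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  hits <- hits[cols]
  if (nrow(hits)) {
    ord <- order(hits$direction, -abs(hits$mean_rz), hits$clone_id)
    hits <- hits[ord, , drop = FALSE]
    for (cc in c("mean_rz", "secondary_p", "counterscreen_p")) {
      hits[[cc]] <- signif(as.numeric(hits[[cc]]), 6)
    }
  }
  write_tsv_atomic(hits, path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Atomic TSV writer: write to a temp file in the target directory, then
# rename, so an interrupted run never leaves a partial table.
write_tsv_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  ok <- tryCatch({
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", eol = "\n")
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (ok && !file.rename(tmp, path)) {
    stop("cannot write ", path, call. = FALSE)
  }
  invisible(path)
}
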