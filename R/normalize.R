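#' Per-worm relative fluorescent signal (RFS)
#'
#' The RFS of a worm is `log2(green / ext)`: the integrated SpH green
#' signal divided by the extinction integral (EXT, a worm-size proxy), on
#' the log2 scale. Dividing by EXT cancels worm size; the log2 transform
#' makes fold changes additive.
#'
#' @param green nonzero positive green signal (a.u.); vectorized.
#' @param ext positive EXT signal (a.u.); vectorized.
#' @return numeric vector of log2 signals.
#' @examples
#' worm_rfs(1024, 256)  # 2
#' worm_rfs(50, 200)    # -2
#' @export
worm_rfs <- function(green, ext) {
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    stop("EXT must be positive and finite (filter records upstream)",
         call. = FALSE)
  }
  if (any(!is.finite(green)) || any(green <= 0)) {
    stop("green must be positive and finite (filter records upstream)",
         call. = FALSE)
  }
  log2(green / ext)
}

#' Summarize COPAS records per well
#'
#' Joins per-worm records to the plate layout and reduces each well to its
#' worm count and the median per-worm RFS (for an even worm count, the
#' mean of the central pair). Wells with fewer than `min_worms` worms
#' carry an undefined (`NA`) median: too few animals to define a signal.
#' Wells in the layout with no records get `n_worms = 0`.
#'
#' @param records COPAS records data.frame (`plate`, `well`, `tof`, `ext`,
#'   `green`), e.g. from [read_copas_table()] or [simulate_screen()].
#' @param layout plate layout data.frame (see [read_plate_layout()]).
#' @param min_worms minimum worms for a defined median.
#' @return data.frame of well summaries: layout columns plus `n_worms`,
#'   `median_rfs`, `sterile` (initialized `FALSE`; see [flag_sterile()])
#'   and `rz` (`NA` until [normalize_plates()]).
#' @export
summarize_wells <- function(records, layout, min_worms = 5L) {
  stopifnot(min_worms >= 1)
  rec_key <- paste(records$plate, normalize_well(records$well))
  lay_key <- paste(layout$plate, layout$well)
  orphan <- !(rec_key %in% lay_key)
  if (any(orphan)) {
    stop("record well(s) absent from layout: ",
         paste(unique(rec_key[orphan])[1:min(5, sum(orphan))],
               collapse = ", "), call. = FALSE)
  }
  rfs <- worm_rfs(records$green, records$ext)
  med <- tapply(rfs, rec_key, stats::median)
  cnt <- tapply(rfs, rec_key, length)
  out <- layout
  out$n_worms <- as.integer(ifelse(is.na(cnt[lay_key]), 0L, cnt[lay_key]))
  out$median_rfs <- as.numeric(med[lay_key])
  out$median_rfs[out$n_worms < min_worms] <- NA_real_
  out$sterile <- FALSE
  out$rz <- NA_real_
  rownames(out) <- NULL
  out
}

#' Robust Z-score
#'
#' `rz_i = (x_i - median(x)) / MAD(x)` with the unscaled MAD,
#' `MAD = median(|x - median(x)|)`. Using the median and MAD instead of
#' the mean and SD makes the score insensitive to the very outliers a
#' screen is looking for. With `scaled = TRUE` the MAD is multiplied by
#' the normal-consistency factor 1.4826 so scores are comparable to
#' ordinary Z-scores under normality.
#'
#' @param x numeric vector of at least 3 finite values.
#' @param scaled apply the 1.4826 consistency factor.
#' @return numeric vector of robust Z-scores.
#' @examples
#' robust_z(c(1, 2, 3, 4, 5))  # -2 -1 0 1 2
#' @export
robust_z <- function(x, scaled = FALSE) {
  if (length(x) < 3L || any(!is.finite(x))) {
    stop("robust_z() needs at least 3 finite values", call. = FALSE)
  }
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    stop("degenerate dispersion: MAD is zero", call. = FALSE)
  }
  if (scaled) mad0 <- mad0 * 1.4826
  (x - med) / mad0
}

#' Plate-wise robust Z normalization of well summaries
#'
#' For each plate, estimates the median and MAD from the experimental
#' wells' median RFS (controls and sterile-flagged wells are excluded from
#' the estimate) and assigns every well with a defined median its robust
#' Z-score against those plate statistics. Normalizing per plate removes
#' plate-to-plate offsets by construction.
#'
#' A plate whose experimental medians have zero MAD has degenerate
#' dispersion; by default this is an error naming the plate (on real data
#' it indicates instrument failure). `zero_mad = "center"` instead returns
#' centred deviations (`x - median`) with a warning, which is the only
#' meaningful score on strictly noise-free data where most wells are
#' identical.
#'
#' @param wells well-summary data.frame from [summarize_wells()] (with
#'   `sterile` set if [flag_sterile()] has run).
#' @param min_wells minimum experimental wells with defined medians per
#'   plate.
#' @param scaled see [robust_z()].
#' @param zero_mad `"error"` or `"center"`.
#' @param pool if `TRUE`, estimate one median/MAD from all plates pooled
#'   instead of per plate (provided for comparison; per-plate is the
#'   default and removes plate offsets).
#' @return the input data.frame with `rz` filled in (sterile wells keep
#'   `NA`).
#' @export
normalize_plates <- function(wells, min_wells = 8L, scaled = FALSE,
                             zero_mad = c("error", "center"),
                             pool = FALSE) {
  zero_mad <- match.arg(zero_mad)
  wells$rz <- NA_real_
  est_pool <- if (pool) {
    wells$role == "experimental" & !wells$sterile & !is.na(wells$median_rfs)
  } else NULL
  for (pid in unique(wells$plate)) {
    on_plate <- wells$plate == pid
    est <- if (pool) est_pool else {
      on_plate & wells$role == "experimental" & !wells$sterile &
        !is.na(wells$median_rfs)
    }
    x <- wells$median_rfs[est]
    if (length(x) < min_wells) {
      stop("plate ", pid, ": only ", length(x),
           " usable experimental wells (need ", min_wells, ")",
           call. = FALSE)
    }
    med <- stats::median(x)
    mad0 <- stats::median(abs(x - med))
    if (mad0 == 0) {
      if (zero_mad == "error") {
        stop("plate ", pid, ": degenerate dispersion (MAD = 0)",
             call. = FALSE)
      }
      warning("plate ", pid, ": MAD = 0; returning centred deviations",
              call. = FALSE)
      denom <- 1
    } else {
      denom <- if (scaled) mad0 * 1.4826 else mad0
    }
    score <- on_plate & !wells$sterile & !is.na(wells$median_rfs)
    wells$rz[score] <- (wells$median_rfs[score] - med) / denom
  }
  wells
}

#' Score clones across repeat plates
#'
#' Collapses normalized well summaries to one record per clone: the
#' per-repeat median RFS and robust Z values, their mean
#' (`mean_rz`, defined only with at least two usable repeats), and the
#' between-repeat fold change `2^(max(rfs) - min(rfs))` (for two repeats,
#' `2^|rfs_1 - rfs_2|`). Status flags: `sterile` if any repeat well was
#' sterile-flagged, `missing_repeat` if fewer than two usable repeats.
#'
#' @param wells normalized well summaries ([normalize_plates()]).
#' @return data.frame with one row per experimental clone: `clone_id`,
#'   `n_repeats`, `mean_rfs`, `mean_rz`, `repeat_fold_change`, `sterile`,
#'   `missing_repeat`, `low_repeatability` (initialized `FALSE`, see
#'   [flag_low_repeatability()]) plus list columns `rfs` and `rz` with the
#'   per-repeat values ordered by `repeat_index`.
#' @export
score_clones <- function(wells) {
  exp_wells <- wells[wells$role == "experimental", , drop = FALSE]
  if (!nrow(exp_wells)) stop("no experimental wells to score", call. = FALSE)
  pieces <- lapply(split(exp_wells, exp_wells$clone_id), function(w) {
    w <- w[order(w$repeat_index), , drop = FALSE]
    usable <- !w$sterile & !is.na(w$median_rfs)
    rfs <- w$median_rfs[usable]
    rz <- w$rz[usable]
    n_rep <- length(rfs)
    data.frame(clone_id = w$clone_id[1L],
               n_repeats = n_rep,
               mean_rfs = if (n_rep) mean(rfs) else NA_real_,
               mean_rz = if (n_rep >= 2L) mean(rz) else NA_real_,
               repeat_fold_change = if (n_rep >= 2L)
                 2^(max(rfs) - min(rfs)) else NA_real_,
               sterile = any(w$sterile),
               missing_repeat = n_rep < 2L,
               low_repeatability = FALSE,
               rfs = I(list(rfs)), rz = I(list(rz)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
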