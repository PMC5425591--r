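#' Check in-plate control behaviour
#'
#' Every experimental plate carries two empty-vector (baseline) wells, one
#' up-regulated control (endocytosis-gene knockdown, expected ~6-fold
#' brighter) and one down-regulated control (reporter knockdown, expected
#' below 0.5-fold). The linear fold change of a control is
#' `2^(median_rfs(control) - mean(median_rfs(empty_vector)))`. A plate
#' fails control QC when the up control does not reach `up_min` or the
#' down control does not fall below `down_max` -- thresholds chosen well
#' inside the expected control magnitudes.
#'
#' @param wells well summaries for one or more plates (median RFS
#'   defined for the control wells).
#' @param up_min,down_max control fold-change thresholds (linear scale).
#' @return data.frame, one row per plate: `plate`, `fold_up`, `fold_down`,
#'   `controls_pass`.
#' @export
check_controls <- function(wells, up_min = 2.0, down_max = 0.7) {
  pieces <- lapply(split(wells, wells$plate), function(p) {
    ev <- p$median_rfs[p$role == "empty_vector"]
    ev <- ev[!is.na(ev)]
    if (!length(ev)) {
      stop("plate ", p$plate[1L], ": no empty-vector wells with defined ",
           "median RFS", call. = FALSE)
    }
    base <- mean(ev)
    fold_of <- function(role) {
      x <- p$median_rfs[p$role == role]
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else 2^(stats::median(x) - base)
    }
    fu <- fold_of("up_control")
    fd <- fold_of("down_control")
    pass <- (is.na(fu) || fu >= up_min) && (is.na(fd) || fd <= down_max)
    data.frame(plate = p$plate[1L], fold_up = fu, fold_down = fd,
               controls_pass = pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Flag clones with poor between-repeat repeatability
#'
#' A clone is flagged when its between-repeat fold change strictly exceeds
#' `threshold`; a fold change exactly at the threshold passes. The primary
#' screen uses 1.5; the secondary screen removes clones above 2.
#'
#' @param clones clone scores from [score_clones()].
#' @param threshold fold-change threshold (>= 1).
#' @return the input with `low_repeatability` set; clones without a
#'   defined fold change (missing repeat) are not flagged.
#' @export
flag_low_repeatability <- function(clones, threshold = 1.5) {
  stopifnot(threshold >= 1)
  fc <- clones$repeat_fold_change
  clones$low_repeatability <- !is.na(fc) & fc > threshold
  clones
}

#' Flag sterile/lethal wells
#'
#' A well is sterile/lethal when its worm (progeny) count is strictly
#' below `fraction` of the mean count over the plate's experimental wells
#' -- the candidate well itself included in the mean. Only experimental
#' wells are flagged; control wells are exempt.
#'
#' @param wells well summaries for one or more plates.
#' @param fraction progeny fraction threshold (default 0.20).
#' @return the input with `sterile` set.
#' @export
flag_sterile <- function(wells, fraction = 0.20) {
  stopifnot(fraction > 0, fraction < 1)
  for (pid in unique(wells$plate)) {
    is_exp <- wells$plate == pid & wells$role == "experimental"
    if (sum(is_exp) < 2L) next
    m <- mean(wells$n_worms[is_exp])
    wells$sterile[is_exp] <- wells$n_worms[is_exp] < fraction * m
  }
  wells
}

#' Between-repeat repeatability of a screen
#'
#' Reports the Pearson correlation of the first two repeats' log2 median
#' RFS across clones, and the fraction of clones whose between-repeat fold
#' change is at most 2 (the band between the lines `y = x + 1` and
#' `y = x - 1` on a repeat-vs-repeat log2 scatter).
#'
#' @param clones clone scores with at least 3 clones carrying both
#'   repeats.
#' @return list with `pearson_r`, `fraction_within_fold2` and `n_clones`.
#' @export
repeatability_report <- function(clones) {
  both <- clones$n_repeats >= 2L
  if (sum(both) < 3L) {
    stop("need at least 3 clones with both repeats", call. = FALSE)
  }
  r1 <- vapply(clones$rfs[both], `[`, 0, 1L)
  r2 <- vapply(clones$rfs[both], `[`, 0, 2L)
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
    stop("repeat vector is constant; correlation undefined", call. = FALSE)
  }
  list(pearson_r = stats::cor(r1, r2),
       fraction_within_fold2 =
         mean(clones$repeat_fold_change[both] <= 2),
       n_clones = sum(both))
}

#' Per-plate QC verdicts
#'
#' Combines control behaviour, sterile-well counts and clone repeatability
#' into one verdict per plate: `"fail"` when a control inverts or misses
#' its threshold, `"redo"` when more than `redo_fraction` of the plate's
#' clones are flagged low-repeatability (the plate should be re-measured),
#' otherwise `"pass"`.
#'
#' @param wells normalized well summaries (sterile flags set).
#' @param clones clone scores with `low_repeatability` set (see
#'   [flag_low_repeatability()]).
#' @param config a [screen_config()].
#' @return data.frame, one row per plate: control folds, `n_sterile`,
#'   `n_low_repeat_clones`, `verdict`.
#' @export
plate_qc <- function(wells, clones, config = screen_config()) {
  ctrl <- check_controls(wells, config$up_min, config$down_max)
  flagged_ids <- clones$clone_id[clones$low_repeatability]
  pieces <- lapply(split(wells, wells$plate), function(p) {
    ids <- p$clone_id[p$role == "experimental"]
    data.frame(plate = p$plate[1L],
               n_clones = length(ids),
               n_low_repeat_clones = sum(ids %in% flagged_ids),
               n_sterile = sum(p$sterile),
               stringsAsFactors = FALSE)
  })
  qc <- merge(ctrl, do.call(rbind, pieces), by = "plate", sort = TRUE)
  frac_flagged <- ifelse(qc$n_clones > 0,
                         qc$n_low_repeat_clones / qc$n_clones, 0)
  qc$verdict <- ifelse(!qc$controls_pass, "fail",
                       ifelse(frac_flagged > config$redo_fraction,
                              "redo", "pass"))
  qc
}
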