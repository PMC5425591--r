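#' Paralysis time-course summary
#'
#' Reduces per-replicate cumulative paralysis counts (worms failing to
#' respond to touch on drug plates, scored every 10 minutes) to the mean
#' paralyzed fraction and its SEM per timepoint. SEM uses the sample SD
#' (n - 1) over replicates divided by `sqrt(n_replicates)`.
#'
#' @param tables data.frame of paralysis counts for one strain and assay
#'   (columns `replicate`, `time_min`, `n_total`, `n_paralyzed`; e.g. from
#'   [simulate_paralysis()] or [read_paralysis_csv()]).
#' @return data.frame of class `"paralysis_curve"` with columns
#'   `time_min`, `mean_fraction`, `sem`; attributes `strain`,
#'   `n_replicates` and `fractions` (the replicate-by-timepoint fraction
#'   matrix used by [compare_paralysis()]).
#' @export
paralysis_curve <- function(tables) {
  need <- c("replicate", "time_min", "n_total", "n_paralyzed")
  missing_cols <- setdiff(need, names(tables))
  if (length(missing_cols)) {
    stop("paralysis table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tables$strain) && length(unique(tables$strain)) > 1L) {
    stop("paralysis_curve() summarizes one strain at a time", call. = FALSE)
  }
  reps <- split(tables, tables$replicate)
  tp <- sort(unique(tables$time_min))
  fr <- vapply(reps, function(r) {
    r <- r[order(r$time_min), , drop = FALSE]
    if (!identical(as.numeric(r$time_min), as.numeric(tp))) {
      stop("replicates carry misaligned timepoints", call. = FALSE)
    }
    if (any(r$n_paralyzed > r$n_total)) {
      stop("n_paralyzed exceeds n_total", call. = FALSE)
    }
    if (is.unsorted(r$n_paralyzed)) {
      stop("cumulative paralysis counts must be nondecreasing in time",
           call. = FALSE)
    }
    r$n_paralyzed / r$n_total
  }, numeric(length(tp)))
  fr <- matrix(fr, nrow = length(tp))
  n_rep <- ncol(fr)
  out <- data.frame(time_min = tp,
                    mean_fraction = rowMeans(fr),
                    sem = if (n_rep > 1) {
                      apply(fr, 1L, stats::sd) / sqrt(n_rep)
                    } else rep(0, length(tp)))
  attr(out, "strain") <- if (is.null(tables$strain)) NA_character_ else
    tables$strain[1L]
  attr(out, "n_replicates") <- n_rep
  attr(out, "fractions") <- fr
  class(out) <- c("paralysis_curve", "data.frame")
  out
}

#' Compare two paralysis curves at one timepoint
#'
#' Unpaired two-tailed t-test on the per-replicate paralyzed fractions of
#' two strains at a given timepoint. With identical zero-spread replicate
#' sets the difference is 0 and p is 1 by convention.
#'
#' @param curve_a,curve_b [paralysis_curve()] results with at least 2
#'   replicates each.
#' @param timepoint_min timepoint (minutes) present in both curves.
#' @return list with `difference` (mean fraction a - b), `p` and
#'   `timepoint_min`.
#' @export
compare_paralysis <- function(curve_a, curve_b, timepoint_min) {
  fa <- replicate_fractions(curve_a, timepoint_min)
  fb <- replicate_fractions(curve_b, timepoint_min)
  if (length(fa) < 2L || length(fb) < 2L) {
    stop("need at least 2 replicates per curve", call. = FALSE)
  }
  d <- mean(fa) - mean(fb)
  p <- if (stats::sd(fa) == 0 && stats::sd(fb) == 0) {
    if (d == 0) 1 else 0
  } else {
    stats::t.test(fa, fb, alternative = "two.sided")$p.value
  }
  list(difference = d, p = p, timepoint_min = timepoint_min)
}

replicate_fractions <- function(curve, timepoint_min) {
  stopifnot(inherits(curve, "paralysis_curve"))
  i <- match(timepoint_min, curve$time_min)
  if (is.na(i)) {
    stop("timepoint ", timepoint_min, " min not present in curve",
         call. = FALSE)
  }
  attr(curve, "fractions")[i, ]
}

#' Locomotion summary of one trajectory
#'
#' Classifies each frame by its signed velocity -- immobile when
#' `|velocity| < immobile_speed_mm_s`, else forward (positive) or backward
#' (negative) -- and reports time-weighted state fractions (summing to 1)
#' plus the time-weighted mean speed `|velocity|` over moving frames
#' (`NA` if the track never moves). Frame weights are the time steps to
#' the next frame (the final frame reuses the last step), so the summary
#' is invariant to uniform time rescaling.
#'
#' @param track data.frame with strictly increasing `time_s` and
#'   `velocity_mm_s` (mm/s, positive = forward) for a single worm.
#' @param immobile_speed_mm_s immobility threshold (mm/s).
#' @return list with `mean_speed`, `forward_fraction`,
#'   `backward_fraction`, `immobile_fraction`.
#' @export
locomotion_summary <- function(track, immobile_speed_mm_s = 0.02) {
  if (is.null(track$time_s) || is.null(track$velocity_mm_s) ||
      nrow(track) == 0L) {
    stop("track must carry time_s and velocity_mm_s", call. = FALSE)
  }
  t <- track$time_s
  v <- track$velocity_mm_s
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  w <- if (length(t) > 1L) {
    dt <- diff(t)
    c(dt, dt[length(dt)])
  } else {
    1
  }
  state <- ifelse(abs(v) < immobile_speed_mm_s, "immobile",
                  ifelse(v > 0, "forward", "backward"))
  tw <- sum(w)
  frac <- function(s) sum(w[state == s]) / tw
  moving <- state != "immobile"
  list(mean_speed = if (any(moving)) {
    sum(w[moving] * abs(v[moving])) / sum(w[moving])
  } else NA_real_,
  forward_fraction = frac("forward"),
  backward_fraction = frac("backward"),
  immobile_fraction = frac("immobile"))
}

#' Relative expression by the delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_mutant - dCt_wildtype`; the relative expression is
#' `2^-ddCt`, assuming perfect amplification efficiency (one PCR cycle =
#' one 2-fold difference).
#'
#' @param ct_target_mut,ct_ref_mut target and reference-gene Ct in the
#'   mutant (cycles).
#' @param ct_target_wt,ct_ref_wt the same in the wild type.
#' @return fold change of the target in the mutant relative to wild type.
#' @examples
#' relative_expression(24, 20, 22, 20)  # 0.25
#' @export
relative_expression <- function(ct_target_mut, ct_ref_mut,
                                ct_target_wt, ct_ref_wt) {
  cts <- c(ct_target_mut, ct_ref_mut, ct_target_wt, ct_ref_wt)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_mut - ct_ref_mut) - (ct_target_wt - ct_ref_wt)
  2^(-ddct)
}

#' Read endpoint assay CSVs
#'
#' Thin readers for the three endpoint formats: paralysis counts
#' (`strain, replicate, time_min, n_total, n_paralyzed`, optional
#' `assay`), locomotion tracks (`strain, worm_id, time_s,
#' velocity_mm_s`), and qPCR Ct values (`condition, gene, reference, ct`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_paralysis_csv <- function(path) {
  read_endpoint_csv(path, c("strain", "replicate", "time_min",
                            "n_total", "n_paralyzed"))
}

#' @rdname read_paralysis_csv
#' @export
read_tracks_csv <- function(path) {
  read_endpoint_csv(path, c("strain", "worm_id", "time_s", "velocity_mm_s"))
}

#' @rdname read_paralysis_csv
#' @export
read_qpcr_csv <- function(path) {
  read_endpoint_csv(path, c("condition", "gene", "reference", "ct"))
}

read_endpoint_csv <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(basename(path), " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
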