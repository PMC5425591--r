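#' Select candidate clones from the distribution tails
#'
#' Ranks usable clones (sterile and missing-repeat clones excluded; also
#' low-repeatability clones when `exclude_flagged = TRUE`) by their mean
#' robust Z-score and takes the `ceiling(tail_fraction/2 * N)` highest as
#' up candidates and as many lowest as down candidates. Ties at a cut are
#' broken by lexicographic `clone_id` order, so the candidate set is
#' deterministic; a fully tied (degenerate) distribution triggers a
#' warning.
#'
#' @param clones clone scores ([score_clones()], optionally with
#'   repeatability flags).
#' @param tail_fraction total tail mass in (0, 0.5].
#' @param exclude_flagged drop low-repeatability clones before ranking.
#' @return data.frame of hit records (`clone_id`, `direction`, `mean_rz`,
#'   `secondary_p`, `counterscreen_p`, `call = "candidate"`).
#' @export
select_tail_candidates <- function(clones, tail_fraction = 0.05,
                                   exclude_flagged = FALSE) {
  if (tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("`tail_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  usable <- !clones$sterile & !clones$missing_repeat & !is.na(clones$mean_rz)
  if (exclude_flagged) usable <- usable & !clones$low_repeatability
  sc <- clones[usable, c("clone_id", "mean_rz")]
  n <- nrow(sc)
  if (n == 0L) stop("no usable clones", call. = FALSE)
  k <- ceiling(tail_fraction / 2 * n)
  if (stats::sd(sc$mean_rz) == 0) {
    warning("degenerate score distribution: all mean rZ equal; ",
            "candidates chosen by clone_id order", call. = FALSE)
  }
  up <- sc[order(-sc$mean_rz, sc$clone_id), ][seq_len(min(k, n)), ]
  rest <- sc[!sc$clone_id %in% up$clone_id, , drop = FALSE]
  down <- rest[order(rest$mean_rz, rest$clone_id), ][
    seq_len(min(k, nrow(rest))), ]
  out <- rbind(data.frame(up, direction = "up", stringsAsFactors = FALSE),
               data.frame(down, direction = "down", stringsAsFactors = FALSE))
  data.frame(clone_id = out$clone_id, direction = out$direction,
             mean_rz = out$mean_rz, secondary_p = NA_real_,
             counterscreen_p = NA_real_, call = "candidate",
             stringsAsFactors = FALSE)
}

#' One-tailed two-sample t-test for screen validation
#'
#' Tests whether a candidate clone's replicate signals differ from the
#' same-plate empty-vector replicates in the direction fixed by the
#' primary screen (locking the direction prevents post-hoc tail
#' switching). Welch's unequal-variance test by default; `var_equal =
#' TRUE` gives the pooled-variance test.
#'
#' When both samples have zero spread the t statistic is undefined; the
#' returned p-value is then 0 if the means differ strictly in the
#' alternative's direction, 1 if they differ in the opposite direction,
#' and 0.5 if equal -- the limit of the test as noise vanishes, needed for
#' strictly noise-free data.
#'
#' @param candidate,control numeric replicate values (>= 2 each),
#'   typically per-repeat well median RFS.
#' @param direction `"up"` (candidate greater) or `"down"`.
#' @param var_equal pooled-variance test instead of Welch.
#' @return one-tailed p-value in \[0, 1\].
#' @examples
#' secondary_ttest(c(2.0, 2.1, 1.9, 2.0), c(1.0, 1.1, 0.9, 1.0), "up")
#' @export
secondary_ttest <- function(candidate, control,
                            direction = c("up", "down"),
                            var_equal = FALSE) {
  direction <- match.arg(direction)
  if (length(candidate) < 2L || length(control) < 2L) {
    stop("need at least 2 replicate values on each side", call. = FALSE)
  }
  alt <- if (direction == "up") "greater" else "less"
  if (stats::sd(candidate) == 0 && stats::sd(control) == 0) {
    d <- mean(candidate) - mean(control)
    if (direction == "down") d <- -d
    return(if (d > 0) 0 else if (d < 0) 1 else 0.5)
  }
  stats::t.test(candidate, control, alternative = alt,
                var.equal = var_equal)$p.value
}

#' Apply the counterscreen exclusion rule
#'
#' A candidate is a validated hit only if it is significant in the
#' secondary screen (`secondary_p < alpha`) and *not* significant in the
#' cytoplasmic-GFP counterscreen (`counterscreen_p >= alpha`); a
#' significant counterscreen marks a nonspecific fluorescence change and
#' excludes the clone. Candidates missing from the counterscreen keep the
#' `candidate` call with a missing-data note -- they are never silently
#' validated.
#'
#' @param hits hit records carrying `secondary_p`.
#' @param counterscreen_p named numeric vector of counterscreen p-values
#'   by `clone_id`.
#' @param alpha significance level for both rules.
#' @return hit records with `counterscreen_p` and `call` set to one of
#'   `validated`, `excluded_counterscreen`, `rejected`, `candidate`.
#' @export
apply_counterscreen <- function(hits, counterscreen_p, alpha = 0.05) {
  hits$counterscreen_p <- unname(counterscreen_p[hits$clone_id])
  call <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    sp <- hits$secondary_p[i]
    cp <- hits$counterscreen_p[i]
    call[i] <- if (is.na(sp) || sp >= alpha) {
      "rejected"
    } else if (is.na(cp)) {
      "candidate"  # missing counterscreen data: undecided, not validated
    } else if (cp < alpha) {
      "excluded_counterscreen"
    } else {
      "validated"
    }
  }
  hits$call <- call
  hits
}

# Secondary/counterscreen measurement: per-candidate replicate well medians
# vs the pooled empty-vector wells of the same plate set.
validation_round <- function(hits, data, config) {
  wells <- summarize_wells(data$records, data$layout, config$min_worms)
  wells <- flag_sterile(wells, config$sterile_fraction)
  p_out <- rep(NA_real_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cw <- wells[wells$role == "experimental" &
                  wells$clone_id == hits$clone_id[i] &
                  !wells$sterile & !is.na(wells$median_rfs), , drop = FALSE]
    if (nrow(cw) < 2L) next
    ev <- wells[wells$role == "empty_vector" & wells$plate %in% cw$plate &
                  !is.na(wells$median_rfs), , drop = FALSE]
    if (nrow(ev) < 2L) next
    p_out[i] <- secondary_ttest(cw$median_rfs, ev$median_rfs,
                                hits$direction[i], config$var_equal)
  }
  p_out
}
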