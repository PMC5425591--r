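#' Screen analysis configuration
#'
#' Collects every tunable threshold of the screening pipeline in one
#' validated list, so that no stage carries magic numbers. Defaults follow
#' the screen design this package implements: wells seeded with 5--8 L1
#' larvae (hence `min_worms = 5`), a 6-fold up-regulated and a <0.5-fold
#' down-regulated control per plate, a 1.5-fold between-repeat fold-change
#' rule in the primary screen, a 2-fold rule in the secondary screen, a 5%
#' two-tail candidate cut and raw `p < 0.05` decisions at the validation and
#' counterscreen rounds.
#'
#' @param min_worms minimum worms per well for the well median RFS to be
#'   considered defined.
#' @param min_wells minimum experimental wells with a defined median RFS
#'   required to normalize a plate.
#' @param mad_scaled if `TRUE`, scale the MAD by the normal-consistency
#'   factor 1.4826 so robust Z-scores are on a standard-deviation-comparable
#'   scale. The default is the bare (unscaled) MAD.
#' @param zero_mad what to do when a plate's experimental wells have zero
#'   MAD: `"error"` (degenerate dispersion aborts, the default) or
#'   `"center"` (return centred deviations with a warning; required for
#'   strictly noise-free data where most wells are identical).
#' @param sterile_fraction wells with fewer worms than this fraction of the
#'   plate's mean experimental-well count are flagged sterile/lethal
#'   (strict `<`).
#' @param up_min,down_max minimum linear fold change (vs the empty-vector
#'   mean) the up-regulated control must reach, and the maximum the
#'   down-regulated control may reach, for a plate to pass control QC.
#' @param repeat_fold_primary between-repeat fold-change threshold above
#'   which a clone is flagged low-repeatability in the primary screen
#'   (strict `>`).
#' @param repeat_fold_secondary same rule for the secondary screen; clones
#'   above it are removed before the validation t-test.
#' @param redo_fraction a plate is given verdict `"redo"` when more than
#'   this fraction of its clones are flagged low-repeatability.
#' @param exclude_low_repeat_primary if `TRUE`, clones flagged at
#'   `repeat_fold_primary` are also excluded from candidate selection. By
#'   default they are only reported (low-repeatability plates are a
#'   re-measurement signal, not a per-clone exclusion; clone-level removal
#'   happens in the secondary round).
#' @param tail_fraction total tail mass used for candidate selection; split
#'   equally between the up and down tails.
#' @param alpha significance level for the secondary t-test and the
#'   counterscreen exclusion rule.
#' @param var_equal if `TRUE`, use the pooled-variance t-test instead of the
#'   default Welch test.
#' @param p_adjust multiple-testing correction method for secondary
#'   p-values (`stats::p.adjust` method name); `"none"` by default, matching
#'   the raw per-round `p < 0.05` design.
#' @param immobile_speed_mm_s absolute velocity (mm/s) below which a
#'   locomotion frame is classified immobile.
#'
#' @return A list of class `"screen_config"`.
#' @examples
#' cfg <- screen_config(tail_fraction = 0.10)
#' cfg$alpha
#' @export
screen_config <- function(min_worms = 5L,
                          min_wells = 8L,
                          mad_scaled = FALSE,
                          zero_mad = c("error", "center"),
                          sterile_fraction = 0.20,
                          up_min = 2.0,
                          down_max = 0.7,
                          repeat_fold_primary = 1.5,
                          repeat_fold_secondary = 2.0,
                          redo_fraction = 0.25,
                          exclude_low_repeat_primary = FALSE,
                          tail_fraction = 0.05,
                          alpha = 0.05,
                          var_equal = FALSE,
                          p_adjust = "none",
                          immobile_speed_mm_s = 0.02) {
  zero_mad <- match.arg(zero_mad)
  stopifnot(min_worms >= 1, min_wells >= 3,
            is.logical(mad_scaled), length(mad_scaled) == 1L,
            sterile_fraction > 0, sterile_fraction < 1,
            up_min > 0, down_max > 0,
            repeat_fold_primary >= 1, repeat_fold_secondary >= 1,
            redo_fraction > 0, redo_fraction <= 1,
            is.logical(exclude_low_repeat_primary),
            alpha > 0, alpha < 1,
            immobile_speed_mm_s >= 0)
  if (tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("`tail_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  structure(list(
    min_worms = as.integer(min_worms),
    min_wells = as.integer(min_wells),
    mad_scaled = mad_scaled,
    zero_mad = zero_mad,
    sterile_fraction = sterile_fraction,
    up_min = up_min,
    down_max = down_max,
    repeat_fold_primary = repeat_fold_primary,
    repeat_fold_secondary = repeat_fold_secondary,
    redo_fraction = redo_fraction,
    exclude_low_repeat_primary = exclude_low_repeat_primary,
    tail_fraction = tail_fraction,
    alpha = alpha,
    var_equal = var_equal,
    p_adjust = p_adjust,
    immobile_speed_mm_s = immobile_speed_mm_s
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
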