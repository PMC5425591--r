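#' Fit the full multi-round screen analysis
#'
#' Runs the whole pipeline on a primary screen and, when supplied, a
#' secondary validation screen and a cytoplasmic-GFP counterscreen:
#'
#' 1. per-worm RFS and per-well medians ([summarize_wells()]);
#' 2. sterile/lethal well flagging ([flag_sterile()]);
#' 3. plate-wise robust Z normalization ([normalize_plates()]);
#' 4. clone scoring across repeats and repeatability flagging
#'    ([score_clones()], [flag_low_repeatability()]);
#' 5. plate QC verdicts and the repeat-reproducibility report
#'    ([plate_qc()], [repeatability_report()]);
#' 6. tail-based candidate selection ([select_tail_candidates()]);
#' 7. one-tailed t-test validation against in-plate empty-vector wells,
#'    after removing clones failing the secondary repeatability rule
#'    ([secondary_ttest()]);
#' 8. counterscreen exclusion ([apply_counterscreen()]).
#'
#' @param primary list with elements `records` and `layout` (e.g. a
#'   [simulate_screen()] result, or data read with [read_copas_table()]
#'   and [read_plate_layout()]).
#' @param secondary,counterscreen optional lists of the same shape for the
#'   validation rounds. Without a secondary screen the hits stay
#'   candidates; without a counterscreen, secondary-significant clones
#'   stay candidates (they are never validated on one round alone).
#' @param config a [screen_config()].
#' @return An object of class `"sph_screen"` with components `wells`,
#'   `clones`, `qc`, `repeatability`, `hits`, `counts` and `config`.
#'   Methods: [print.sph_screen()], [summary.sph_screen()],
#'   [coef.sph_screen()] (mean robust Z per clone), [plot.sph_screen()]
#'   (repeat-reproducibility scatter).
#' @examples
#' sim <- simulate_screen(n_plates = 2, noise_sd = 0.2, seed = 42)
#' fit <- sph_screen(sim)
#' fit
#' head(coef(fit))
#' @export
sph_screen <- function(primary, secondary = NULL, counterscreen = NULL,
                       config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  check_screen_data(primary, "primary")
  wells <- summarize_wells(primary$records, primary$layout, config$min_worms)
  wells <- flag_sterile(wells, config$sterile_fraction)
  wells <- normalize_plates(wells, config$min_wells, config$mad_scaled,
                            config$zero_mad)
  clones <- score_clones(wells)
  clones <- flag_low_repeatability(clones, config$repeat_fold_primary)
  qc <- plate_qc(wells, clones, config)
  rep_report <- repeatability_report(clones)

  hits <- select_tail_candidates(clones, config$tail_fraction,
                                 config$exclude_low_repeat_primary)
  # Before validation, drop candidates whose two primary repeats disagreed
  # by more than the secondary-round fold rule (strict >).
  fc <- clones$repeat_fold_change[match(hits$clone_id, clones$clone_id)]
  fold_fail <- !is.na(fc) & fc > config$repeat_fold_secondary
  n_secondary_low_repeat <- sum(fold_fail)
  if (!is.null(secondary)) {
    check_screen_data(secondary, "secondary")
    p <- validation_round(hits, secondary, config)
    p[fold_fail] <- NA_real_
    hits$secondary_p <- stats::p.adjust(p, method = config$p_adjust)
    if (!is.null(counterscreen)) {
      check_screen_data(counterscreen, "counterscreen")
      cp <- validation_round(hits, counterscreen, config)
      names(cp) <- hits$clone_id
      hits <- apply_counterscreen(hits, cp, config$alpha)
    } else {
      hits$call <- ifelse(is.na(hits$secondary_p) |
                            hits$secondary_p >= config$alpha,
                          "rejected", "candidate")
    }
    hits$call[fold_fail] <- "rejected"
  }

  counts <- c(clones = nrow(clones),
              usable = sum(!clones$sterile & !clones$missing_repeat),
              sterile = sum(clones$sterile),
              low_repeat_primary = sum(clones$low_repeatability),
              candidates = nrow(hits),
              candidates_up = sum(hits$direction == "up"),
              candidates_down = sum(hits$direction == "down"),
              low_repeat_secondary = n_secondary_low_repeat,
              validated = sum(hits$call == "validated"),
              validated_up = sum(hits$call == "validated" &
                                   hits$direction == "up"),
              validated_down = sum(hits$call == "validated" &
                                     hits$direction == "down"),
              excluded_counterscreen =
                sum(hits$call == "excluded_counterscreen"),
              rejected = sum(hits$call == "rejected"))

  structure(list(wells = wells, clones = clones, qc = qc,
                 repeatability = rep_report, hits = hits, counts = counts,
                 config = config,
                 has_secondary = !is.null(secondary),
                 has_counterscreen = !is.null(counterscreen)),
            class = "sph_screen")
}

check_screen_data <- function(x, what) {
  if (!is.list(x) || is.null(x$records) || is.null(x$layout)) {
    stop("`", what, "` must be a list with elements `records` and `layout`",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.sph_screen <- function(x, ...) {
  cat("COPAS SpH screen analysis\n")
  cat(sprintf("  plates: %d   clones scored: %d (usable %d, sterile %d)\n",
              nrow(x$qc), x$counts[["clones"]], x$counts[["usable"]],
              x$counts[["sterile"]]))
  cat(sprintf("  repeatability: r = %.3f, %.1f%% of clones within 2-fold\n",
              x$repeatability$pearson_r,
              100 * x$repeatability$fraction_within_fold2))
  cat(sprintf("  candidates: %d (%d up / %d down)\n",
              x$counts[["candidates"]], x$counts[["candidates_up"]],
              x$counts[["candidates_down"]]))
  if (x$has_secondary) {
    cat(sprintf("  validated hits: %d (%d up / %d down), %d excluded by counterscreen\n",
                x$counts[["validated"]], x$counts[["validated_up"]],
                x$counts[["validated_down"]],
                x$counts[["excluded_counterscreen"]]))
  } else {
    cat("  (no secondary screen supplied: hits are candidates only)\n")
  }
  invisible(x)
}

#' @rdname sph_screen
#' @param object,x an `sph_screen` fit.
#' @param ... unused.
#' @export
summary.sph_screen <- function(object, ...) {
  structure(list(counts = object$counts,
                 qc = object$qc,
                 repeatability = object$repeatability,
                 verdicts = table(object$qc$verdict),
                 hits = object$hits[object$hits$call %in%
                                      c("validated", "candidate"), ]),
            class = "summary.sph_screen")
}

#' @export
print.summary.sph_screen <- function(x, ...) {
  cat("Stage counts:\n")
  print(x$counts)
  cat("\nPlate verdicts:\n")
  print(x$verdicts)
  cat(sprintf("\nRepeatability: r = %.3f, fraction within 2-fold = %.3f (n = %d)\n",
              x$repeatability$pearson_r, x$repeatability$fraction_within_fold2,
              x$repeatability$n_clones))
  if (nrow(x$hits)) {
    cat("\nHits:\n")
    h <- x$hits[order(x$hits$direction, -abs(x$hits$mean_rz)), ]
    print(utils::head(h[c("clone_id", "direction", "mean_rz",
                          "secondary_p", "call")], 20), row.names = FALSE)
    if (nrow(h) > 20) cat("  ...", nrow(h) - 20, "more\n")
  }
  invisible(x)
}

#' @rdname sph_screen
#' @export
coef.sph_screen <- function(object, ...) {
  stats::setNames(object$clones$mean_rz, object$clones$clone_id)
}

#' @rdname sph_screen
#' @param main plot title.
#' @export
plot.sph_screen <- function(x, main = "Repeat reproducibility", ...) {
  both <- x$clones$n_repeats >= 2L
  r1 <- vapply(x$clones$rfs[both], `[`, numeric(1), 1L)
  r2 <- vapply(x$clones$rfs[both], `[`, numeric(1), 2L)
  graphics::plot(r1, r2, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("grey30", 0.6),
                 xlab = "log2 median RFS, repeat 1",
                 ylab = "log2 median RFS, repeat 2", main = main, ...)
  graphics::abline(0, 1, col = "red")
  graphics::abline(1, 1, col = "darkgreen", lty = 2)
  graphics::abline(-1, 1, col = "darkgreen", lty = 2)
  graphics::legend("topleft", bty = "n", lty = c(1, 2),
                   col = c("red", "darkgreen"),
                   legend = c("y = x", "2-fold change"))
  invisible(x)
}
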