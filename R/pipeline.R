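#' Run one pipeline stage from a configuration
#'
#' Orchestrates the screen stages behind a single entry point with a YAML
#' (or list) configuration, deterministic seeding, atomic output writes
#' and a JSON run manifest. This is what the `inst/cli/sphscreen.R`
#' command-line wrapper dispatches to.
#'
#' Config keys: `seed` (integer), `simulate` (arguments passed to
#' [simulate_screen()]), `inputs` (paths: `copas`, `layout`,
#' `secondary_copas`, `secondary_layout`, `counterscreen_copas`,
#' `counterscreen_layout`, `paralysis`, `tracks`, `qpcr`, `hits`, `qc`,
#' `summary`) and `thresholds` (arguments passed to [screen_config()]).
#'
#' The manifest (`manifest.json` in `out_dir`) records the config
#' snapshot, md5 digests of all inputs, the seed, per-stage timings, the
#' output file list and the package version; it is written even when a
#' stage fails, with the failing stage named.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param subcommand one of `simulate`, `normalize`, `qc`, `call-hits`,
#'   `endpoints`, `report`.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @return invisibly, a named character vector of output paths.
#' @export
run_pipeline <- function(config, subcommand, out_dir = ".", seed = NULL) {
  subcommands <- c("simulate", "normalize", "qc", "call-hits",
                   "endpoints", "report")
  if (length(subcommand) != 1L || !subcommand %in% subcommands) {
    stop("unknown subcommand: ", paste(subcommand, collapse = ", "),
         "; expected one of ", paste(subcommands, collapse = ", "),
         call. = FALSE)
  }
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a YAML path or a list", call. = FALSE)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  inputs <- unlist(cfg$inputs)
  if (is.null(inputs)) inputs <- character()
  missing_inputs <- inputs[!file.exists(inputs)]
  manifest <- list(subcommand = subcommand,
                   config = cfg,
                   seed = cfg$seed,
                   inputs = if (length(inputs)) {
                     data.frame(path = unname(inputs),
                                md5 = unname(tools::md5sum(inputs)))
                   } else NULL,
                   outputs = character(),
                   version = as.character(utils::packageVersion("sphscreen")),
                   status = "running")
  write_manifest <- function() {
    json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA, na = "null")
    writeLines(json, file.path(out_dir, "manifest.json"))
  }
  t0 <- proc.time()[["elapsed"]]
  outputs <- tryCatch({
    if (length(missing_inputs)) {
      stop("input file(s) not found: ",
           paste(missing_inputs, collapse = ", "), call. = FALSE)
    }
    run_stage(subcommand, cfg, out_dir)
  }, error = function(e) {
    manifest$status <<- paste0("failed at ", subcommand, ": ",
                               conditionMessage(e))
    manifest$elapsed_s <<- proc.time()[["elapsed"]] - t0
    write_manifest()
    stop(e)
  })
  manifest$status <- "ok"
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  manifest$outputs <- unname(outputs)
  write_manifest()
  message(sprintf("[sphscreen] %s: wrote %d file(s) to %s in %.2fs",
                  subcommand, length(outputs), out_dir,
                  manifest$elapsed_s))
  invisible(outputs)
}

run_stage <- function(subcommand, cfg, out_dir) {
  config <- do.call(screen_config, as.list(cfg$thresholds))
  path_of <- function(key) cfg$inputs[[key]]
  out <- function(name) file.path(out_dir, name)

  if (subcommand == "simulate") {
    args <- as.list(cfg$simulate)
    args$seed <- cfg$seed
    sim <- do.call(simulate_screen, args)
    write_tsv_atomic(sim$records, out("copas.tsv"))
    write_tsv_atomic(sim$layout, out("layout.csv.tsv"))
    utils::write.csv(sim$layout, out("layout.csv"), row.names = FALSE,
                     quote = FALSE)
    unlink(out("layout.csv.tsv"))
    truth <- data.frame(clone_id = names(sim$truth$clone_effects),
                        effect = unname(sim$truth$clone_effects),
                        sterile = names(sim$truth$clone_effects) %in%
                          sim$truth$sterile_clones)
    write_tsv_atomic(truth, out("truth.tsv"))
    return(c(out("copas.tsv"), out("layout.csv"), out("truth.tsv")))
  }

  if (subcommand %in% c("normalize", "qc", "call-hits")) {
    records <- read_copas_table(path_of("copas"))
    layout <- read_plate_layout(path_of("layout"))
    wells <- summarize_wells(records, layout, config$min_worms)
    wells <- flag_sterile(wells, config$sterile_fraction)
    wells <- normalize_plates(wells, config$min_wells, config$mad_scaled,
                              config$zero_mad)
    clones <- score_clones(wells)
    clones <- flag_low_repeatability(clones, config$repeat_fold_primary)
    if (subcommand == "normalize") {
      write_tsv_atomic(wells, out("well_summary.tsv"))
      write_tsv_atomic(flatten_clones(clones), out("clone_scores.tsv"))
      return(c(out("well_summary.tsv"), out("clone_scores.tsv")))
    }
    if (subcommand == "qc") {
      qc <- plate_qc(wells, clones, config)
      rep_report <- repeatability_report(clones)
      qc$pearson_r <- rep_report$pearson_r
      qc$fraction_within_fold2 <- rep_report$fraction_within_fold2
      write_tsv_atomic(qc, out("qc_report.tsv"))
      flagged <- flatten_clones(clones[clones$low_repeatability |
                                         clones$sterile, , drop = FALSE])
      write_tsv_atomic(flagged, out("flagged_clones.tsv"))
      return(c(out("qc_report.tsv"), out("flagged_clones.tsv")))
    }
    # call-hits
    secondary <- screen_data_from(path_of("secondary_copas"),
                                  path_of("secondary_layout"))
    counter <- screen_data_from(path_of("counterscreen_copas"),
                                path_of("counterscreen_layout"))
    fit <- sph_screen(list(records = records, layout = layout),
                      secondary = secondary, counterscreen = counter,
                      config = config)
    write_hit_table(fit$hits, out("hits.tsv"))
    counts <- data.frame(stage = names(fit$counts),
                         count = unname(fit$counts))
    write_tsv_atomic(counts, out("screen_summary.tsv"))
    return(c(out("hits.tsv"), out("screen_summary.tsv")))
  }

  if (subcommand == "endpoints") {
    outs <- character()
    if (!is.null(path_of("paralysis"))) {
      tab <- read_paralysis_csv(path_of("paralysis"))
      curves <- lapply(split(tab, tab$strain), paralysis_curve)
      flat <- do.call(rbind, lapply(names(curves), function(s) {
        data.frame(strain = s, as.data.frame(curves[[s]]))
      }))
      write_tsv_atomic(flat, out("paralysis_summary.tsv"))
      outs <- c(outs, out("paralysis_summary.tsv"))
    }
    if (!is.null(path_of("tracks"))) {
      tr <- read_tracks_csv(path_of("tracks"))
      key <- interaction(tr$strain, tr$worm_id, drop = TRUE)
      flat <- do.call(rbind, lapply(split(tr, key), function(w) {
        s <- locomotion_summary(w, config$immobile_speed_mm_s)
        data.frame(strain = w$strain[1L], worm_id = w$worm_id[1L],
                   as.data.frame(s))
      }))
      write_tsv_atomic(flat, out("locomotion_summary.tsv"))
      outs <- c(outs, out("locomotion_summary.tsv"))
    }
    if (!is.null(path_of("qpcr"))) {
      q <- read_qpcr_csv(path_of("qpcr"))
      flat <- qpcr_fold_changes(q)
      write_tsv_atomic(flat, out("qpcr_summary.tsv"))
      outs <- c(outs, out("qpcr_summary.tsv"))
    }
    if (!length(outs)) {
      stop("endpoints: no endpoint inputs in config", call. = FALSE)
    }
    return(outs)
  }

  # report
  hits <- read_hit_table(path_of("hits"))
  qc <- utils::read.delim(path_of("qc"), stringsAsFactors = FALSE)
  counts <- utils::read.delim(path_of("summary"), stringsAsFactors = FALSE)
  txt <- render_report(hits, qc, counts)
  tmp <- tempfile(tmpdir = out_dir)
  writeLines(txt, tmp)
  file.rename(tmp, out("report.txt"))
  out("report.txt")
}

screen_data_from <- function(copas_path, layout_path) {
  if (is.null(copas_path) || is.null(layout_path)) return(NULL)
  list(records = read_copas_table(copas_path),
       layout = read_plate_layout(layout_path))
}

flatten_clones <- function(clones) {
  clones$rfs <- vapply(clones$rfs, function(x) {
    paste(signif(x, 6), collapse = ";")
  }, character(1))
  clones$rz <- vapply(clones$rz, function(x) {
    paste(signif(x, 6), collapse = ";")
  }, character(1))
  clones
}

# mean fold change per (gene, reference) pair: mutant vs wildtype Ct
qpcr_fold_changes <- function(q) {
  if (!all(c("wildtype", "mutant") %in% unique(q$condition))) {
    stop("qPCR table needs conditions 'wildtype' and 'mutant'",
         call. = FALSE)
  }
  pieces <- lapply(split(q, list(q$gene, q$reference), drop = TRUE),
                   function(g) {
    if (g$gene[1L] == g$reference[1L]) return(NULL)
    ref <- q[q$gene == g$reference[1L], ]
    ct <- function(df, cond) mean(df$ct[df$condition == cond])
    fold <- relative_expression(ct(g, "mutant"), ct(ref, "mutant"),
                                ct(g, "wildtype"), ct(ref, "wildtype"))
    data.frame(gene = g$gene[1L], reference = g$reference[1L],
               fold_change = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Render a human-readable screen report
#'
#' Assembles the stage counts, per-plate control folds and verdicts,
#' the repeatability summary and the hit list into a plain-text report.
#' Rendering is deterministic: the same inputs give identical bytes.
#'
#' @param hits hit table data.frame.
#' @param qc plate QC data.frame (optionally carrying `pearson_r` and
#'   `fraction_within_fold2` columns).
#' @param counts stage-count data.frame (`stage`, `count`).
#' @return character vector of report lines.
#' @export
render_report <- function(hits, qc, counts) {
  lines <- c("SpH screen report",
             "=================", "")
  lines <- c(lines, "Stage counts:")
  if (nrow(counts)) {
    lines <- c(lines, sprintf("  %-24s %d", counts$stage, counts$count))
  } else {
    lines <- c(lines, "  (none)")
  }
  lines <- c(lines, "", "Plate QC:")
  if (nrow(qc)) {
    lines <- c(lines, sprintf(
      "  %-10s fold_up=%.3f fold_down=%.3f sterile=%d verdict=%s",
      qc$plate, qc$fold_up, qc$fold_down, qc$n_sterile, qc$verdict))
    if (!is.null(qc$pearson_r)) {
      lines <- c(lines, sprintf(
        "  repeatability: r=%.3f, %.1f%% of clones within 2-fold",
        qc$pearson_r[1L], 100 * qc$fraction_within_fold2[1L]))
    }
  } else {
    lines <- c(lines, "  (no plates)")
  }
  lines <- c(lines, "", sprintf("Hits (%d):",
                                sum(hits$call == "validated")))
  hv <- hits[hits$call == "validated", , drop = FALSE]
  if (nrow(hv)) {
    hv <- hv[order(hv$direction, -abs(hv$mean_rz), hv$clone_id), ]
    lines <- c(lines, sprintf("  %-12s %-5s rZ=%+.3f p=%.4g",
                              hv$clone_id, hv$direction, hv$mean_rz,
                              hv$secondary_p))
  } else {
    lines <- c(lines, "  (none)")
  }
  lines
}
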