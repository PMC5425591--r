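#' Simulate a COPAS RNAi screen with planted truth
#'
#' Generates per-worm sorter reads, plate layouts and the planted ground
#' truth for a duplicated whole-genome-style screen: every clone appears on
#' exactly `n_repeats` repeat plates, every plate carries two empty-vector
#' wells, one up-regulated and one down-regulated control, and a fraction
#' of clones carries a planted multiplicative effect on the SpH signal.
#'
#' The noise model is chosen so that the EXT normalization cancels worm
#' size: per worm, `ext` is log-normal, and
#' `green = base_green_per_ext * ext * effect * 2^(plate_offset + well_noise)`
#' with `well_noise ~ N(0, noise_sd)` drawn once per well on the log2
#' scale. Sterile/lethal wells emit `Binomial(worms_per_well, 0.1)` worms,
#' safely below the 20% progeny rule. Control magnitudes default to the
#' screen design this emulates: a 6-fold up control and a 0.5-fold down
#' control.
#'
#' Reproducibility: the master `seed` streams into deterministic per-plate
#' substreams, so the same seed gives byte-identical tables.
#'
#' @param n_plates number of distinct clone plates (each is replicated
#'   `n_repeats` times).
#' @param clones_per_plate experimental clones per plate (92 fills a
#'   96-well plate around the four control wells).
#' @param hit_fraction fraction of clones given a planted effect (half up,
#'   half down); must be <= 0.5.
#' @param up_effect,down_effect planted multiplicative effects on green.
#' @param noise_sd per-well log2-scale SD of the multiplicative noise.
#' @param plate_offset_sd SD of per-plate additive log2 offsets (batch
#'   effects); 0 disables them.
#' @param worms_per_well nominal worms read per well.
#' @param sterile_fraction fraction of clones made sterile/lethal (their
#'   wells emit ~10% of the nominal worm count).
#' @param base_green_per_ext baseline green/EXT ratio of the reporter
#'   strain (a.u.).
#' @param ext_meanlog,ext_sdlog log-scale parameters of the per-worm EXT
#'   (worm size) distribution.
#' @param n_repeats repeat plates per clone (2 for the primary screen).
#' @param plate_prefix prefix for plate identifiers.
#' @param seed integer master seed.
#' @return An object of class `"copas_screen"`: a list with `records`
#'   (per-worm data.frame: plate, well, tof, ext, green), `layout`
#'   (plate-map data.frame) and `truth` (list with `clone_effects`,
#'   `sterile_clones`, `sterile_wells`, `plate_offsets` and the generator
#'   parameters).
#' @examples
#' sim <- simulate_screen(n_plates = 2, noise_sd = 0.1, seed = 1)
#' head(sim$records)
#' sim$truth$clone_effects[sim$truth$clone_effects != 1][1:3]
#' @export
simulate_screen <- function(n_plates = 10L,
                            clones_per_plate = 92L,
                            hit_fraction = 0.05,
                            up_effect = 6.0,
                            down_effect = 0.5,
                            noise_sd = 0.25,
                            plate_offset_sd = 0,
                            worms_per_well = 50L,
                            sterile_fraction = 0,
                            base_green_per_ext = 4,
                            ext_meanlog = log(250),
                            ext_sdlog = 0.3,
                            n_repeats = 2L,
                            plate_prefix = "P",
                            seed = 1L) {
  stopifnot(n_plates >= 1, clones_per_plate >= 1, clones_per_plate <= 92,
            up_effect > 0, down_effect > 0, noise_sd >= 0,
            plate_offset_sd >= 0, worms_per_well >= 1,
            sterile_fraction >= 0, sterile_fraction < 1,
            base_green_per_ext > 0, n_repeats >= 1)
  if (hit_fraction < 0 || hit_fraction > 0.5) {
    stop("`hit_fraction` must lie in [0, 0.5] (larger tails would overlap ",
         "the controls)", call. = FALSE)
  }
  n_clones <- n_plates * clones_per_plate
  clone_ids <- sprintf("c%05d", seq_len(n_clones))

  set.seed(as.integer(seed))
  effects <- rep(1, n_clones)
  names(effects) <- clone_ids
  n_hits <- round(hit_fraction * n_clones)
  hit_ids <- sample(clone_ids, n_hits)
  n_up <- ceiling(n_hits / 2)
  effects[hit_ids[seq_len(n_up)]] <- up_effect
  if (n_hits > n_up) effects[hit_ids[(n_up + 1):n_hits]] <- down_effect
  n_sterile <- round(sterile_fraction * n_clones)
  sterile_ids <- sample(setdiff(clone_ids, hit_ids), n_sterile)
  plate_ids <- as.vector(t(outer(sprintf("%s%02d", plate_prefix,
                                         seq_len(n_plates)),
                                 sprintf("_R%d", seq_len(n_repeats)),
                                 paste0)))
  plate_offsets <- stats::rnorm(length(plate_ids), 0, plate_offset_sd)
  names(plate_offsets) <- plate_ids

  chunks <- split(clone_ids, rep(seq_len(n_plates), each = clones_per_plate))
  pieces <- vector("list", n_plates * n_repeats)
  lays <- vector("list", n_plates * n_repeats)
  k <- 0L
  for (p in seq_len(n_plates)) {
    for (r in seq_len(n_repeats)) {
      k <- k + 1L
      pid <- sprintf("%s%02d_R%d", plate_prefix, p, r)
      plate_seed <- (as.integer(seed) + 7919L * (p * n_repeats + r)) %%
        .Machine$integer.max
      set.seed(plate_seed)
      lay <- plate_layout_frame(pid, chunks[[p]], r)
      eff <- control_effects(lay, effects, up_effect, down_effect)
      sterile <- lay$role == "experimental" & lay$clone_id %in% sterile_ids
      n_w <- ifelse(sterile,
                    stats::rbinom(nrow(lay), worms_per_well, 0.1),
                    worms_per_well)
      n_w[lay$role == "unused"] <- 0L
      well_noise <- stats::rnorm(nrow(lay), 0, noise_sd)
      idx <- rep(seq_len(nrow(lay)), n_w)
      total <- length(idx)
      ext <- stats::rlnorm(total, ext_meanlog, ext_sdlog)
      tof <- ext * 0.45 * exp(stats::rnorm(total, 0, 0.1))
      green <- base_green_per_ext * ext * eff[idx] *
        2^(plate_offsets[[pid]] + well_noise[idx])
      pieces[[k]] <- data.frame(plate = pid, well = lay$well[idx],
                                tof = tof, ext = ext, green = green,
                                stringsAsFactors = FALSE)
      lays[[k]] <- lay
    }
  }
  records <- do.call(rbind, pieces)
  rownames(records) <- NULL
  layout <- do.call(rbind, lays)
  rownames(layout) <- NULL
  layout <- suppressWarnings(validate_layout(layout))

  sterile_wells <- layout[layout$role == "experimental" &
                            layout$clone_id %in% sterile_ids,
                          c("plate", "well", "clone_id")]
  rownames(sterile_wells) <- NULL
  truth <- list(clone_effects = effects,
                sterile_clones = sterile_ids,
                sterile_wells = sterile_wells,
                plate_offsets = plate_offsets,
                noise_sd = noise_sd,
                worms_per_well = as.integer(worms_per_well),
                up_effect = up_effect, down_effect = down_effect,
                base_green_per_ext = base_green_per_ext,
                seed = as.integer(seed))
  structure(list(records = records, layout = layout, truth = truth),
            class = "copas_screen")
}

# fixed control positions; experimental clones fill the remaining wells
plate_layout_frame <- function(plate_id, clones, repeat_index) {
  wells <- all_wells()
  ctrl <- c(A1 = "empty_vector", H12 = "empty_vector",
            A12 = "up_control", H1 = "down_control")
  role <- rep("experimental", length(wells))
  names(role) <- wells
  role[names(ctrl)] <- ctrl
  exp_wells <- wells[role == "experimental"]
  if (length(clones) > length(exp_wells)) {
    stop("too many clones for one plate", call. = FALSE)
  }
  role[exp_wells[seq_along(exp_wells) > length(clones)]] <- "unused"
  clone_id <- rep(NA_character_, length(wells))
  names(clone_id) <- wells
  clone_id[exp_wells[seq_along(clones)]] <- clones
  clone_id[role == "empty_vector"] <- "L4440"
  clone_id[role == "up_control"] <- "unc-11"
  clone_id[role == "down_control"] <- "gfp"
  out <- data.frame(plate = plate_id, well = wells, clone_id = clone_id,
                    role = unname(role),
                    repeat_index = as.integer(repeat_index),
                    stringsAsFactors = FALSE)
  out[out$role != "unused", , drop = FALSE]
}

control_effects <- function(lay, effects, up_effect, down_effect) {
  eff <- rep(1, nrow(lay))
  is_exp <- lay$role == "experimental"
  eff[is_exp] <- effects[lay$clone_id[is_exp]]
  eff[lay$role == "up_control"] <- up_effect
  eff[lay$role == "down_control"] <- down_effect
  eff
}

#' Simulate a validation (secondary or counterscreen) round
#'
#' Re-arrays a set of candidate clones into fresh 96-well plates with the
#' standard four control wells and measures each plate `n_repeats` times
#' (four repeats in the secondary validation design). Effects default to
#' null (1.0) for every clone, which is the appropriate counterscreen
#' expectation for genuine vesicle-cycling hits; pass the planted primary
#' effects to emulate the secondary screen, or nonspecific-expression
#' effects to emulate counterscreen artifacts.
#'
#' @param clone_ids clones to re-array.
#' @param effects named vector of multiplicative effects; clones absent
#'   from it get effect 1.
#' @param n_repeats repeat plates (4 in the validation design).
#' @param plate_prefix prefix for the new plate identifiers.
#' @inheritParams simulate_screen
#' @return A `"copas_screen"` object (records, layout, truth).
#' @export
simulate_validation <- function(clone_ids,
                                effects = NULL,
                                n_repeats = 4L,
                                noise_sd = 0.25,
                                plate_offset_sd = 0,
                                worms_per_well = 50L,
                                base_green_per_ext = 4,
                                ext_meanlog = log(250),
                                ext_sdlog = 0.3,
                                plate_prefix = "V",
                                seed = 1L) {
  stopifnot(length(clone_ids) >= 1, !anyDuplicated(clone_ids))
  full <- rep(1, length(clone_ids))
  names(full) <- clone_ids
  if (!is.null(effects)) {
    hit <- intersect(names(effects), clone_ids)
    full[hit] <- effects[hit]
  }
  n_plates <- ceiling(length(clone_ids) / 92)
  chunks <- split(clone_ids, ceiling(seq_along(clone_ids) / 92))
  up_eff <- 6.0; down_eff <- 0.5
  pieces <- list(); lays <- list()
  k <- 0L
  for (p in seq_len(n_plates)) {
    for (r in seq_len(n_repeats)) {
      k <- k + 1L
      pid <- sprintf("%s%02d_R%d", plate_prefix, p, r)
      plate_seed <- (as.integer(seed) + 6131L * (p * n_repeats + r)) %%
        .Machine$integer.max
      set.seed(plate_seed)
      lay <- plate_layout_frame(pid, chunks[[p]], r)
      eff <- control_effects(lay, full, up_eff, down_eff)
      well_noise <- stats::rnorm(nrow(lay), 0, noise_sd)
      offset <- stats::rnorm(1, 0, plate_offset_sd)
      idx <- rep(seq_len(nrow(lay)), worms_per_well)
      total <- length(idx)
      ext <- stats::rlnorm(total, ext_meanlog, ext_sdlog)
      tof <- ext * 0.45 * exp(stats::rnorm(total, 0, 0.1))
      green <- base_green_per_ext * ext * eff[idx] *
        2^(offset + well_noise[idx])
      pieces[[k]] <- data.frame(plate = pid, well = lay$well[idx],
                                tof = tof, ext = ext, green = green,
                                stringsAsFactors = FALSE)
      lays[[k]] <- lay
    }
  }
  records <- do.call(rbind, pieces)
  rownames(records) <- NULL
  layout <- do.call(rbind, lays)
  rownames(layout) <- NULL
  layout <- suppressWarnings(validate_layout(layout))
  truth <- list(clone_effects = full, noise_sd = noise_sd,
                worms_per_well = as.integer(worms_per_well),
                seed = as.integer(seed))
  structure(list(records = records, layout = layout, truth = truth),
            class = "copas_screen")
}

#' Simulate paralysis time-course counts
#'
#' Draws cumulative paralysis counts from a discrete-time survival process:
#' in each 10-minute scoring interval a still-moving worm paralyzes with
#' probability `hazard` (scalar, or one value per interval). Emulates the
#' aldicarb/levamisole assay structure in which 25--35 young adults are
#' scored for touch response every 10 minutes for 2 hours.
#'
#' @param hazard per-interval paralysis probability in \[0, 1\]; scalar or
#'   one value per timepoint.
#' @param n_worms worms per replicate plate.
#' @param timepoints_min scoring times in minutes.
#' @param n_replicates independent replicate plates.
#' @param strain,assay labels carried into the output.
#' @param seed integer seed.
#' @return data.frame with columns `assay`, `strain`, `replicate`,
#'   `time_min`, `n_total`, `n_paralyzed` (cumulative, nondecreasing).
#' @examples
#' simulate_paralysis(0.2, n_worms = 30, n_replicates = 2, seed = 1)[1:4, ]
#' @export
simulate_paralysis <- function(hazard, n_worms = 30L,
                               timepoints_min = seq(10L, 120L, by = 10L),
                               n_replicates = 3L, strain = "wt",
                               assay = c("aldicarb", "levamisole"),
                               seed = 1L) {
  assay <- match.arg(assay)
  n_t <- length(timepoints_min)
  if (length(hazard) == 1L) hazard <- rep(hazard, n_t)
  if (length(hazard) != n_t) {
    stop("`hazard` must be scalar or one value per timepoint", call. = FALSE)
  }
  if (any(hazard < 0 | hazard > 1)) {
    stop("`hazard` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_worms >= 1, n_replicates >= 1,
            !is.unsorted(timepoints_min, strictly = TRUE))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_replicates), function(rep_i) {
    # per worm, per interval: paralyzed by t_j iff any success up to j
    still <- rep(TRUE, n_worms)
    n_par <- integer(n_t)
    for (j in seq_len(n_t)) {
      hit <- still & (stats::runif(n_worms) < hazard[j])
      still[hit] <- FALSE
      n_par[j] <- n_worms - sum(still)
    }
    data.frame(assay = assay, strain = strain, replicate = rep_i,
               time_min = as.integer(timepoints_min),
               n_total = as.integer(n_worms), n_paralyzed = n_par,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate locomotion trajectories
#'
#' Draws signed per-frame velocities from a three-state
#' (forward/backward/immobile) Markov chain whose stationary distribution
#' equals the requested state fractions, with a tunable mean dwell time
#' controlling state persistence. Forward frames get velocity
#' `+|N(speed_mean, speed_sd)|`, backward frames the negative, immobile
#' frames 0.
#'
#' @param speed_mean,speed_sd moving-frame speed distribution (mm/s).
#' @param forward_fraction,immobile_fraction stationary fractions of time
#'   spent moving forward and immobile; backward takes the remainder.
#' @param duration_s track duration (seconds).
#' @param frame_rate frames per second (> 0).
#' @param dwell_s mean state dwell time in seconds (persistence of the
#'   chain); values at or below one frame give independent frames.
#' @param strain label carried into the output.
#' @param n_tracks number of worms to simulate.
#' @param seed integer seed.
#' @return data.frame with columns `strain`, `worm_id`, `time_s`,
#'   `velocity_mm_s`.
#' @export
simulate_tracks <- function(speed_mean = 0.15, speed_sd = 0.03,
                            forward_fraction = 0.7,
                            immobile_fraction = 0.05,
                            duration_s = 40, frame_rate = 20,
                            dwell_s = 0.5, strain = "wt",
                            n_tracks = 1L, seed = 1L) {
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  if (forward_fraction < 0 || forward_fraction > 1 ||
      immobile_fraction < 0 || immobile_fraction > 1 ||
      forward_fraction + immobile_fraction > 1) {
    stop("state fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  stopifnot(speed_mean >= 0, speed_sd >= 0, duration_s > 0, n_tracks >= 1)
  pi_s <- c(forward = forward_fraction,
            backward = 1 - forward_fraction - immobile_fraction,
            immobile = immobile_fraction)
  rho <- max(0, 1 - 1 / (dwell_s * frame_rate))
  n <- max(1L, floor(duration_s * frame_rate))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_tracks), function(w) {
    state <- integer(n)
    state[1L] <- sample.int(3L, 1L, prob = pi_s)
    if (n > 1L) {
      stay <- stats::runif(n - 1L) < rho
      fresh <- sample.int(3L, n - 1L, replace = TRUE, prob = pi_s)
      for (i in 2:n) state[i] <- if (stay[i - 1L]) state[i - 1L] else fresh[i - 1L]
    }
    speed <- abs(stats::rnorm(n, speed_mean, speed_sd))
    v <- ifelse(state == 1L, speed, ifelse(state == 2L, -speed, 0))
    data.frame(strain = strain, worm_id = w,
               time_s = (seq_len(n) - 1L) / frame_rate,
               velocity_mm_s = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
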