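test_that("control fold changes are measured against the empty-vector mean", {
  # up control planted at +log2(6), down at log2(0.5), empties at 0
  wells <- make_wells(median_rfs = seq(-1, 1, length.out = 11))
  ctrl <- check_controls(wells)
  expect_equal(ctrl$fold_up, 6)
  expect_equal(ctrl$fold_down, 0.5)
  expect_true(ctrl$controls_pass)
  # fold 0.4 passes the down criterion
  w2 <- make_wells(seq(-1, 1, length.out = 11), down_rfs = log2(0.4))
  expect_true(check_controls(w2)$controls_pass)
  # inverted up control (fold 1.0) fails
  w3 <- make_wells(seq(-1, 1, length.out = 11), up_rfs = 0)
  expect_false(check_controls(w3)$controls_pass)
  expect_equal(check_controls(w3)$fold_up, 1)
  # no empty-vector wells is a QC error
  w4 <- wells[wells$role != "empty_vector", ]
  expect_error(check_controls(w4), "empty-vector")
})

test_that("repeatability flags use a strict inequality and are monotone in the threshold", {
  clones <- data.frame(clone_id = c("a", "b", "c", "d"),
                       repeat_fold_change = c(1.5, 2.2, 1.49, NA),
                       low_repeatability = FALSE,
                       stringsAsFactors = FALSE)
  f15 <- flag_low_repeatability(clones, 1.5)
  expect_equal(f15$low_repeatability, c(FALSE, TRUE, FALSE, FALSE))
  f20 <- flag_low_repeatability(clones, 2.0)
  expect_equal(f20$low_repeatability, c(FALSE, TRUE, FALSE, FALSE))
  f22 <- flag_low_repeatability(clones, 2.2)
  expect_equal(f22$low_repeatability, c(FALSE, FALSE, FALSE, FALSE))
  # raising the threshold never flags more clones
  thresholds <- seq(1, 3, by = 0.1)
  counts <- vapply(thresholds, function(th) {
    sum(flag_low_repeatability(clones, th)$low_repeatability)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sterile flagging uses strictly-less-than the progeny fraction of the plate mean", {
  wells <- make_wells(median_rfs = seq(0, 1, length.out = 11), n_worms = 50L)
  # plate mean over experimental wells includes the candidate well:
  # 10 wells at 55 and one at 9 -> mean 50.8..., 20% = 10.16 > 9 -> flagged
  wells$n_worms[wells$role == "experimental"] <- c(9L, rep(55L, 10))
  fl <- flag_sterile(wells, fraction = 0.20)
  expect_equal(sum(fl$sterile), 1L)
  expect_equal(fl$clone_id[fl$sterile], "c00001")
  # exactly at the boundary: n = 0.2 * mean is NOT sterile
  w2 <- make_wells(seq(0, 1, length.out = 11), n_worms = 50L)
  w2$n_worms[w2$role == "experimental"] <- c(20L, rep(56L, 10))
  # mean = (20 + 560)/11 ... pick counts making the boundary exact:
  w2$n_worms[w2$role == "experimental"] <- c(10L, rep(49L, 10))
  m <- mean(w2$n_worms[w2$role == "experimental"])  # = 45.45..., 20% = 9.09
  expect_true(10 >= 0.2 * m)
  expect_equal(sum(flag_sterile(w2, 0.20)$sterile), 0L)
  # equal counts everywhere: nothing flagged; order invariance
  w3 <- make_wells(seq(0, 1, length.out = 11), n_worms = 40L)
  expect_equal(sum(flag_sterile(w3)$sterile), 0L)
  shuffle <- wells[rev(seq_len(nrow(wells))), ]
  expect_equal(sum(flag_sterile(shuffle)$sterile), 1L)
  # scaling all counts by a common factor preserves the decision
  w5 <- wells
  w5$n_worms <- w5$n_worms * 3L
  expect_equal(flag_sterile(w5)$sterile[order(w5$well)],
               fl$sterile[order(wells$well)])
})

test_that("sterile boundary uses an exactly-20% fixture", {
  # 4 experimental wells: counts 10, 10, 10, 10 -> mean 10; a well with
  # exactly 2 = 0.2 * 10 must NOT be flagged, 1 must be
  lay_rfs <- rep(0:3, length.out = 4)
  w <- make_wells(median_rfs = as.numeric(lay_rfs), n_worms = 10L)
  w <- w[w$role == "experimental" | w$role == "empty_vector", ]
  w$n_worms[w$clone_id == "c00001"] <- 2L
  w$n_worms[w$clone_id == "c00002"] <- 14L  # keep mean at 10: 2+14+10+14=40
  w$n_worms[w$clone_id == "c00004"] <- 14L
  m <- mean(w$n_worms[w$role == "experimental"])
  expect_equal(0.2 * m, 2)
  expect_equal(sum(flag_sterile(w, 0.20)$sterile), 0L)
  w$n_worms[w$clone_id == "c00001"] <- 1L
  w$n_worms[w$clone_id == "c00002"] <- 15L
  expect_equal(0.2 * mean(w$n_worms[w$role == "experimental"]), 2)
  expect_equal(sum(flag_sterile(w, 0.20)$sterile), 1L)
})

test_that("repeatability report gives r and the within-2-fold fraction", {
  sim <- simulate_screen(n_plates = 1, clones_per_plate = 20, noise_sd = 0,
                         hit_fraction = 0.1, seed = 3)
  wells <- suppressWarnings(normalize_plates(
    summarize_wells(sim$records, sim$layout), zero_mad = "center"))
  clones <- score_clones(wells)
  rep0 <- repeatability_report(clones)
  expect_equal(rep0$pearson_r, 1.0)
  expect_equal(rep0$fraction_within_fold2, 1.0)
  # a constant +1.5 log2 shift between repeats keeps r = 1 but breaks the
  # 2-fold band everywhere
  clones2 <- clones
  clones2$rfs <- lapply(clones2$rfs, function(v) v + c(0, 1.5))
  clones2$repeat_fold_change <- vapply(clones2$rfs, function(v) {
    2^abs(diff(v))
  }, numeric(1))
  rep2 <- repeatability_report(clones2)
  expect_equal(rep2$pearson_r, 1.0)
  expect_equal(rep2$fraction_within_fold2, 0.0)
  # brute-force recount on a noisy screen
  simn <- simulate_screen(n_plates = 2, noise_sd = 0.25, seed = 19)
  cn <- score_clones(normalize_plates(
    summarize_wells(simn$records, simn$layout)))
  repn <- repeatability_report(cn)
  direct <- mean(vapply(cn$rfs, function(v) abs(diff(v)) <= 1, logical(1)))
  expect_equal(repn$fraction_within_fold2, direct)
  # degenerate constant repeats: correlation undefined
  cflat <- clones
  cflat$rfs <- lapply(cflat$rfs, function(v) c(1, 1))
  expect_error(repeatability_report(cflat), "constant")
})

test_that("plate verdicts: pass on clean data, fail on inverted controls, redo on low repeatability", {
  sim <- simulate_screen(n_plates = 2, noise_sd = 0.1, seed = 61)
  wells <- normalize_plates(summarize_wells(sim$records, sim$layout))
  clones <- flag_low_repeatability(score_clones(wells), 1.5)
  qc <- plate_qc(wells, clones, screen_config())
  expect_true(all(qc$verdict == "pass"))
  # force an inverted up control on one plate
  w2 <- wells
  w2$median_rfs[w2$plate == "P01_R1" & w2$role == "up_control"] <-
    mean(w2$median_rfs[w2$plate == "P01_R1" & w2$role == "empty_vector"])
  qc2 <- plate_qc(w2, clones, screen_config())
  expect_equal(qc2$verdict[qc2$plate == "P01_R1"], "fail")
  # flag most clones: verdict redo
  clones3 <- clones
  clones3$low_repeatability <- TRUE
  qc3 <- plate_qc(wells, clones3, screen_config())
  expect_true(all(qc3$verdict == "redo"))
})

test_that("zero-noise screens pass QC with perfect repeatability", {
  sim <- simulate_screen(n_plates = 2, noise_sd = 0, hit_fraction = 0.05,
                         seed = 71)
  wells <- suppressWarnings(normalize_plates(
    summarize_wells(sim$records, sim$layout), zero_mad = "center"))
  wells <- flag_sterile(wells)
  clones <- flag_low_repeatability(score_clones(wells), 1.5)
  qc <- plate_qc(wells, clones, screen_config())
  expect_true(all(qc$verdict == "pass"))
  expect_equal(sum(clones$low_repeatability), 0L)
  rep0 <- repeatability_report(clones)
  expect_equal(rep0$pearson_r, 1.0)
  expect_equal(rep0$fraction_within_fold2, 1.0)
})
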