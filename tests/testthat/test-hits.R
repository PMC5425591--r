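make_scores <- function(mean_rz, clone_id = sprintf("c%05d", seq_along(mean_rz))) {
  data.frame(clone_id = clone_id, mean_rz = mean_rz,
             sterile = FALSE, missing_repeat = FALSE,
             low_repeatability = FALSE, stringsAsFactors = FALSE)
}

test_that("tail selection takes ceil(f/2 * N) per side with deterministic ties", {
  set.seed(23)
  sc <- make_scores(rnorm(1000))
  cand <- select_tail_candidates(sc, 0.05)
  expect_equal(sum(cand$direction == "up"), 25L)
  expect_equal(sum(cand$direction == "down"), 25L)
  # the up candidates are exactly the 25 largest scores
  expect_setequal(cand$clone_id[cand$direction == "up"],
                  sc$clone_id[order(-sc$mean_rz)][1:25])
  expect_setequal(cand$clone_id[cand$direction == "down"],
                  sc$clone_id[order(sc$mean_rz)][1:25])

  # zero-noise separation: planted ranks are recovered exactly
  sc2 <- make_scores(c(rep(5, 25), rep(0, 950), rep(-5, 25)))
  cand2 <- select_tail_candidates(sc2, 0.05)
  expect_setequal(cand2$clone_id[cand2$direction == "up"],
                  sc2$clone_id[1:25])
  expect_setequal(cand2$clone_id[cand2$direction == "down"],
                  sc2$clone_id[976:1000])

  # fully tied scores: deterministic by clone_id, with a warning, and no
  # clone in both tails
  sc3 <- make_scores(rep(0, 100))
  expect_warning(cand3 <- select_tail_candidates(sc3, 0.1), "degenerate")
  expect_warning(cand3b <- select_tail_candidates(sc3, 0.1), "degenerate")
  expect_identical(cand3, cand3b)
  expect_equal(anyDuplicated(cand3$clone_id), 0L)
  expect_equal(cand3$clone_id[cand3$direction == "up"], sc3$clone_id[1:5])

  # flagged clones are excluded before ranking when requested
  sc4 <- make_scores(c(10, 9, rnorm(98)))
  sc4$low_repeatability[1] <- TRUE
  cand4 <- select_tail_candidates(sc4, 0.04, exclude_flagged = TRUE)
  expect_false("c00001" %in% cand4$clone_id)
  expect_true("c00002" %in% cand4$clone_id)

  expect_error(select_tail_candidates(sc, 0), "tail_fraction")
  expect_error(select_tail_candidates(sc, 0.6), "tail_fraction")
})

test_that("tail monotonicity: smaller tail fractions never add candidates", {
  set.seed(29)
  sc <- make_scores(rnorm(400))
  fracs <- c(0.5, 0.3, 0.2, 0.1, 0.05, 0.02)
  sets <- lapply(fracs, function(f) select_tail_candidates(sc, f)$clone_id)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("the one-tailed validation t-test matches an independent Welch oracle", {
  # equal samples with spread: t = 0, one-tailed p = 0.5
  expect_equal(secondary_ttest(c(1, 2, 3), c(1, 2, 3), "up"), 0.5)
  # clear separation in the right direction
  x <- c(2.0, 2.1, 1.9, 2.0); y <- c(1.0, 1.1, 0.9, 1.0)
  p <- secondary_ttest(x, y, "up")
  expect_lt(p, 0.001)
  expect_equal(p, welch_p_oracle(x, y, "greater"), tolerance = 1e-12)
  expect_equal(secondary_ttest(x, y, "down"),
               welch_p_oracle(x, y, "less"), tolerance = 1e-12)
  # wrong-sided alternative gives p > 0.5
  expect_gt(secondary_ttest(y, x, "up"), 0.5)
  # random cases against the oracle, both directions and pooled variant
  set.seed(37)
  for (i in 1:50) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(secondary_ttest(a, b, "up"),
                 welch_p_oracle(a, b, "greater"), tolerance = 1e-10)
    expect_equal(secondary_ttest(a, b, "down", var_equal = TRUE),
                 t.test(a, b, alternative = "less", var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # degenerate zero-variance limits
  expect_equal(secondary_ttest(c(2, 2), c(1, 1), "up"), 0)
  expect_equal(secondary_ttest(c(2, 2), c(1, 1), "down"), 1)
  expect_equal(secondary_ttest(c(1, 1), c(1, 1), "up"), 0.5)
  expect_error(secondary_ttest(1, c(1, 2), "up"), "replicate")
})

test_that("the t-test is calibrated: null rejection rate 0.05 +/- 0.01", {
  set.seed(43)
  n_sim <- 2000
  rejected <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    p <- secondary_ttest(rnorm(4, 0, 0.25), rnorm(8, 0, 0.25),
                         if (i %% 2) "up" else "down")
    rejected[i] <- p < 0.05
  }
  expect_lt(abs(mean(rejected) - 0.05), 0.01)
})

test_that("counterscreen rules classify candidates as the design dictates", {
  hits <- data.frame(clone_id = c("a", "b", "c", "d"),
                     direction = "up", mean_rz = 3,
                     secondary_p = c(0.01, 0.01, 0.20, 0.01),
                     counterscreen_p = NA_real_, call = "candidate",
                     stringsAsFactors = FALSE)
  cp <- c(a = 0.40, b = 0.01, c = 0.40)  # d missing
  out <- apply_counterscreen(hits, cp, alpha = 0.05)
  expect_equal(out$call, c("validated", "excluded_counterscreen",
                           "rejected", "candidate"))
  # shrinking alpha never grows the validated set
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  sets <- lapply(alphas, function(a) {
    o <- apply_counterscreen(hits, cp, alpha = a)
    o$clone_id[o$call == "validated"]
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("the full screen validates planted truth exactly at zero noise", {
  sim <- simulate_screen(n_plates = 4, hit_fraction = 0.05, noise_sd = 0,
                         seed = 83)
  cfg <- screen_config(tail_fraction = 0.06, zero_mad = "center")
  fit0 <- suppressWarnings(sph_screen(sim, config = cfg))
  cand <- fit0$hits$clone_id
  sec <- simulate_validation(cand, effects = sim$truth$clone_effects,
                             noise_sd = 0, seed = 84)
  cs <- simulate_validation(cand, noise_sd = 0, seed = 85)
  fit <- suppressWarnings(sph_screen(sim, secondary = sec,
                                     counterscreen = cs, config = cfg))
  planted <- names(sim$truth$clone_effects)[sim$truth$clone_effects != 1]
  val <- fit$hits$clone_id[fit$hits$call == "validated"]
  expect_setequal(val, planted)
  expect_equal(fit$counts[["excluded_counterscreen"]], 0L)
  # determinism end to end
  fit2 <- suppressWarnings(sph_screen(sim, secondary = sec,
                                      counterscreen = cs, config = cfg))
  expect_identical(fit$hits, fit2$hits)
})

test_that("clones that perturb the counterscreen are excluded", {
  sim <- simulate_screen(n_plates = 4, hit_fraction = 0.05, noise_sd = 0,
                         seed = 91)
  cfg <- screen_config(tail_fraction = 0.06, zero_mad = "center")
  fit0 <- suppressWarnings(sph_screen(sim, config = cfg))
  cand <- fit0$hits$clone_id
  planted <- names(sim$truth$clone_effects)[sim$truth$clone_effects != 1]
  artifacts <- planted[1:3]
  sec <- simulate_validation(cand, effects = sim$truth$clone_effects,
                             noise_sd = 0, seed = 92)
  cs_eff <- setNames(rep(3, length(artifacts)), artifacts)
  cs <- simulate_validation(cand, effects = cs_eff, noise_sd = 0, seed = 93)
  fit <- suppressWarnings(sph_screen(sim, secondary = sec,
                                     counterscreen = cs, config = cfg))
  h <- fit$hits
  # up-direction artifacts brightened in the counterscreen are excluded
  up_art <- intersect(artifacts, h$clone_id[h$direction == "up"])
  expect_true(all(h$call[h$clone_id %in% up_art] == "excluded_counterscreen"))
  # remaining planted clones validate
  clean <- setdiff(planted, artifacts)
  expect_true(all(h$call[h$clone_id %in% clean] == "validated"))
})

test_that("hit records keep direction consistent with the sign of mean rZ", {
  sim <- simulate_screen(n_plates = 2, hit_fraction = 0.05, noise_sd = 0.2,
                         seed = 97)
  fit <- sph_screen(sim, config = screen_config(tail_fraction = 0.06))
  h <- fit$hits
  expect_true(all(h$mean_rz[h$direction == "up"] >
                    min(h$mean_rz[h$direction == "down"])))
  up_scores <- h$mean_rz[h$direction == "up"]
  down_scores <- h$mean_rz[h$direction == "down"]
  expect_true(min(up_scores) > max(down_scores))
})
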