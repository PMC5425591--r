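# Shared fixtures and independent oracles used across test files.

# Brute-force median/MAD robust Z, written independently of robust_z():
# sorts and indexes rather than calling median() so the two paths share
# no code beyond arithmetic.
rz_oracle <- function(x) {
  mid <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }
  m <- mid(x)
  d <- mid(abs(x - m))
  (x - m) / d
}

# One-tailed Welch p-value from first principles (statistic + tail
# probability), as an independent check on the t.test-based implementation.
welch_p_oracle <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  if (alternative == "greater") {
    pt(t_stat, df, lower.tail = FALSE)
  } else {
    pt(t_stat, df)
  }
}

# Minimal single-plate well-summary frame for unit tests that do not need
# the generator: one plate, the standard four controls, n experimental
# wells with given median RFS values.
make_wells <- function(median_rfs, plate = "P01_R1", repeat_index = 1L,
                       empty_rfs = c(0, 0), up_rfs = log2(6),
                       down_rfs = log2(0.5), n_worms = 50L) {
  n <- length(median_rfs)
  wells <- all_wells <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  ctrl_wells <- c("A1", "H12", "A12", "H1")
  exp_wells <- setdiff(all_wells, ctrl_wells)[seq_len(n)]
  df <- data.frame(
    plate = plate,
    well = c(exp_wells, ctrl_wells),
    clone_id = c(sprintf("c%05d", seq_len(n)), "L4440", "L4440",
                 "unc-11", "gfp"),
    role = c(rep("experimental", n), "empty_vector", "empty_vector",
             "up_control", "down_control"),
    repeat_index = repeat_index,
    n_worms = n_worms,
    median_rfs = c(median_rfs, empty_rfs, up_rfs, down_rfs),
    sterile = FALSE,
    rz = NA_real_,
    stringsAsFactors = FALSE
  )
  df
}

# Write a small COPAS TSV fixture and return its path.
write_copas_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "copas.tsv")
  writeLines(lines, path)
  path
}
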