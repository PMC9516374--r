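# Fixtures are built in code; nothing is stored on disk.

# small synthetic cohort via the package's own generator
toy_cohort <- function(n = 12, seed = 42) {
  generate_cohort(sim_params(n = n, seed = seed))$cohort
}

# fully hand-specified 3-patient cohort for arithmetic oracles
hand_cohort <- function() {
  df <- data.frame(
    patient_id = c("a", "b", "c"),
    age = c(50, 60, 70), insulin = c(0L, 1L, 0L),
    hba1c_t0 = c(8, 9, 10), hba1c_t6 = c(7, 9, 11), hba1c_t12 = c(7, 8, 10),
    eq5d_t0 = c(0.5, 0.8, 0.4), eq5d_t6 = c(0.6, 0.8, 0.5),
    eq5d_t12 = c(0.5, 0.9, 0.6),
    stringsAsFactors = FALSE)
  for (cl in rec_cols_all()) df[[cl]] <- c(1L, 2L, 0L)
  as_cohort(df)
}

rec_cols_all <- function() {
  c(paste0("s1_", rec_types()), paste0("s2_", rec_types()))
}

# set the 9 per-type counts of one stage for one row of a cohort data.frame
set_counts <- function(df, row, stage, counts) {
  stopifnot(length(counts) == 9)
  for (j in 1:9) df[row, paste0("s", stage, "_", rec_types()[j])] <- counts[j]
  df
}

# a discrete-state cohort whose Q-functions are exactly tabulated:
# one binary covariate, two realized focus categories, two intensity levels,
# deterministic outcomes keyed to (z, action, parity)
discrete_cohort <- function(n = 64) {
  z <- rep(c(0L, 1L), length.out = n)
  parity <- rep(c(0L, 1L), each = 2, length.out = n)
  df <- data.frame(patient_id = sprintf("d%03d", seq_len(n)), insulin = z,
                   stringsAsFactors = FALSE)
  # action pattern cycles over 4 (focus x intensity) combinations per stage
  pat <- (seq_len(n) - 1L) %% 4L
  counts_for <- function(k) {
    # k in 0:3 -> (behavior/case) x (low/high); dominance is unambiguous
    total <- if (k < 2L) 4L else 12L
    # place counts: behavior mass on diet, case mass on case_mgmt
    cnt <- integer(9)
    if (k %% 2L == 0L) cnt[1] <- total else cnt[8] <- total
    cnt
  }
  for (i in seq_len(n)) {
    df <- set_counts(df, i, 1, counts_for(pat[i]))
    df <- set_counts(df, i, 2, counts_for((pat[i] + z[i]) %% 4L))
  }
  df$hba1c_t0 <- 10
  df$eq5d_t0 <- 0.8
  # deterministic discrete outcomes: drop depends on z, stage-1 action, parity
  a1_high <- pat >= 2L
  a1_case <- pat %% 2L == 1L
  drop1 <- 0.10 + 0.04 * (a1_case == (z == 1L)) + 0.02 * a1_high +
    0.01 * parity
  df$hba1c_t6 <- df$hba1c_t0 * (1 - drop1)
  pat2 <- (pat + z) %% 4L
  a2_high <- pat2 >= 2L
  a2_case <- pat2 %% 2L == 1L
  drop2 <- 0.02 + 0.04 * (a2_case == (z == 1L)) + 0.02 * a2_high +
    0.01 * parity
  df$hba1c_t12 <- df$hba1c_t6 * (1 - drop2)
  df$eq5d_t6 <- 0.8
  df$eq5d_t12 <- 0.8
  as_cohort(df)
}

expect_same_actions <- function(a, b) {
  expect_equal(as.character(a$focus), as.character(b$focus))
  expect_equal(as.character(a$intensity), as.character(b$intensity))
}
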