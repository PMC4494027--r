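test_that("detrend + z-score: ramp annihilation, moments, orthogonality", {
  n <- 84
  set.seed(3)
  tc <- cbind(ramp = 5 + 0.3 * seq_len(n),          # pure linear ramp
              noise = rnorm(n),
              mix = 2 + 0.1 * seq_len(n) + rnorm(n))
  out <- detrend_standardize(tc)
  expect_true(all(out[, "ramp"] == 0))              # zero-variance contract
  for (j in c("noise", "mix")) {
    expect_lt(abs(mean(out[, j])), 1e-10)
    expect_equal(sd(out[, j]), 1, tolerance = 1e-10)
    expect_lt(abs(cor(out[, j], seq_len(n))), 1e-10)
  }
  expect_error(detrend_standardize(tc[1:2, ]), "3 volumes")
})

test_that("block extraction: lag window arithmetic and overrun error", {
  p <- design_params(blocks_per_cond = 1)
  ev <- build_session_timeline(p, seed = 1)        # blocks at 10 s and 27.5 s
  ex <- experimental_blocks(ev)
  nvol <- 18
  tc <- matrix(0, nvol, 1)
  # first block occupies volumes 5-8 (0-based 4-7); with lag 3 the window is
  # volumes 8-11 (1-based): put known values there
  v0 <- floor(ex$onset[1] / 2.5) + 1
  tc[(v0 + 3):(v0 + 6), 1] <- c(1, 2, 3, 4)
  bp <- extract_block_patterns(tc, ev, lag_trs = 3, tr_s = 2.5)
  expect_equal(bp$X[1, 1], 2.5)
  # lag 0 window sees an impulse at the onset volume; lag 3 does not
  tc2 <- matrix(0, nvol, 1); tc2[v0, 1] <- 8
  bp0 <- extract_block_patterns(tc2, ev, lag_trs = 0, tr_s = 2.5)
  bp3 <- extract_block_patterns(tc2, ev, lag_trs = 3, tr_s = 2.5)
  expect_equal(bp0$X[1, 1], 2)                     # 8 / 4 volumes
  expect_equal(bp3$X[1, 1], 0)
  # last block's shifted window overruns the session
  expect_error(extract_block_patterns(tc[1:14, , drop = FALSE], ev,
                                      lag_trs = 3, tr_s = 2.5), "overrun")
})

test_that("cocktail subtraction: arithmetic, shift invariance, leakage guard", {
  X <- rbind(c(1, 3), c(3, 5), c(10, 10), c(20, 20))
  bp <- block_patterns(X, c("A", "B", "A", "B"), c(1, 1, 2, 2),
                       rep("guessed", 4))
  # session 1 condition A: mean 2 -> [-1, 1]; wait: mean over block AND voxels
  out <- cocktail_subtract(bp)
  expect_equal(out$X[1, ], c(1, 3) - 2)
  expect_equal(out$X[2, ], c(3, 5) - 4)
  # worked example: two condition-A rows in one session
  bp2 <- block_patterns(rbind(c(1, 3), c(3, 5), c(0, 0), c(0, 0)),
                        c("A", "A", "B", "B"), c(1, 1, 1, 1),
                        rep("guessed", 4))
  out2 <- cocktail_subtract(bp2)
  expect_equal(out2$X[1:2, ], rbind(c(-2, 0), c(0, 2)))
  # per-session per-condition grand means are exactly 0
  for (s in unique(out2$session)) for (cn in unique(out2$condition)) {
    expect_lt(abs(mean(out2$X[out2$session == s & out2$condition == cn, ])),
              1e-10)
  }
  # adding a constant to one condition pre-subtraction changes nothing
  bp3 <- bp2; bp3$X[bp3$condition == "A", ] <- bp3$X[bp3$condition == "A", ] + 7
  expect_equal(cocktail_subtract(bp3)$X, out2$X)
  # conditions differing only by a global offset become identical
  base <- matrix(rnorm(8), 2, 4)
  bp4 <- block_patterns(rbind(base, base + 3), rep(c("A", "B"), each = 2),
                        rep(1, 4), rep("guessed", 4))
  out4 <- cocktail_subtract(bp4)
  expect_equal(out4$X[1:2, ], out4$X[3:4, ])
  # session lacking a condition errors
  bp5 <- block_patterns(X, c("A", "A", "A", "B"), c(1, 1, 2, 2),
                        rep("guessed", 4))
  expect_error(cocktail_subtract(bp5), "leakage")
})

test_that("guessed filtering keeps only subjectively invisible blocks", {
  bp <- block_patterns(matrix(1:12, 12, 1),
                       rep(c("A", "B"), 6), rep(1:2, each = 6),
                       c(rep("guessed", 10), "knew", "knew"))
  out <- filter_guessed(bp)
  expect_equal(nrow(out$X), 10L)
  expect_identical(filter_guessed(out)$X, out$X)   # all guessed -> identity
  bpk <- block_patterns(matrix(1:2, 2, 1), c("A", "B"), c(1, 1),
                        c("knew", "knew"))
  expect_error(filter_guessed(bpk), "guessed")
})

test_that("class balancing: counts, determinism, errors", {
  bp <- block_patterns(matrix(seq_len(18), 18, 1),
                       c(rep("A", 10), rep("B", 8)),
                       rep(1:2, 9), rep("guessed", 18))
  out <- balance_classes(bp, seed = 5)
  expect_equal(as.integer(table(out$condition)), c(8L, 8L))
  out2 <- balance_classes(bp, seed = 5)
  expect_identical(out$X, out2$X)                  # same seed, same discards
  # already balanced -> identity
  bpb <- bp_sub <- balance_classes(bp, seed = 5)
  expect_identical(balance_classes(bpb, seed = 9)$X, bpb$X)
  bp1 <- block_patterns(matrix(1:3, 3, 1), rep("A", 3), rep(1, 3),
                        rep("guessed", 3))
  expect_error(balance_classes(bp1), "both conditions")
})

test_that("preparation is leakage-free: held-out session does not affect others", {
  gd <- c(3, 3, 2)
  set.seed(21)
  amp <- list(sentences = array(rnorm(prod(gd), sd = 0.3), gd),
              nonwords = array(rnorm(prod(gd), sd = 0.3), gd))
  sig <- signal_spec(100, amp, c(sentences = 0, nonwords = 0))
  ses <- fixture_sessions(4, sig, gd, seed0 = 30)
  roi <- fixture_roi(gd)
  bp_full <- prepare_patterns(ses$runs, ses$events, roi, balance_seed = 1)
  # perturb session 4's data heavily and re-prepare
  ses2 <- ses
  ses2$runs[[4]]$data <- ses2$runs[[4]]$data * 3 + 17
  bp_pert <- prepare_patterns(ses2$runs, ses2$events, roi, balance_seed = 1)
  keep <- bp_full$session != 4
  expect_equal(bp_full$X[keep, ], bp_pert$X[bp_pert$session != 4, ])
})

test_that("patterns round-trip through the TSV sidecar representation", {
  bp <- fixture_patterns(2, 3, p = 4, delta = 0.5, seed = 2)
  dir <- tempfile("bp"); dir.create(dir); on.exit(unlink(dir, recursive = TRUE))
  write_table_tsv(cbind(as.data.frame(bp$X),
                        condition = bp$condition, session = bp$session,
                        subjective = bp$subjective),
                  file.path(dir, "patterns.tsv"))
  df <- read.table(file.path(dir, "patterns.tsv"), sep = "\t", header = TRUE)
  expect_equal(as.matrix(df[, 1:4]), bp$X, ignore_attr = TRUE)
  expect_equal(df$condition, bp$condition)
})
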