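test_that("zero signal, zero noise gives a constant-baseline run", {
  ev <- build_session_timeline(design_params(), seed = 1)
  sig <- signal_spec(baseline = 7, global_offset = c(sentences = 0,
                                                     nonwords = 0))
  run <- simulate_bold(ev, sig, noise_spec(white_sd = 0, drift_amp = 0),
                       c(3, 3, 2))
  expect_true(all(run$data == 7))
  expect_equal(n_volumes(run), 88L)
})

test_that("noiseless single-voxel run equals baseline + boxcar * HRF (oracle)", {
  p <- design_params()
  ev <- build_session_timeline(p, seed = 3)
  gd <- c(1, 1, 1)
  amp <- list(sentences = array(1, gd), nonwords = array(0, gd))
  sig <- signal_spec(baseline = 2, amplitude = amp,
                     global_offset = c(sentences = 0, nonwords = 0))
  run <- simulate_bold(ev, sig, noise_spec(white_sd = 0, drift_amp = 0), gd)
  # independent direct-convolution oracle
  nvol <- 88L
  tv <- (seq_len(nvol) - 1) * p$tr_s
  ex <- experimental_blocks(ev)
  box <- rep(0, nvol)
  for (i in which(ex$trial_type == "sentences")) {
    box[tv >= ex$onset[i] & tv < ex$onset[i] + ex$duration[i]] <- 1
  }
  k <- canonical_hrf(p$tr_s)
  expected <- 2 + vapply(seq_len(nvol), function(t)
    sum(box[seq_len(t)] * k[t - seq_len(t) + 1], na.rm = TRUE), numeric(1))
  expect_equal(as.numeric(run$data[1, 1, 1, ]), expected, tolerance = 1e-10)
})

test_that("same seed gives bit-identical runs; different seed differs", {
  ev <- build_session_timeline(design_params(), seed = 1)
  sig <- signal_spec(global_offset = c(sentences = 0, nonwords = 0))
  r1 <- simulate_bold(ev, sig, noise_spec(seed = 42), c(3, 2, 2))
  r2 <- simulate_bold(ev, sig, noise_spec(seed = 42), c(3, 2, 2))
  r3 <- simulate_bold(ev, sig, noise_spec(seed = 43), c(3, 2, 2))
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
})

test_that("grid/amplitude shape mismatch errors", {
  ev <- build_session_timeline(design_params(), seed = 1)
  amp <- list(sentences = array(1, c(2, 2, 2)), nonwords = array(0, c(2, 2, 2)))
  sig <- signal_spec(amplitude = amp,
                     global_offset = c(sentences = 0, nonwords = 0))
  expect_error(simulate_bold(ev, sig, noise_spec(), c(3, 3, 3)),
               "shape")
})

test_that("AR(1) noise matches its coefficient; mean converges to baseline", {
  # long synthetic run: one voxel, noise only
  p <- design_params(blocks_per_cond = 6)
  ev <- build_session_timeline(p, seed = 1)
  attr(ev, "n_volumes") <- 4000L                  # long noise-only timeline
  sig <- signal_spec(baseline = 10, global_offset = c(sentences = 0,
                                                      nonwords = 0))
  sig$amplitude <- list(sentences = array(0, c(1, 1, 1)),
                        nonwords = array(0, c(1, 1, 1)))
  run <- simulate_bold(ev, sig, noise_spec(white_sd = 1, ar1 = 0.3,
                                           drift_amp = 0, seed = 9),
                       c(1, 1, 1))
  x <- as.numeric(run$data[1, 1, 1, ])
  expect_lt(abs(mean(x) - 10), 3 * sd(x) / sqrt(length(x) * (1 - 0.3) / (1 + 0.3)))
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.3), 0.05)                  # Monte-Carlo tolerance
})

test_that("awareness labels follow the behavioral model probabilities", {
  # many blocks: proportions within 3 binomial SDs of the generators
  p <- design_params(blocks_per_cond = 6)
  evs <- lapply(1:70, function(s) build_session_timeline(p, seed = s,
                                                         session_id = s))
  ev <- do.call(rbind, evs)
  attr(ev, "tr_s") <- p$tr_s
  ev <- simulate_awareness(ev, awareness_model(seed = 11))
  ex <- experimental_blocks(ev)
  for (cn in c("sentences", "nonwords")) {
    pg <- c(sentences = 0.803, nonwords = 0.826)[[cn]]
    sub <- ex[ex$trial_type == cn, ]
    n <- nrow(sub)
    phat <- mean(sub$subjective == "guessed")
    expect_lt(abs(phat - pg), 3 * sqrt(pg * (1 - pg) / n))
    g <- sub[sub$subjective == "guessed", ]
    pc <- mean(g$objective_correct)
    expect_lt(abs(pc - 0.517), 3 * sqrt(0.517 * 0.483 / nrow(g)))
    k <- sub[sub$subjective == "knew", ]
    pk <- c(sentences = 0.624, nonwords = 0.865)[[cn]]
    # binomial test non-rejection at alpha = 0.01
    expect_gt(binom.test(sum(k$objective_correct), nrow(k), pk)$p.value, 0.01)
  }
  expect_true(all(simulate_awareness(
    ev, awareness_model(p_guessed = c(sentences = 1, nonwords = 1),
                        seed = 1))$subjective[ev$trial_type != "fixation"] ==
      "guessed"))
})

test_that("awareness model validates probabilities", {
  expect_error(awareness_model(p_guessed = c(sentences = 1.2, nonwords = 0.5)),
               "probabilities")
})

test_that("discard_initial_volumes shifts onsets and validates length", {
  p <- design_params()
  ev <- build_session_timeline(p, seed = 1)
  run <- simulate_bold(ev, signal_spec(global_offset = c(sentences = 0,
                                                         nonwords = 0)),
                       noise_spec(white_sd = 0, drift_amp = 0), c(2, 2, 1))
  de <- discard_initial_volumes(run, ev, 4)
  expect_equal(n_volumes(de$run), 84L)
  ex <- experimental_blocks(de$events)
  expect_equal(ex$onset[1], 0)
  expect_true(all(ex$onset >= 0))
  # n = 0 is the identity
  de0 <- discard_initial_volumes(run, ev, 0)
  expect_identical(de0$run$data, run$data)
  # too-short run errors
  short <- bold_run(run$data[, , , 1:3, drop = FALSE], run$tr_s)
  expect_error(discard_initial_volumes(short, ev, 4), "cannot discard")
})
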