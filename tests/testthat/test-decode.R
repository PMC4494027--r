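test_that("linearly separable clouds decode at 100%; errors on bad input", {
  bp <- fixture_patterns(4, 6, p = 5, delta = 8, seed = 1, sd = 0.5)
  res <- loso_decode(bp)
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$n_folds, 4L)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 100))
  # single session errors
  bp1 <- fixture_patterns(1, 6, p = 5, delta = 8)
  expect_error(loso_decode(bp1), ">= 2 sessions")
  # training fold missing a condition errors
  bp2 <- fixture_patterns(2, 4, p = 3, delta = 1)
  bp2$condition[bp2$session == 1] <- "sentences"
  expect_error(loso_decode(bp2), "lacks a condition")
})

test_that("label permutations center the accuracy on chance", {
  bp <- fixture_patterns(4, 6, p = 8, delta = 1.2, seed = 3, sd = 1)
  pn <- permutation_null(bp, n_perm = 200, seed = 9)
  se <- sd(pn$accuracies) / sqrt(length(pn$accuracies))
  expect_lt(abs(mean(pn$accuracies) - 50), 2 * se + 1e-9)
  expect_lt(pn$band[1], 50); expect_gt(pn$band[2], 50)
})

test_that("fold accuracies do not depend on session order", {
  bp <- fixture_patterns(5, 5, p = 6, delta = 0.8, seed = 4)
  res <- loso_decode(bp)
  perm <- c(3, 1, 5, 2, 4)
  idx <- order(match(bp$session, perm))
  bp2 <- block_patterns(bp$X[idx, ], bp$condition[idx], bp$session[idx],
                        bp$subjective[idx])
  res2 <- loso_decode(bp2)
  expect_equal(res2$fold_accuracy[names(res$fold_accuracy)],
               res$fold_accuracy)
})

test_that("decision-boundary ties resolve to the first condition label", {
  bp <- fixture_patterns(2, 3, p = 2, delta = 0, seed = 5)
  bp$X[] <- 0                                    # all-constant features
  res <- loso_decode(bp)
  # every prediction is the first label -> each balanced fold scores 50%
  expect_equal(res$mean_accuracy, 50)
})

test_that("signal monotonicity: accuracy is non-decreasing in pattern amplitude", {
  deltas <- c(0, 0.35, 1.2)
  mean_acc <- sapply(seq_along(deltas), function(i) {
    accs <- sapply(1:20, function(s)
      loso_decode(fixture_patterns(4, 6, p = 8, delta = deltas[i],
                                   seed = 100 * i + s))$mean_accuracy)
    mean(accs)
  })
  expect_true(all(diff(mean_acc) > 0))
  expect_lt(abs(mean_acc[1] - 50), 3)            # null is near chance
  expect_gt(mean_acc[3], 90)
})

test_that("univariate control dissociates pattern from global-level signal", {
  p <- design_params()
  gd <- c(4, 4, 2)
  nvox <- prod(gd)
  roi <- fixture_roi(gd)
  # (a) antisymmetric zero-sum pattern difference, no global offset
  set.seed(8)
  half <- rnorm(nvox / 2, sd = 0.6)
  patt <- c(half, -half)                         # sums to 0 across ROI
  amp <- list(sentences = array(patt, gd), nonwords = array(-patt, gd))
  sig <- signal_spec(100, amp, c(sentences = 0, nonwords = 0))
  ses <- fixture_sessions(6, sig, gd, seed0 = 60)
  bp <- prepare_patterns(ses$runs, ses$events, roi, balance_seed = 2)
  mv <- loso_decode(bp)
  uv <- univariate_decode(ses$runs, ses$events, roi, balance_seed = 2)
  null_band <- permutation_null(bp, n_perm = 120, seed = 3)$band
  expect_gt(mv$mean_accuracy, null_band[2])      # multivariate succeeds
  expect_lte(uv$mean_accuracy, null_band[2])     # univariate does not
  # (b) global offset only: univariate succeeds, cocktail-subtracted
  # multivariate returns to the chance band
  sig2 <- signal_spec(100, NULL, c(sentences = 1.5, nonwords = 0))
  ses2 <- fixture_sessions(6, sig2, gd, seed0 = 90)
  uv2 <- univariate_decode(ses2$runs, ses2$events, roi, balance_seed = 2)
  expect_gt(uv2$mean_accuracy, 90)
  bp2 <- prepare_patterns(ses2$runs, ses2$events, roi, balance_seed = 2)
  null2 <- permutation_null(bp2, n_perm = 120, seed = 4)$band
  mv2 <- loso_decode(bp2)
  expect_gte(mv2$mean_accuracy, null2[1])
  expect_lte(mv2$mean_accuracy, null2[2])
})

test_that("roi_size_sweep: nesting, single-size equivalence, propagation", {
  p <- design_params()
  gd <- c(6, 6, 3)
  set.seed(12)
  amp <- list(sentences = array(rnorm(prod(gd), 0.5, 0.2), gd),
              nonwords = array(rnorm(prod(gd), 0, 0.2), gd))
  sig <- signal_spec(100, amp, c(sentences = 0, nonwords = 0))
  ses <- fixture_sessions(3, sig, gd, seed0 = 200)
  zm <- fit_localizer(ses$runs, ses$events)
  mask <- array(TRUE, gd)
  sweep <- roi_size_sweep(zm, mask, ses$runs, ses$events,
                          sizes = c(10, 25, 40), balance_seed = 3)
  expect_length(sweep, 3L)
  expect_equal(vapply(sweep, `[[`, numeric(1), "roi_size"), c(10, 25, 40),
               ignore_attr = TRUE)
  # prefix nesting of the greedy ROIs across the sweep
  r10 <- grow_roi(zm, mask, 10); r25 <- grow_roi(zm, mask, 25)
  expect_identical(r25$voxels[1:10, ], r10$voxels)
  # single size matches a direct main-analysis run
  one <- roi_size_sweep(zm, mask, ses$runs, ses$events, sizes = 25,
                        balance_seed = 3)[[1]]
  direct <- loso_decode(prepare_patterns(ses$runs, ses$events, r25,
                                         balance_seed = 3), roi_size = 25)
  expect_equal(one$mean_accuracy, direct$mean_accuracy)
  # oversize request propagates the mask-deficit error
  small_mask <- array(FALSE, gd); small_mask[1:20] <- TRUE
  expect_error(roi_size_sweep(zm, small_mask, ses$runs, ses$events,
                              sizes = 30), "deficit|connected")
})

test_that("chance calibration: null subjects center on 50%", {
  accs <- sapply(1:40, function(s)
    loso_decode(fixture_patterns(6, 5, p = 10, delta = 0,
                                 seed = 9000 + s))$mean_accuracy)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 2 * se + 1e-9)
})
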