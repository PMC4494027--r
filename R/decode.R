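#' Fit a linear soft-margin classifier
#'
#' L2-regularized squared-hinge primal,
#' `0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b))^2`, minimized by BFGS
#' with the analytic gradient. Convex and deterministic; equivalent in
#' spirit to the classical linear SVM with soft margin, differing only in
#' the squaring of the hinge.
#'
#' @param X n x p feature matrix.
#' @param y labels; the first level of `factor(y)` (or of `levels` when
#'   given) is coded +1 and predicted on ties at the decision boundary.
#' @param C soft-margin regularization constant (default 1).
#' @param levels optional explicit label ordering.
#' @return object of class `linear_svm` with `w`, `b`, `levels`.
#' @export
linear_svm <- function(X, y, C = 1, levels = NULL) {
  X <- as.matrix(X)
  if (is.null(levels)) levels <- sort(unique(as.character(y)))
  if (length(levels) != 2L) stop("need exactly two classes")
  yy <- ifelse(as.character(y) == levels[1], 1, -1)
  if (length(unique(yy)) < 2L) stop("both classes must be present")
  p <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1]
    m <- 1 - yy * (drop(X %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1]
    m <- 1 - yy * (drop(X %*% w) + b)
    a <- pmax(m, 0) * yy
    c(w - 2 * C * drop(crossprod(X, a)), -2 * C * sum(a))
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  out <- list(w = fit$par[seq_len(p)], b = fit$par[p + 1], levels = levels,
              C = C, converged = fit$convergence == 0)
  class(out) <- "linear_svm"
  out
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  # ties at the boundary resolve toward the first label
  ifelse(f >= 0, object$levels[1], object$levels[2])
}

#' Leave-one-session-out decoding
#'
#' For each session, trains the linear classifier on all other sessions'
#' blocks and predicts the held-out session; fold accuracy is the percent
#' correct, and the subject-level accuracy is the unweighted mean over
#' folds.
#'
#' @param bp a [block_patterns()] (already prepared; see
#'   [prepare_patterns()]).
#' @param C classifier regularization constant.
#' @param kind analysis label stored in the result ("multivariate" or
#'   "univariate").
#' @param roi_size ROI size recorded in the result (defaults to the
#'   feature count).
#' @return object of class `decoding_result`: per-fold accuracies (%),
#'   fold count, mean accuracy (%), provenance fields.
#' @export
loso_decode <- function(bp, C = 1, kind = "multivariate",
                        roi_size = ncol(bp$X)) {
  stopifnot(inherits(bp, "block_patterns"))
  sessions <- sort(unique(bp$session))
  if (length(sessions) < 2L) stop("leave-one-session-out needs >= 2 sessions")
  levels <- sort(unique(bp$condition))
  acc <- numeric(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    tr <- bp$session != s
    if (length(unique(bp$condition[tr])) < 2L)
      stop(sprintf("training fold for session %s lacks a condition", s))
    fit <- linear_svm(bp$X[tr, , drop = FALSE], bp$condition[tr], C = C,
                      levels = levels)
    pred <- predict(fit, bp$X[!tr, , drop = FALSE])
    acc[i] <- 100 * mean(pred == bp$condition[!tr])
  }
  res <- list(fold_accuracy = stats::setNames(acc, sessions),
              n_folds = length(sessions),
              mean_accuracy = mean(acc),
              roi_name = bp$roi_name, roi_size = roi_size,
              kind = kind, C = C)
  class(res) <- "decoding_result"
  res
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s] %s (%d voxels): mean %.1f%% over %d folds\n",
              x$kind, x$roi_name, x$roi_size, x$mean_accuracy, x$n_folds))
  invisible(x)
}

#' Univariate (global-signal) control decoding
#'
#' Identical pipeline to the multivariate analysis except that (a) no
#' cocktail subtraction is applied and (b) the feature is the single
#' ROI-mean timecourse value per block, so classification can only use the
#' global signal level.
#'
#' @inheritParams prepare_patterns
#' @param C classifier regularization constant.
#' @return a `decoding_result` with `kind = "univariate"`.
#' @export
univariate_decode <- function(runs, events_list, roi, lag_trs = 3L,
                              discard_vols = 4L, balance_seed = 1L, C = 1) {
  stopifnot(length(runs) == length(events_list))
  parts <- vector("list", length(runs))
  for (s in seq_along(runs)) {
    de <- discard_initial_volumes(runs[[s]], events_list[[s]], discard_vols)
    d <- dim(de$run$data)
    tc <- t(matrix(de$run$data, nrow = prod(d[1:3]), ncol = d[4]))
    tc <- tc[, roi_linear_index(roi), drop = FALSE]
    tc <- detrend_standardize(tc)
    tc <- matrix(rowMeans(tc), ncol = 1)       # one dimension: ROI mean
    parts[[s]] <- extract_block_patterns(tc, de$events, roi = NULL,
                                         lag_trs = lag_trs,
                                         tr_s = de$run$tr_s)
  }
  bp <- block_patterns(do.call(rbind, lapply(parts, `[[`, "X")),
                       unlist(lapply(parts, `[[`, "condition")),
                       unlist(lapply(parts, `[[`, "session")),
                       unlist(lapply(parts, `[[`, "subjective")),
                       roi_name = roi$name, lag_trs = lag_trs)
  bp <- filter_guessed(bp)
  bp <- balance_classes(bp, seed = balance_seed)
  loso_decode(bp, C = C, kind = "univariate", roi_size = roi$size)
}

#' Repeat the multivariate analysis over a range of ROI sizes
#'
#' Grows one ROI per requested size on the same z-map/mask (the greedy
#' growth is prefix-nested across sizes) and runs the full multivariate
#' preparation and decoding at each size with identical settings.
#'
#' @param zm a [zmap()].
#' @param mask logical 3D mask.
#' @param runs,events_list main-experiment sessions.
#' @param sizes ROI sizes in voxels.
#' @param connectivity passed to [grow_roi()].
#' @param name ROI name.
#' @param ... further arguments to [prepare_patterns()] / [loso_decode()]
#'   (`lag_trs`, `discard_vols`, `balance_seed`, `C`).
#' @param C classifier regularization constant.
#' @return list of `decoding_result`, one per size.
#' @export
roi_size_sweep <- function(zm, mask, runs, events_list,
                           sizes = c(50, 100, 150), connectivity = 26,
                           name = "roi", C = 1, ...) {
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    r <- grow_roi(zm, mask, sizes[i], connectivity = connectivity,
                  name = name)
    bp <- prepare_patterns(runs, events_list, r, ...)
    out[[i]] <- loso_decode(bp, C = C, roi_size = r$size)
  }
  names(out) <- paste0("size", sizes)
  out
}

#' Permutation null band for LOSO decoding accuracy
#'
#' Permutes condition labels within sessions and re-runs the full LOSO
#' decode, returning the permutation distribution of mean accuracies and
#' its central 95% interval.
#'
#' @param bp a prepared [block_patterns()].
#' @param n_perm number of permutations.
#' @param C classifier regularization constant.
#' @param seed RNG seed.
#' @return list with `accuracies`, `band` (2.5% and 97.5% quantiles).
#' @export
permutation_null <- function(bp, n_perm = 200, C = 1, seed = 1L) {
  stopifnot(inherits(bp, "block_patterns"))
  accs <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      bp2 <- bp
      for (s in unique(bp$session)) {
        idx <- which(bp$session == s)
        bp2$condition[idx] <- bp$condition[sample(idx)]
      }
      ok <- tryCatch(loso_decode(bp2, C = C)$mean_accuracy,
                     error = function(e) NA_real_)
      ok
    }, numeric(1))
  })
  accs <- accs[is.finite(accs)]
  list(accuracies = accs,
       band = stats::quantile(accs, c(0.025, 0.975), names = FALSE))
}
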