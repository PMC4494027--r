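#' Detrend and z-score voxel timecourses
#'
#' Per voxel (column) within one session: remove the least-squares linear
#' trend, then center to mean 0 and scale to unit standard deviation.
#' Zero-variance voxels map to all-zeros rather than NaN so downstream
#' stages never see degenerate columns.
#'
#' @param tc volumes x voxels numeric matrix (one session).
#' @return matrix of the same shape.
#' @export
detrend_standardize <- function(tc) {
  tc <- as.matrix(tc)
  n <- nrow(tc)
  if (n < 3) stop("need at least 3 volumes per session")
  t0 <- seq_len(n) - (n + 1) / 2                 # centered time index
  slope <- crossprod(t0, tc) / sum(t0^2)          # 1 x nvox
  res <- tc - outer(t0, drop(slope)) -
    matrix(colMeans(tc), n, ncol(tc), byrow = TRUE)
  sdv <- sqrt(colSums(res^2) / (n - 1))
  # degenerate = residual variation at numerical-noise level relative to the
  # original timecourse (covers exact constants and pure linear ramps)
  ref <- pmax(apply(tc, 2, stats::sd), 1)
  degen <- sdv <= 1e-8 * ref
  res <- sweep(res, 2, ifelse(degen, 1, sdv), "/")
  res[, degen] <- 0
  res
}

#' Block-pattern container
#'
#' @param X blocks x features numeric matrix.
#' @param condition per-block condition labels.
#' @param session per-block session ids.
#' @param subjective per-block subjective awareness labels.
#' @param roi_name provenance: ROI name.
#' @param lag_trs provenance: hemodynamic lag applied, in TRs.
#' @return object of class `block_patterns`.
#' @export
block_patterns <- function(X, condition, session, subjective,
                           roi_name = "roi", lag_trs = 3L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(condition), nrow(X) == length(session),
            nrow(X) == length(subjective))
  bp <- list(X = X, condition = as.character(condition),
             session = as.integer(session),
             subjective = as.character(subjective),
             roi_name = roi_name, lag_trs = as.integer(lag_trs))
  class(bp) <- "block_patterns"
  bp
}

#' @export
print.block_patterns <- function(x, ...) {
  cat(sprintf("block_patterns: %d blocks x %d features (%s), %d sessions | %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", "),
              length(unique(x$session)), x$roi_name))
  invisible(x)
}

# subset rows of a block_patterns, keeping metadata aligned
bp_subset <- function(bp, idx) {
  block_patterns(bp$X[idx, , drop = FALSE], bp$condition[idx],
                 bp$session[idx], bp$subjective[idx], bp$roi_name, bp$lag_trs)
}

#' Extract per-block patterns with hemodynamic lag
#'
#' For each experimental block the analysis window is the block's volumes
#' shifted forward by `lag_trs` volumes; feature values are the mean over
#' that window of each ROI voxel's (already normalized) timecourse,
#' yielding one row per block.
#'
#' @param tc volumes x voxels matrix for one session (ROI columns, or the
#'   full grid with `roi` giving column indices).
#' @param events event table for the session (onsets on the same clock as
#'   row 1 of `tc`).
#' @param roi optional `roi` object or integer column indices selecting the
#'   features; default all columns.
#' @param lag_trs lag in volumes (default 3).
#' @param tr_s repetition time; defaults to the event table's attribute.
#' @return a [block_patterns()] for this session.
#' @export
extract_block_patterns <- function(tc, events, roi = NULL, lag_trs = 3L,
                                   tr_s = attr(events, "tr_s")) {
  tc <- as.matrix(tc)
  if (!is.null(roi)) {
    cols <- if (inherits(roi, "roi")) roi_linear_index(roi) else as.integer(roi)
    tc <- tc[, cols, drop = FALSE]
  }
  ex <- experimental_blocks(events)
  if (nrow(ex) == 0L) stop("no experimental blocks")
  nvol <- nrow(tc)
  rows <- matrix(0, nrow(ex), ncol(tc))
  for (i in seq_len(nrow(ex))) {
    v0 <- floor(ex$onset[i] / tr_s + 1e-9) + 1L          # 1-based first volume
    nb <- as.integer(round(ex$duration[i] / tr_s))
    win <- (v0 + lag_trs):(v0 + lag_trs + nb - 1L)
    if (max(win) > nvol)
      stop(sprintf("block %s (onset %.1f s) window overruns the session end",
                   ex$block[i], ex$onset[i]))
    rows[i, ] <- colMeans(tc[win, , drop = FALSE])
  }
  block_patterns(rows, ex$trial_type, ex$session, ex$subjective,
                 roi_name = if (inherits(roi, "roi")) roi$name else "all",
                 lag_trs = lag_trs)
}

#' Per-session per-condition global-signal ("cocktail") subtraction
#'
#' For each session and condition, subtracts the scalar grand mean over all
#' of that condition's blocks and all features, so classification cannot
#' exploit condition-wise global activation differences. An alternative
#' per-voxel reading (subtracting the condition's mean pattern) is
#' available via `per_voxel = TRUE`.
#'
#' @param bp a [block_patterns()].
#' @param per_voxel subtract the per-feature condition mean instead of the
#'   scalar grand mean.
#' @return a [block_patterns()] with per-session per-condition (grand)
#'   means of exactly 0.
#' @export
cocktail_subtract <- function(bp, per_voxel = FALSE) {
  stopifnot(inherits(bp, "block_patterns"))
  conds <- unique(bp$condition)
  X <- bp$X
  for (s in unique(bp$session)) {
    present <- unique(bp$condition[bp$session == s])
    if (length(setdiff(conds, present)) > 0)
      stop(sprintf("session %s lacks condition '%s'; refusing (leakage guard)",
                   s, setdiff(conds, present)[1]))
    for (cn in conds) {
      idx <- bp$session == s & bp$condition == cn
      if (per_voxel) {
        X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                          colMeans(X[idx, , drop = FALSE]))
      } else {
        X[idx, ] <- X[idx, , drop = FALSE] - mean(X[idx, , drop = FALSE])
      }
    }
  }
  block_patterns(X, bp$condition, bp$session, bp$subjective,
                 bp$roi_name, bp$lag_trs)
}

#' Keep only subjectively invisible ("guessed") blocks
#'
#' @param bp a [block_patterns()].
#' @return a [block_patterns()] with non-"guessed" rows removed.
#' @export
filter_guessed <- function(bp) {
  stopifnot(inherits(bp, "block_patterns"))
  keep <- bp$subjective == "guessed"
  if (!any(keep)) stop("no 'guessed' blocks remain after filtering")
  bp_subset(bp, keep)
}

#' Balance class counts by random down-sampling
#'
#' Randomly discards blocks from the larger condition (uniformly, without
#' replacement, seeded) so both conditions contribute equally many blocks.
#' Performed once per subject before cross-validation.
#'
#' @param bp a [block_patterns()].
#' @param seed integer seed for the discard draw.
#' @return a balanced [block_patterns()].
#' @export
balance_classes <- function(bp, seed = 1L) {
  stopifnot(inherits(bp, "block_patterns"))
  tab <- table(bp$condition)
  if (length(tab) < 2L || any(tab == 0))
    stop("both conditions must be present to balance")
  k <- min(tab)
  keep <- logical(nrow(bp$X))
  withr_seed(seed, {
    for (cn in names(tab)) {
      idx <- which(bp$condition == cn)
      keep[if (length(idx) > k) sort(sample(idx, k)) else idx] <- TRUE
    }
  })
  bp_subset(bp, keep)
}

#' Prepare classifier-ready patterns for one subject
#'
#' Runs the fixed preparation chain over the subject's main-experiment
#' sessions: discard initial volumes, detrend + z-score per session,
#' lag-shifted block extraction on the ROI, "guessed" filtering, class
#' balancing, and per-session per-condition cocktail subtraction.
#'
#' @param runs list of [bold_run()]s (main-experiment sessions).
#' @param events_list list of matching event tables (with awareness labels).
#' @param roi an `roi` object.
#' @param lag_trs hemodynamic lag in volumes.
#' @param discard_vols initial volumes to discard per session.
#' @param balance_seed seed for class balancing.
#' @param cocktail apply cocktail subtraction (TRUE for the multivariate
#'   analysis; FALSE reproduces the univariate control's input).
#' @param per_voxel passed to [cocktail_subtract()].
#' @return a [block_patterns()] spanning all sessions.
#' @export
prepare_patterns <- function(runs, events_list, roi, lag_trs = 3L,
                             discard_vols = 4L, balance_seed = 1L,
                             cocktail = TRUE, per_voxel = FALSE) {
  stopifnot(length(runs) == length(events_list))
  parts <- vector("list", length(runs))
  for (s in seq_along(runs)) {
    de <- discard_initial_volumes(runs[[s]], events_list[[s]], discard_vols)
    d <- dim(de$run$data)
    tc <- t(matrix(de$run$data, nrow = prod(d[1:3]), ncol = d[4]))
    tc <- tc[, roi_linear_index(roi), drop = FALSE]
    tc <- detrend_standardize(tc)
    parts[[s]] <- extract_block_patterns(tc, de$events, roi = NULL,
                                         lag_trs = lag_trs,
                                         tr_s = de$run$tr_s)
    parts[[s]]$roi_name <- roi$name
  }
  bp <- block_patterns(do.call(rbind, lapply(parts, `[[`, "X")),
                       unlist(lapply(parts, `[[`, "condition")),
                       unlist(lapply(parts, `[[`, "session")),
                       unlist(lapply(parts, `[[`, "subjective")),
                       roi_name = roi$name, lag_trs = lag_trs)
  bp <- filter_guessed(bp)
  bp <- balance_classes(bp, seed = balance_seed)
  if (cocktail) bp <- cocktail_subtract(bp, per_voxel = per_voxel)
  bp
}
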