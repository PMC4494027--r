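#' Experimental design parameters
#'
#' Bundle and validate the timing parameters of a block-design session:
#' experimental blocks of `block_s` seconds interleaved with `fix_s` fixation,
#' a leading fixation of `initial_fix_s`, and `blocks_per_cond` blocks of each
#' of two conditions per session. Defaults describe a 220 s session sampled at
#' TR = 2.5 s (88 volumes): 12 blocks of 10 s each, 7.5 s fixation between
#' blocks, 10 s initial fixation.
#'
#' @param tr_s repetition time, seconds per volume.
#' @param block_s duration of one experimental block in seconds.
#' @param fix_s duration of the fixation interval that follows each block.
#' @param initial_fix_s leading fixation before the first block.
#' @param blocks_per_cond number of blocks per condition per session.
#' @param word_s duration of a single word within a block (metadata only).
#' @param words_per_sentence words per sentence (metadata only).
#' @param sentences_per_block sentences per block (metadata only).
#' @param conditions ordered pair of condition labels; the first label is the
#'   "positive" class throughout (contrasts, classifier tie-breaking).
#' @return an object of class `design_params`.
#' @export
#' @examples
#' p <- design_params()
#' session_duration_s(p)   # 220
#' session_n_volumes(p)    # 88
design_params <- function(tr_s = 2.5, block_s = 10, fix_s = 7.5,
                          initial_fix_s = 10, blocks_per_cond = 6,
                          word_s = 0.4, words_per_sentence = 6,
                          sentences_per_block = 4,
                          conditions = c("sentences", "nonwords")) {
  stopifnot(is.numeric(tr_s), length(tr_s) == 1L)
  if (tr_s <= 0) stop("tr_s must be > 0")
  for (nm in c("block_s", "fix_s", "initial_fix_s", "word_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("%s must be a positive scalar", nm))
  }
  if (blocks_per_cond < 1) stop("blocks_per_cond must be >= 1")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("conditions must be two distinct labels")
  if (words_per_sentence * word_s * sentences_per_block > block_s + 1e-9)
    stop("word micro-structure does not fit inside block_s")
  p <- list(tr_s = tr_s, block_s = block_s, fix_s = fix_s,
            initial_fix_s = initial_fix_s, blocks_per_cond = blocks_per_cond,
            word_s = word_s, words_per_sentence = words_per_sentence,
            sentences_per_block = sentences_per_block,
            conditions = as.character(conditions))
  class(p) <- "design_params"
  # total duration must tile the volume grid exactly
  tot <- session_duration_s(p)
  if (abs(tot / tr_s - round(tot / tr_s)) > 1e-9)
    stop(sprintf("session duration %.3f s is not an integer number of TRs (%.3f s)",
                 tot, tr_s))
  p
}

#' @export
print.design_params <- function(x, ...) {
  cat(sprintf(
    "design_params: TR %.3g s | block %.3g s + fix %.3g s | %d+%d blocks | %g s, %d volumes\n",
    x$tr_s, x$block_s, x$fix_s, x$blocks_per_cond, x$blocks_per_cond,
    session_duration_s(x), session_n_volumes(x)))
  invisible(x)
}

#' Total session duration in seconds
#' @param params a `design_params` object.
#' @export
session_duration_s <- function(params) {
  n_blocks <- 2L * params$blocks_per_cond
  params$initial_fix_s + n_blocks * (params$block_s + params$fix_s)
}

#' Number of volumes in one session
#' @param params a `design_params` object.
#' @export
session_n_volumes <- function(params) {
  as.integer(round(session_duration_s(params) / params$tr_s))
}

#' Build the event timeline of one session
#'
#' Lays out a session as initial fixation, then alternating (block, fixation)
#' pairs. Condition order is a seeded uniform permutation of
#' `blocks_per_cond` repeats of each label. Awareness columns are initialized
#' to "none"/NA; see [simulate_awareness()].
#'
#' @param params a [design_params()] object.
#' @param seed integer seed fixing the condition permutation.
#' @param session_id integer session identifier stored in each row.
#' @return a data.frame event table with columns `session`, `block`,
#'   `onset` (s from session start), `duration` (s), `trial_type`
#'   (a condition label, or "fixation"), `subjective`
#'   (one of "knew"/"guessed"/"none") and `objective_correct` (logical, NA
#'   when not applicable).
#' @export
build_session_timeline <- function(params, seed = 1L, session_id = 1L) {
  stopifnot(inherits(params, "design_params"))
  if (params$blocks_per_cond < 1) stop("blocks_per_cond must be >= 1")
  n_blocks <- 2L * params$blocks_per_cond
  labels <- rep(params$conditions, each = params$blocks_per_cond)
  order <- withr_seed(seed, sample.int(n_blocks))
  labels <- labels[order]

  onset <- numeric(0); duration <- numeric(0); type <- character(0)
  block_id <- integer(0)
  # leading fixation
  onset <- c(onset, 0); duration <- c(duration, params$initial_fix_s)
  type <- c(type, "fixation"); block_id <- c(block_id, NA_integer_)
  t <- params$initial_fix_s
  for (b in seq_len(n_blocks)) {
    onset <- c(onset, t); duration <- c(duration, params$block_s)
    type <- c(type, labels[b]); block_id <- c(block_id, b)
    t <- t + params$block_s
    onset <- c(onset, t); duration <- c(duration, params$fix_s)
    type <- c(type, "fixation"); block_id <- c(block_id, NA_integer_)
    t <- t + params$fix_s
  }
  ev <- data.frame(
    session = as.integer(session_id),
    block = block_id,
    onset = onset,
    duration = duration,
    trial_type = type,
    subjective = "none",
    objective_correct = NA,
    stringsAsFactors = FALSE)
  ev$objective_correct <- as.logical(ev$objective_correct)
  attr(ev, "tr_s") <- params$tr_s
  attr(ev, "n_volumes") <- session_n_volumes(params)
  attr(ev, "conditions") <- params$conditions
  ev
}

# run `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experimental (non-fixation) rows of an event table
#' @param events an event table.
#' @export
experimental_blocks <- function(events) {
  events[events$trial_type != "fixation", , drop = FALSE]
}
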