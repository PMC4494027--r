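#' Signal specification for the BOLD forward model
#'
#' Separates the two components the downstream analyses dissociate: a
#' per-voxel, per-condition amplitude map (the multivoxel "pattern"
#' component) and a per-condition scalar offset applied to every voxel (the
#' univariate "global level" component). In visible-localizer mode the whole
#' signal is multiplied by `localizer_gain`.
#'
#' @param baseline scalar baseline BOLD level (arbitrary units).
#' @param amplitude named list (one entry per condition) of 3D arrays with
#'   the per-voxel pattern amplitudes, or NULL for no pattern component.
#' @param global_offset named numeric, scalar offset per condition.
#' @param localizer_gain multiplier applied when simulating visible
#'   localizer sessions.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(baseline = 100,
                        amplitude = NULL,
                        global_offset = c(sentences = 0, nonwords = 0),
                        localizer_gain = 3) {
  s <- list(baseline = baseline, amplitude = amplitude,
            global_offset = global_offset, localizer_gain = localizer_gain)
  class(s) <- "signal_spec"
  s
}

#' Noise specification for the BOLD forward model
#'
#' White Gaussian noise passed through an AR(1) filter, plus a slow
#' sinusoidal scanner drift shared by all voxels. The seed fixes the run
#' bit-for-bit.
#'
#' @param white_sd innovation standard deviation.
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift_amp amplitude of the sinusoidal drift.
#' @param drift_period_s drift period in seconds.
#' @param seed integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 1, ar1 = 0.3, drift_amp = 0.5,
                       drift_period_s = 128, seed = 1L) {
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  if (white_sd < 0) stop("white_sd must be >= 0")
  n <- list(white_sd = white_sd, ar1 = ar1, drift_amp = drift_amp,
            drift_period_s = drift_period_s, seed = as.integer(seed))
  class(n) <- "noise_spec"
  n
}

#' Behavioral awareness model
#'
#' Per-block awareness reports: the subjective report is "guessed" with
#' probability `p_guessed[condition]` (otherwise "knew"), and the objective
#' forced-choice response is correct with the conditional probability
#' matching the subjective state. Defaults reproduce the behavioral
#' structure the analysis assumes: ~80% of blocks subjectively invisible,
#' with objective accuracy at chance (51.7%) on those blocks and well above
#' chance on "knew" blocks.
#'
#' @param p_guessed named per-condition probability of a "guessed" report.
#' @param p_correct_given_guessed probability the objective response is
#'   correct on a guessed block (shared between conditions).
#' @param p_correct_given_knew named per-condition probability of a correct
#'   objective response on a "knew" block.
#' @param seed integer RNG seed.
#' @return object of class `awareness_model`.
#' @export
awareness_model <- function(p_guessed = c(sentences = 0.803, nonwords = 0.826),
                            p_correct_given_guessed = 0.517,
                            p_correct_given_knew = c(sentences = 0.624,
                                                     nonwords = 0.865),
                            seed = 1L) {
  probs <- c(p_guessed, p_correct_given_guessed, p_correct_given_knew)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  m <- list(p_guessed = p_guessed,
            p_correct_given_guessed = p_correct_given_guessed,
            p_correct_given_knew = p_correct_given_knew,
            seed = as.integer(seed))
  class(m) <- "awareness_model"
  m
}

#' Construct a BOLD run container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param origin_mm world coordinate of voxel (1,1,1).
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, voxel_size_mm = c(2, 2, 3),
                     origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 4L)
  if (!all(is.finite(data))) stop("bold_run values must be finite")
  r <- list(data = data, tr_s = tr_s,
            voxel_size_mm = as.numeric(voxel_size_mm),
            origin_mm = as.numeric(origin_mm))
  class(r) <- "bold_run"
  r
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %d x %d x %d voxels x %d volumes, TR %.3g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Number of volumes in a run
#' @param run a `bold_run`.
#' @export
n_volumes <- function(run) dim(run$data)[4]

#' Simulate a block-design BOLD run
#'
#' Forward model: each voxel's timecourse is
#' `baseline + sum_conditions (pattern amplitude + global offset) *
#' (condition boxcar convolved with the canonical HRF) + drift +
#' AR(1)-filtered white noise`. Word/sentence micro-structure is not
#' modelled: the neural regressor is the block boxcar.
#'
#' @param events event table from [build_session_timeline()].
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param grid_dim length-3 spatial grid dimensions.
#' @param tr_s repetition time; defaults to the event table's `tr_s`
#'   attribute.
#' @param localizer logical; multiply signal amplitudes by
#'   `signal$localizer_gain`.
#' @param voxel_size_mm voxel size passed through to the run.
#' @return a [bold_run()].
#' @export
simulate_bold <- function(events, signal, noise, grid_dim,
                          tr_s = attr(events, "tr_s"),
                          localizer = FALSE,
                          voxel_size_mm = c(2, 2, 3)) {
  stopifnot(inherits(signal, "signal_spec"), inherits(noise, "noise_spec"))
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L) stop("grid_dim must have length 3")
  nvox <- prod(grid_dim)
  nvol <- attr(events, "n_volumes")
  if (is.null(nvol)) {
    tot <- max(events$onset + events$duration)
    nvol <- as.integer(round(tot / tr_s))
  }
  conds <- setdiff(unique(events$trial_type), "fixation")
  B <- condition_boxcars(events, nvol, tr_s, conds)
  R <- apply(B, 2, convolve_hrf, tr_s = tr_s)           # nvol x ncond
  gain <- if (localizer) signal$localizer_gain else 1

  # amplitude matrix: nvox x ncond (pattern map + scalar global offset)
  A <- matrix(0, nrow = nvox, ncol = length(conds))
  for (j in seq_along(conds)) {
    amp <- 0
    if (!is.null(signal$amplitude) && !is.null(signal$amplitude[[conds[j]]])) {
      m <- signal$amplitude[[conds[j]]]
      if (!identical(as.integer(dim(m)), grid_dim))
        stop("amplitude map shape does not match grid_dim")
      amp <- as.vector(m)
    }
    off <- signal$global_offset[[conds[j]]]
    if (is.null(off)) off <- 0
    A[, j] <- gain * (amp + off)
  }

  Y <- tcrossprod(R, A)                                  # nvol x nvox
  Y <- Y + signal$baseline
  tsec <- (seq_len(nvol) - 1) * tr_s
  if (noise$drift_amp != 0)
    Y <- Y + noise$drift_amp * sin(2 * pi * tsec / noise$drift_period_s)
  if (noise$white_sd > 0) {
    E <- withr_seed(noise$seed, {
      W <- matrix(stats::rnorm(nvol * nvox, sd = noise$white_sd), nvol, nvox)
      if (noise$ar1 > 0)
        apply(W, 2, function(w)
          as.numeric(stats::filter(w, noise$ar1, method = "recursive")))
      else W
    })
    Y <- Y + E
  }
  bold_run(array(t(Y), dim = c(grid_dim, nvol)), tr_s = tr_s,
           voxel_size_mm = voxel_size_mm)
}

#' Assign awareness reports to experimental blocks
#'
#' Each experimental block independently receives a subjective label
#' ("guessed" with probability `p_guessed[condition]`, else "knew") and then
#' an objective correctness draw from the matching conditional probability.
#'
#' @param events event table with unlabeled experimental blocks.
#' @param model an [awareness_model()].
#' @return the event table with `subjective` and `objective_correct` filled
#'   in on experimental rows.
#' @export
simulate_awareness <- function(events, model) {
  stopifnot(inherits(model, "awareness_model"))
  idx <- which(events$trial_type != "fixation")
  if (length(idx) == 0L) stop("no experimental blocks to label")
  cond <- events$trial_type[idx]
  pg <- unname(model$p_guessed[cond])
  if (anyNA(pg)) stop("p_guessed missing for some condition in the events")
  pk <- unname(model$p_correct_given_knew[cond])
  withr_seed(model$seed, {
    guessed <- stats::runif(length(idx)) < pg
    pc <- ifelse(guessed, model$p_correct_given_guessed, pk)
    correct <- stats::runif(length(idx)) < pc
    events$subjective[idx] <- ifelse(guessed, "guessed", "knew")
    events$objective_correct[idx] <- correct
  })
  events
}

#' Discard initial volumes of a run (T1 equilibration)
#'
#' Removes the first `n` volumes and shifts every onset back by
#' `n * tr_s`; fixation rows that end at or before the new origin are
#' dropped and a partially clipped leading fixation is truncated. Under the
#' default design, discarding 4 volumes (10 s) removes exactly the initial
#' fixation, leaving the first block at onset 0.
#'
#' @param run a [bold_run()].
#' @param events the matching event table.
#' @param n number of volumes to discard.
#' @return list with elements `run` and `events`.
#' @export
discard_initial_volumes <- function(run, events, n = 4L) {
  stopifnot(inherits(run, "bold_run"))
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  nv <- n_volumes(run)
  if (nv <= n) stop(sprintf("run has %d volumes; cannot discard %d", nv, n))
  if (n == 0L) return(list(run = run, events = events))
  run2 <- bold_run(run$data[, , , -(seq_len(n)), drop = FALSE], run$tr_s,
                   run$voxel_size_mm, run$origin_mm)
  shift <- n * run$tr_s
  ev <- events
  ev$onset <- ev$onset - shift
  clipped <- ev$onset < 0 & ev$onset + ev$duration > 1e-9
  ev$duration[clipped] <- ev$duration[clipped] + ev$onset[clipped]
  ev$onset[clipped] <- 0
  ev <- ev[ev$onset + ev$duration > 1e-9 | ev$trial_type != "fixation", ,
           drop = FALSE]
  ev <- ev[!(ev$trial_type == "fixation" & ev$duration <= 1e-9), , drop = FALSE]
  if (any(ev$trial_type != "fixation" & ev$onset < -1e-9))
    warning("an experimental block onset became negative after discarding")
  rownames(ev) <- NULL
  attr(ev, "tr_s") <- attr(events, "tr_s")
  attr(ev, "n_volumes") <- nv - n
  list(run = run2, events = ev)
}
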