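#' Canonical double-gamma hemodynamic response function
#'
#' The community-standard double-gamma impulse response: a gamma density
#' peaking near 5 s minus an undershoot gamma peaking near 15 s scaled by
#' 1/6, sampled on the volume grid over a 32 s support and normalized to unit
#' peak. The value at t = 0 is exactly 0.
#'
#' @param tr_s sampling interval in seconds (> 0).
#' @return numeric kernel of length `ceiling(32 / tr_s) + 1`, sampled at
#'   `t = 0, tr_s, 2 tr_s, ...`.
#' @export
#' @examples
#' k <- canonical_hrf(2.5)  # 14 samples covering 0..32.5 s
canonical_hrf <- function(tr_s) {
  stopifnot(is.numeric(tr_s), length(tr_s) == 1L, tr_s > 0)
  n <- ceiling(32 / tr_s) + 1L
  t <- (seq_len(n) - 1) * tr_s
  h <- hrf_double_gamma(t)
  h / hrf_peak_value()
}

# unnormalized double-gamma: shape 6 response minus shape 16 undershoot / 6
hrf_double_gamma <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

# peak of the continuous kernel, cached (dense-grid maximum; peak ~ 5.0 s)
hrf_peak_value <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- max(hrf_double_gamma(seq(0, 32, by = 1e-3)))
    val
  }
})

#' Convolve a volume-resolution boxcar with the canonical HRF
#'
#' @param boxcar numeric vector, one value per volume (condition indicator).
#' @param tr_s sampling interval in seconds.
#' @return vector of the same length as `boxcar` (causal convolution,
#'   truncated to the run).
#' @export
convolve_hrf <- function(boxcar, tr_s) {
  k <- canonical_hrf(tr_s)
  n <- length(boxcar)
  nk <- length(k)
  # direct causal convolution (exact zeros before stimulus onset)
  padded <- c(rep(0, nk - 1), boxcar)
  out <- as.numeric(stats::filter(padded, k, method = "convolution",
                                  sides = 1))
  out[nk:(nk + n - 1)]
}

#' Per-condition boxcar regressors on the volume grid
#'
#' A volume belongs to a block when its acquisition time `(i - 1) * tr_s`
#' falls inside `[onset, onset + duration)`; equivalently the block occupies
#' volumes `floor(onset / tr_s) .. floor((onset + duration) / tr_s) - 1` for
#' block timings aligned to the TR grid.
#'
#' @param events event table (see [build_session_timeline()]).
#' @param n_volumes number of volumes in the run.
#' @param tr_s repetition time in seconds.
#' @param conditions condition labels, one boxcar per label.
#' @return `n_volumes` x `length(conditions)` 0/1 matrix.
#' @export
condition_boxcars <- function(events, n_volumes, tr_s,
                              conditions = setdiff(unique(events$trial_type),
                                                   "fixation")) {
  ex <- experimental_blocks(events)
  if (nrow(ex) == 0L) stop("event table has no experimental blocks")
  B <- matrix(0, nrow = n_volumes, ncol = length(conditions),
              dimnames = list(NULL, conditions))
  tv <- (seq_len(n_volumes) - 1) * tr_s
  for (i in seq_len(nrow(ex))) {
    j <- match(ex$trial_type[i], conditions)
    if (is.na(j)) next
    inside <- tv >= ex$onset[i] - 1e-9 & tv < ex$onset[i] + ex$duration[i] - 1e-9
    B[inside, j] <- 1
  }
  B
}
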