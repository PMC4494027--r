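#' Z-map container
#'
#' Per-voxel contrast statistic in standard-normal units on the run's
#' spatial grid.
#'
#' @param data 3D numeric array of z values.
#' @param contrast contrast name.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param origin_mm world coordinate of voxel (1,1,1).
#' @return object of class `zmap`.
#' @export
zmap <- function(data, contrast = "contrast",
                 voxel_size_mm = c(2, 2, 3), origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L)
  z <- list(data = data, contrast = contrast,
            voxel_size_mm = as.numeric(voxel_size_mm),
            origin_mm = as.numeric(origin_mm))
  class(z) <- "zmap"
  z
}

#' Build a single-session GLM design matrix
#'
#' One boxcar-convolved-with-HRF regressor per condition, an intercept, and
#' optionally a linear drift column (centered, unit range).
#'
#' @param events event table.
#' @param n_volumes number of volumes in the run.
#' @param tr_s repetition time in seconds.
#' @param add_drift include a linear drift regressor.
#' @param conditions condition labels; defaults to the non-fixation labels
#'   present, in order of first appearance.
#' @return matrix with named columns; attribute `condition_cols` gives the
#'   indices of the condition regressors.
#' @export
build_design_matrix <- function(events, n_volumes, tr_s, add_drift = TRUE,
                                conditions = NULL) {
  ex <- experimental_blocks(events)
  if (nrow(ex) == 0L) stop("cannot build a design matrix from empty events")
  if (is.null(conditions))
    conditions <- attr(events, "conditions") %||% unique(ex$trial_type)
  B <- condition_boxcars(events, n_volumes, tr_s, conditions)
  R <- apply(B, 2, convolve_hrf, tr_s = tr_s)
  X <- cbind(R, intercept = 1)
  if (add_drift) {
    d <- seq_len(n_volumes) - (n_volumes + 1) / 2
    X <- cbind(X, drift = d / n_volumes)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "condition_cols") <- seq_along(conditions)
  attr(X, "conditions") <- conditions
  X
}

#' Fit a GLM contrast and return a z-map
#'
#' Ordinary least squares per voxel; the contrast t statistic
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` on `n - p` residual degrees of
#' freedom is mapped to a z value through the exact t CDF. Degenerate voxels
#' (zero residual variance and zero contrast estimate, i.e. constant
#' timecourses) get z = 0; a zero-residual voxel with a nonzero contrast is
#' assigned the largest-representable |z| with the contrast's sign.
#'
#' @param run a [bold_run()] (or an n_volumes x n_voxels matrix).
#' @param design design matrix from [build_design_matrix()].
#' @param contrast numeric contrast weights, one per design column (short
#'   vectors are zero-padded on the right, so `c(1, -1)` addresses the two
#'   condition columns).
#' @return a [zmap()] when `run` is a `bold_run`, else a numeric vector of z
#'   values with attributes `t`, `effect` and `df`.
#' @export
fit_contrast_zmap <- function(run, design, contrast) {
  is_run <- inherits(run, "bold_run")
  Y <- if (is_run) {
    d <- dim(run$data)
    t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
  } else as.matrix(run)
  if (nrow(Y) != nrow(design))
    stop("design rows do not match run volumes")
  if (length(contrast) < ncol(design))
    contrast <- c(contrast, rep(0, ncol(design) - length(contrast)))
  if (length(contrast) != ncol(design))
    stop("contrast length does not match design columns")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  n <- nrow(design); p <- ncol(design); df <- n - p
  if (df < 1) stop("no residual degrees of freedom")
  beta <- qr.coef(qrX, Y)                        # p x nvox
  res <- Y - design %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  effect <- drop(crossprod(contrast, beta))
  # degenerate voxels: residual variance at numerical-noise level relative
  # to the signal scale (constant voxels, noiseless synthetic runs)
  scale2 <- colMeans(Y^2) + 1
  degen <- sigma2 <= 1e-20 * scale2
  se <- sqrt(sigma2 * cvar)
  tval <- ifelse(!degen & se > 0, effect / se, 0)
  z <- t_to_z(tval, df)
  eff_nz <- abs(effect) > 1e-8 * sqrt(scale2)
  z[degen & eff_nz] <- sign(effect[degen & eff_nz]) * 38
  z[degen & !eff_nz] <- 0
  attr(z, "t") <- tval
  attr(z, "effect") <- effect
  attr(z, "df") <- df
  if (is_run) {
    zm <- zmap(array(as.numeric(z), dim = dim(run$data)[1:3]),
               voxel_size_mm = run$voxel_size_mm, origin_mm = run$origin_mm)
    attr(zm, "t") <- tval
    attr(zm, "effect") <- effect
    attr(zm, "df") <- df
    zm
  } else z
}

# exact-t-CDF conversion to standard normal, numerically safe in the tails
t_to_z <- function(tval, df) {
  z <- numeric(length(tval))
  pos <- tval >= 0
  # work in the upper tail on log scale to avoid saturation at |t| large
  z[pos] <- -stats::qnorm(stats::pt(tval[pos], df, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  z[!pos] <- stats::qnorm(stats::pt(tval[!pos], df, lower.tail = TRUE,
                                    log.p = TRUE), log.p = TRUE)
  z
}

#' Fit the localizer contrast across concatenated sessions
#'
#' Sessions are concatenated in time with shared condition regressors and
#' per-session intercept (and optional drift) columns, and a single
#' subject-level contrast z-map is computed.
#'
#' @param runs list of [bold_run()]s, one per localizer session.
#' @param events_list list of matching event tables.
#' @param contrast_weights named numeric over conditions, e.g.
#'   `c(sentences = 1, nonwords = -1)`.
#' @param add_drift include per-session linear drift columns.
#' @return a [zmap()].
#' @export
fit_localizer <- function(runs, events_list,
                          contrast_weights = c(sentences = 1, nonwords = -1),
                          add_drift = TRUE) {
  stopifnot(length(runs) == length(events_list), length(runs) >= 1L)
  conds <- names(contrast_weights)
  nses <- length(runs)
  tr_s <- runs[[1]]$tr_s
  Rs <- vector("list", nses); nv <- integer(nses)
  for (s in seq_len(nses)) {
    nv[s] <- n_volumes(runs[[s]])
    B <- condition_boxcars(events_list[[s]], nv[s], tr_s, conds)
    Rs[[s]] <- apply(B, 2, convolve_hrf, tr_s = tr_s)
  }
  ntot <- sum(nv)
  X <- do.call(rbind, Rs)
  for (s in seq_len(nses)) {
    icol <- numeric(ntot)
    icol[(cumsum(nv)[s] - nv[s] + 1):cumsum(nv)[s]] <- 1
    X <- cbind(X, icol)
    if (add_drift) {
      dcol <- numeric(ntot)
      idx <- (cumsum(nv)[s] - nv[s] + 1):cumsum(nv)[s]
      dcol[idx] <- (seq_len(nv[s]) - (nv[s] + 1) / 2) / nv[s]
      X <- cbind(X, dcol)
    }
  }
  colnames(X) <- c(conds, paste0(rep(c("sess", if (add_drift) "drift"), nses),
                                 rep(seq_len(nses),
                                     each = if (add_drift) 2 else 1)))
  Y <- do.call(rbind, lapply(runs, function(r) {
    d <- dim(r$data)
    t(matrix(r$data, nrow = prod(d[1:3]), ncol = d[4]))
  }))
  cw <- c(unname(contrast_weights), rep(0, ncol(X) - length(conds)))
  z <- fit_contrast_zmap(Y, X, cw)
  zmap(array(as.numeric(z), dim = dim(runs[[1]]$data)[1:3]),
       contrast = paste(conds, collapse = " > "),
       voxel_size_mm = runs[[1]]$voxel_size_mm,
       origin_mm = runs[[1]]$origin_mm)
}

#' Spatially smooth a BOLD run
#'
#' Separable Gaussian smoothing applied volume by volume, with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis in mm converted to voxels via
#' the voxel size. Edges use renormalized (mass-preserving) truncation, so a
#' spatially constant volume is unchanged.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @return a smoothed [bold_run()].
#' @export
smooth_bold <- function(run, fwhm_mm = 6) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(run)
  sig_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / run$voxel_size_mm
  d <- dim(run$data)
  out <- run$data
  for (ax in 1:3) {
    if (sig_vox[ax] <= 0) next
    r <- max(1L, ceiling(3 * sig_vox[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sig_vox[ax])
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  bold_run(out, run$tr_s, run$voxel_size_mm, run$origin_mm)
}

# 1D convolution along spatial axis `ax` of a 4D array, edge-renormalized
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- c(ax, setdiff(1:4, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  n <- d[ax]
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in -r:r) {
    w <- k[j + r + 1L]
    src <- (1:n) + j
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  out <- out / wsum
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}
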