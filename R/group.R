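#' One-tailed one-sample t-test against chance
#'
#' Tests whether subject accuracies exceed the chance level:
#' `t = (mean - chance) / (sd / sqrt(n))`, upper-tail p on `n - 1` degrees
#' of freedom. A zero-variance sample exactly at chance returns p = 0.5 by
#' contract; zero variance away from chance returns p = 0 (above) or 1
#' (below).
#'
#' @param acc per-subject accuracies (percent).
#' @param chance chance level on the same scale (default 50).
#' @return list with `t`, `df`, `p` (one-tailed), `mean`, `sem`, `n`.
#' @export
one_sample_t_onetailed <- function(acc, chance = 50) {
  acc <- as.numeric(acc)
  if (length(acc) < 2L) stop("need at least 2 subjects")
  if (!all(is.finite(acc))) stop("accuracies must be finite")
  n <- length(acc)
  m <- mean(acc); s <- stats::sd(acc)
  sem <- s / sqrt(n)
  if (s == 0) {
    t <- if (m == chance) 0 else sign(m - chance) * Inf
    p <- if (m == chance) 0.5 else if (m > chance) 0 else 1
  } else {
    t <- (m - chance) / sem
    p <- stats::pt(t, n - 1, lower.tail = FALSE)
  }
  list(t = t, df = n - 1L, p = p, mean = m, sem = sem, n = n)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise alpha (default 0.05).
#' @param m number of tests in the family.
#' @return `alpha / m`, rounded to 4 decimals for reporting (e.g. 0.0071
#'   for 7 tests, 0.0125 for 4).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  round(alpha / m, 4)
}

#' Paired t-test between two regions' accuracies
#'
#' One-sample t-test of the within-subject differences against 0,
#' two-tailed (the direction of a between-region difference is not
#' prespecified).
#'
#' @param a,b subject-aligned accuracy vectors.
#' @return list with `t`, `df`, `p` (two-tailed), `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must be subject-aligned (equal length)")
  if (length(a) < 2L) stop("need at least 2 subjects")
  d <- as.numeric(a) - as.numeric(b)
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  }
  list(t = t, df = n - 1L, p = p, mean_diff = mean(d))
}

#' 2x2 repeated-measures ANOVA (region x hemisphere)
#'
#' Fully within-subject two-factor ANOVA with two levels per factor. Each
#' effect is tested against its own subject-by-effect interaction error
#' term on (1, n-1) degrees of freedom, via the direct sums-of-squares
#' decomposition. With two-level factors sphericity is not at issue.
#' Zero-error degenerate cases report F = Inf with p = 0 and a warning.
#'
#' @param y numeric array `n_subjects x 2 x 2` (subject, region,
#'   hemisphere), or a data.frame with columns `subject`, `region`,
#'   `hemisphere`, `accuracy`.
#' @return data.frame with rows region, hemisphere, interaction: F, df1,
#'   df2, p.
#' @export
rm_anova_2x2 <- function(y) {
  if (is.data.frame(y)) {
    need <- c("subject", "region", "hemisphere", "accuracy")
    if (!all(need %in% names(y))) stop("missing columns in ANOVA table")
    subj <- sort(unique(y$subject))
    regs <- sort(unique(y$region)); hems <- sort(unique(y$hemisphere))
    if (length(regs) != 2L || length(hems) != 2L)
      stop("factors must each have exactly 2 levels")
    arr <- array(NA_real_, dim = c(length(subj), 2, 2))
    for (i in seq_len(nrow(y))) {
      arr[match(y$subject[i], subj), match(y$region[i], regs),
          match(y$hemisphere[i], hems)] <- y$accuracy[i]
    }
    y <- arr
  }
  stopifnot(length(dim(y)) == 3L, dim(y)[2] == 2L, dim(y)[3] == 2L)
  if (anyNA(y)) stop("design is incomplete: every subject needs all 4 cells")
  n <- dim(y)[1]
  if (n < 2L) stop("need at least 2 subjects")
  # effect scores per subject: mean differences over the other factor
  a_eff <- (y[, 2, 1] + y[, 2, 2]) / 2 - (y[, 1, 1] + y[, 1, 2]) / 2
  b_eff <- (y[, 1, 2] + y[, 2, 2]) / 2 - (y[, 1, 1] + y[, 2, 1]) / 2
  ab_eff <- (y[, 2, 2] - y[, 2, 1]) - (y[, 1, 2] - y[, 1, 1])
  # for a 2x2 within design, F_effect = t^2 of the per-subject effect scores
  f_of <- function(e) {
    m <- mean(e); v <- stats::var(e)
    if (v == 0) {
      if (m == 0) return(c(F = 0, p = 1))
      warning("zero error variance: reporting F = Inf, p = 0")
      return(c(F = Inf, p = 0))
    }
    Fv <- n * m^2 / v
    c(F = Fv, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  }
  res <- rbind(region = f_of(a_eff), hemisphere = f_of(b_eff),
               interaction = f_of(ab_eff / 2))
  data.frame(effect = rownames(res), F = res[, "F"], df1 = 1L, df2 = n - 1L,
             p = res[, "p"], row.names = NULL)
}

#' Group-level report over ROIs
#'
#' One-tailed t versus chance per ROI with family-wise Bonferroni
#' thresholds (temporal family of 7, frontal family of 4 by default).
#'
#' @param acc_table data.frame with columns `roi`, `subject`, `accuracy`
#'   (percent), and optionally `kind` and `roi_size` (carried through).
#' @param families named character vector mapping ROI names to family
#'   labels; see [language_region_families()].
#' @param alpha family-wise alpha.
#' @param chance chance level (percent).
#' @return data.frame, one row per ROI: n, mean, sem, t, df, p, family,
#'   family size, threshold, significant flag.
#' @export
group_report <- function(acc_table, families = language_region_families(),
                         alpha = 0.05, chance = 50) {
  stopifnot(all(c("roi", "subject", "accuracy") %in% names(acc_table)))
  rois <- unique(acc_table$roi)
  fam <- families[rois]
  fam[is.na(fam)] <- "unassigned"
  fam_sizes <- table(factor(fam))
  rows <- lapply(seq_along(rois), function(i) {
    acc <- acc_table$accuracy[acc_table$roi == rois[i]]
    tt <- one_sample_t_onetailed(acc, chance = chance)
    fs <- as.integer(fam_sizes[[fam[i]]])
    thr <- bonferroni_threshold(alpha, fs)
    data.frame(roi = rois[i], n = tt$n, mean_accuracy = tt$mean,
               sem = tt$sem, t = tt$t, df = tt$df, p = tt$p,
               family = unname(fam[i]), family_size = fs,
               threshold = thr, significant = tt$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
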