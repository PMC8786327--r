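# Replicate-level hypothesis tests applied to the locus statistics:
# Welch's unequal-variance t-test for cut vs. uncut contrasts, the paired
# t-test for within-replicate comparisons, and an exact binomial test of
# equal per-nucleotide read density used by the terminator scan. Two-sided
# p-values throughout; no multiple-testing correction is applied because the
# pipeline reports raw p per named locus.

#' Welch's unequal-variance t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When both
#' samples have zero variance the result carries `degenerate = TRUE`
#' (`t = 0, p = 1` for equal means; `p = 0` as the limit for unequal means).
#'
#' @param x,y Numeric replicate vectors (each length >= 2).
#' @return A `ttest_result` list: `t`, `df`, `p`, `kind`, `degenerate`.
#' @export
welch_ttest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 replicates")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    eq <- mean(x) == mean(y)
    return(ttest_result(t = if (eq) 0 else Inf,
                        df = nx + ny - 2, p = if (eq) 1 else 0,
                        kind = "welch_unpaired", degenerate = TRUE))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  ttest_result(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
               kind = "welch_unpaired", degenerate = FALSE)
}

#' Paired t-test
#'
#' One-sample t-test on the differences `x - y` with `n - 1` degrees of
#' freedom, two-sided. All-identical nonzero differences are flagged
#' degenerate with the limit p-value 0; all-zero differences give
#' `t = 0, p = 1`.
#'
#' @param x,y Numeric vectors of equal length >= 2, paired by replicate.
#' @return A `ttest_result` list.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  n <- length(d)
  if (stats::var(d) == 0) {
    zero <- d[1L] == 0
    return(ttest_result(t = if (zero) 0 else Inf, df = n - 1,
                        p = if (zero) 1 else 0, kind = "paired",
                        degenerate = TRUE))
  }
  t <- mean(d) / sqrt(stats::var(d) / n)
  ttest_result(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
               kind = "paired", degenerate = FALSE)
}

ttest_result <- function(t, df, p, kind, degenerate) {
  structure(list(t = t, df = df, p = p, kind = kind,
                 degenerate = degenerate), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.3g, p = %.4g%s\n", x$kind, x$t, x$df,
              x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Exact binomial test of equal per-nucleotide read density
#'
#' Tests whether `up_count` reads over `up_len` nt and `down_count` reads
#' over `down_len` nt are consistent with one common density: conditional on
#' `n = up_count + down_count`, the upstream count is
#' `Binomial(n, up_len / (up_len + down_len))` under the null. The two-sided
#' p-value sums all outcome probabilities not exceeding that of the observed
#' count (the standard minimum-likelihood rule).
#'
#' @param up_count,down_count Read counts (>= 0).
#' @param up_len,down_len Segment lengths in nt (> 0).
#' @return List: `p` (NA-flagged when both counts are 0), `n`, `p0`.
#' @export
binomial_density_test <- function(up_count, up_len, down_count, down_len) {
  stopifnot(up_count >= 0, down_count >= 0, up_len > 0, down_len > 0)
  n <- up_count + down_count
  p0 <- up_len / (up_len + down_len)
  if (n == 0) return(list(p = NA_real_, n = 0L, p0 = p0))
  dens <- stats::dbinom(0:n, n, p0)
  obs <- dens[up_count + 1L]
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  list(p = p, n = n, p0 = p0)
}
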