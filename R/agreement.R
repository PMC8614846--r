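#' Agreement statistics between two measurement series
#'
#' Computes the standard method-comparison summary between paired
#' measurement series `a` and `b` (e.g. automated vs radiologist
#' minimum-JSW): Pearson correlation with two-sided p-value, the R^2 of
#' the simple linear regression of one series on the other (equal to
#' r^2), Bland-Altman bias and 95% limits of agreement, the
#' intraclass correlation coefficient ICC(2,1), and the interobserver
#' error summarized both as signed differences and as absolute
#' differences (mean and SD of `|d|`; the absolute summary corresponds
#' to the folded distribution conventionally quoted as "mean error").
#'
#' Differences are `d_i = a_i - b_i` (first argument minus second).
#' Limits of agreement use `1.96 * SD(d)` with the n-1 denominator.
#'
#' @param a,b numeric vectors of equal length `n >= 3`, finite.
#' @return An object of class `kj_agreement` with fields `n`,
#'   `pearson_r`, `pearson_p`, `r_squared`, `bias_d`, `loa_half_width`,
#'   `icc`, `mean_abs_error`, `sd_abs_error`, `mean_error`, `sd_error`.
#'   If either series has zero variance the Pearson fields are `NA` with
#'   a warning (the ICC is still computed).
#' @export
agreement <- function(a, b) {
  check_pairs(a, b)
  d <- a - b
  bias <- mean(d)
  loa <- 1.96 * sd(d)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("Pearson correlation undefined: zero variance in a series")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(a, b)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(n = length(a), pearson_r = r, pearson_p = p,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 bias_d = bias, loa_half_width = loa,
                 icc = icc_agreement(a, b),
                 mean_abs_error = mean(abs(d)), sd_abs_error = sd(abs(d)),
                 mean_error = bias, sd_error = sd(d)),
            class = "kj_agreement")
}

check_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("series must be finite")
  invisible(TRUE)
}

#' @export
print.kj_agreement <- function(x, ...) {
  cat(sprintf("<kj_agreement> n=%d\n", x$n))
  cat(sprintf("  Pearson r=%.4f (p=%.3g), R^2=%.4f\n",
              x$pearson_r, x$pearson_p, x$r_squared))
  cat(sprintf("  Bland-Altman bias (a-b) = %.4f, LoA = bias +/- %.4f\n",
              x$bias_d, x$loa_half_width))
  cat(sprintf("  ICC(2,1) = %.4f\n", x$icc))
  cat(sprintf("  |error|: mean %.4f, SD %.4f\n",
              x$mean_abs_error, x$sd_abs_error))
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the mean squares of the subjects-by-raters ANOVA:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2`
#' raters, the standard inter-observer reliability form.
#'
#' @param a,b paired measurement vectors, `n >= 3`.
#' @return ICC estimate in `[-1, 1]`.
#' @export
icc_agreement <- function(a, b) {
  check_pairs(a, b)
  n <- length(a); k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) return(if (msr == mse) 1 else NA_real_)
  (msr - mse) / denom
}

#' Bland-Altman point set
#'
#' Per-pair `(mean, difference)` coordinates with the bias and limits of
#' agreement attached, ready for plotting.
#'
#' @inheritParams agreement
#' @return Data frame with columns `mean` and `diff` (`a - b`), one row
#'   per pair, and attributes `bias`, `lower`, `upper`.
#' @export
bland_altman_points <- function(a, b) {
  check_pairs(a, b)
  d <- a - b
  out <- data.frame(mean = (a + b) / 2, diff = d)
  attr(out, "bias") <- mean(d)
  attr(out, "lower") <- mean(d) - 1.96 * sd(d)
  attr(out, "upper") <- mean(d) + 1.96 * sd(d)
  out
}

#' Bland-Altman plot
#'
#' @inheritParams agreement
#' @param ... passed to [plot()].
#' @return The [bland_altman_points()] table, invisibly.
#' @export
plot_bland_altman <- function(a, b, ...) {
  pts <- bland_altman_points(a, b)
  plot(pts$mean, pts$diff, xlab = "Mean of pair (mm)",
       ylab = "Difference a - b (mm)", pch = 16,
       col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = attr(pts, "bias"), col = "red")
  graphics::abline(h = c(attr(pts, "lower"), attr(pts, "upper")),
                   col = "blue", lty = 2)
  invisible(pts)
}
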