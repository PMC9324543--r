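# Agreement and segmentation metrics: Dice / IoU overlap, ICC(2,1) from the
# two-way random-effects mean squares, RMSE and Bland-Altman statistics.

#' Dice coefficient and IoU between two masks
#'
#' `dice = 2|A&B| / (|A| + |B|)`, `iou = |A&B| / |A|B|`; when both masks are
#' empty for the label, both are defined as 1 (documented convention for
#' degenerate phantom cases).
#'
#' @param a,b [label_mask]s (or matrices) of equal shape.
#' @param label foreground label compared (default 1).
#' @return named numeric vector `c(dice, iou)`.
#' @export
dice_iou <- function(a, b, label = 1L) {
  am <- as_binary(a, label); bm <- as_binary(b, label)
  if (!all(dim(am) == dim(bm)))
    stop("dimension error: masks differ in shape")
  inter <- sum(am & bm)
  na <- sum(am); nb <- sum(bm)
  uni <- na + nb - inter
  if (na + nb == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / (na + nb), iou = inter / uni)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC, computed
#' from the ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param m numeric matrix, `n` subjects x `k` raters, no missing cells.
#' @return ICC(2,1) value; zero between-subject variance returns 0 with a
#'   warning.
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(m)) stop("missing cells are not supported")
  g <- mean(m)
  ri <- rowMeans(m); cj <- colMeans(m)
  ssr <- k * sum((ri - g)^2)
  ssc <- n * sum((cj - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (msr <= .Machine$double.eps * 100 || denom <= 0) {
    warning("zero between-subject variance: ICC undefined, returning 0")
    return(0)
  }
  (msr - mse) / denom
}

#' Bland-Altman agreement statistics
#'
#' Differences `d_i = x_i - y_i`; bias is their mean, the 95% limits of
#' agreement are `bias +/- 1.96 * SD(d)` (SD with the `n - 1` denominator),
#' and RMSE is `sqrt(mean(d^2))`.
#'
#' @param x,y equal-length paired measurement vectors, `n >= 3`.
#' @return object of class `agreement_stats`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `rmse`, `n`, `mean_xy`, `diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("sample-size error: need at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 rmse = sqrt(mean(d^2)), n = n,
                 mean_xy = (x + y) / 2, diff = d),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d, bias = %.4g, LoA = [%.4g, %.4g], RMSE = %.4g\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$rmse))
  invisible(x)
}

#' Root-mean-square error between paired vectors
#'
#' @param x,y equal-length numeric vectors.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  sqrt(mean((x - y)^2))
}

#' Bland-Altman plot
#'
#' Mean-vs-difference scatter with bias and 95% limits of agreement.
#'
#' @param stats an [bland_altman()] result.
#' @param title plot title.
#' @return a ggplot object (requires ggplot2).
#' @export
ba_plot <- function(stats, title = "Bland-Altman") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(m = stats$mean_xy, d = stats$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = stats$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(stats$loa_low, stats$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(title = title, x = "Mean of methods",
                  y = "Difference between methods") +
    ggplot2::theme_minimal()
}

#' Compare two measurement tables
#'
#' Joins two report CSV-style data frames on `image_id` and computes
#' agreement statistics (RMSE, ICC(2,1), Bland-Altman) per shared numeric
#' column.
#'
#' @param a,b data frames with `image_id` and numeric measurement columns.
#' @param columns measurement columns to compare (default: thickness, angle,
#'   length).
#' @return named list of per-column lists: `rmse`, `icc21`, `bland_altman`.
#' @export
evaluate_reports <- function(a, b, columns = c("d_mm", "theta_deg", "lf_mm")) {
  mrg <- merge(a, b, by = "image_id", suffixes = c(".a", ".b"))
  out <- list()
  for (cl in columns) {
    xa <- mrg[[paste0(cl, ".a")]]; xb <- mrg[[paste0(cl, ".b")]]
    if (is.null(xa) || is.null(xb)) next
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 3) next
    out[[cl]] <- list(rmse = rmse(xa[ok], xb[ok]),
                      icc21 = suppressWarnings(icc21(cbind(xa[ok], xb[ok]))),
                      bland_altman = bland_altman(xa[ok], xb[ok]))
  }
  out
}
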