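#' Bland-Altman agreement statistics
#'
#' Differences d = estimated - measured; bias is their mean, SD the sample
#' (n-1) standard deviation, and the 95% limits of agreement are
#' bias +/- 1.96 SD.
#'
#' @param estimated,measured Numeric vectors of equal length (n >= 2).
#' @return A list of class `lv_agreement` with `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
#' @examples
#' bland_altman(c(9, 10, 11), c(10, 10, 10))  # bias 0, sd 1, limits +/-1.96
bland_altman <- function(estimated, measured) {
  if (length(estimated) != length(measured))
    stop("estimated and measured must have equal length")
  ok <- !(is.na(estimated) | is.na(measured))
  d <- estimated[ok] - measured[ok]
  n <- length(d)
  if (n < 2L) stop("insufficient data: need at least 2 paired values")
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = n),
            class = "lv_agreement")
}

#' @export
print.lv_agreement <- function(x, ...) {
  cat(sprintf(
    "<lv_agreement> n = %d, bias = %.3f, sd = %.3f, LoA [%.3f, %.3f]\n",
    x$n, x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Ordinary least-squares fit with Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must vary.
#' @return A list with `slope`, `intercept`, `r`, `r2`, `n`. For constant
#'   `y`, `slope = 0` and `r = 0` by convention.
#' @export
#' @examples
#' linfit(1:3, c(1, 2, 4))  # slope 1.5, intercept -2/3, r = 0.982
linfit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need at least 3 paired values")
  sx <- stats::sd(x)
  if (sx == 0) stop("degenerate fit: zero variance in x")
  sy <- stats::sd(y)
  cxy <- stats::cov(x, y)
  slope <- cxy / sx^2
  intercept <- mean(y) - slope * mean(x)
  r <- if (sy == 0) 0 else cxy / (sx * sy)
  list(slope = slope, intercept = intercept, r = r, r2 = r^2, n = n)
}

#' Combined agreement report (Bland-Altman + regression)
#'
#' @param estimated,measured Numeric vectors of equal length (n >= 3).
#' @return A list merging [bland_altman()] and [linfit()] (the fit regresses
#'   estimated on measured).
#' @export
agreement_stats <- function(estimated, measured) {
  ba <- bland_altman(estimated, measured)
  fit <- linfit(measured, estimated)
  c(unclass(ba), fit[c("slope", "intercept", "r", "r2")])
}

#' Bland-Altman and scatter plots
#'
#' Base-graphics diagnostic plots: identity scatter of estimated vs
#' measured, and the Bland-Altman plot of differences against means with
#' the bias and 1.96 SD limits drawn.
#'
#' @param estimated,measured Numeric vectors of equal length.
#' @param label Axis label stem (e.g. `"pre-A P_LV (mmHg)"`).
#' @param file Optional PNG path; when given, the plot is written there.
#' @return The [bland_altman()] statistics, invisibly.
#' @export
plot_agreement <- function(estimated, measured, label = "value",
                           file = NULL) {
  ba <- bland_altman(estimated, measured)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(1, 2))
  # restore par before any device teardown registered above
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  lim <- range(c(estimated, measured), na.rm = TRUE)
  plot(measured, estimated, xlim = lim, ylim = lim,
       xlab = paste("measured", label), ylab = paste("estimated", label))
  graphics::abline(0, 1, lty = 2)
  m <- (estimated + measured) / 2
  d <- estimated - measured
  plot(m, d, xlab = paste("mean", label),
       ylab = paste("difference", label),
       ylim = range(c(d, ba$loa_low, ba$loa_high)))
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}
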