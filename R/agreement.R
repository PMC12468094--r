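# Agreement statistics for model-vs-clinic (or model-vs-truth) comparisons.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, per Lin's original definition.
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @return concordance correlation coefficient in `[-1, 1]`
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) {
    stop_cxl("ccc: inputs must have equal length", "cxl_stats_error")
  }
  if (length(x) < 3 || !all(is.finite(x)) || !all(is.finite(y))) {
    stop_cxl("ccc: inputs must be finite with length >= 3", "cxl_stats_error")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop_cxl("ccc: both inputs are constant and identical", "cxl_stats_error")
  }
  2 * sxy / denom
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `d = x - y` (reference first, model second, so a negative
#' bias means the model overestimates). `bias = mean(d)`,
#' `LoA = bias +/- 1.96 sd(d)` with the sample (n-1) standard deviation.
#'
#' @param x reference (e.g. clinical) values
#' @param y comparison (e.g. model) values
#' @return list with `bias`, `loa_low`, `loa_high`
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop_cxl("bland_altman: inputs must have equal length", "cxl_stats_error")
  }
  if (length(x) < 3) {
    stop_cxl("bland_altman: need length >= 3", "cxl_stats_error")
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Combined agreement statistics
#'
#' @inheritParams bland_altman
#' @return object of class `agreement_stats` with `pearson_r2`, `ccc`,
#'   `bias`, `loa_low`, `loa_high`
#' @export
agreement_stats <- function(x, y) {
  ba <- bland_altman(x, y)
  structure(list(pearson_r2 = cor(x, y)^2, ccc = ccc(x, y),
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement: R^2 %.3f, CCC %.3f, bias %.3g [LoA %.3g, %.3g]\n",
              x$pearson_r2, x$ccc, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
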