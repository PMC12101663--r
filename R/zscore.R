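#' Student-t Z-score statistic for a new observation
#'
#' Given a subject's own history \eqn{Y_1, \dots, Y_n} (assumed iid Normal)
#' and a new observation \eqn{Y_{n+1}}, computes
#' \deqn{T_{n+1} = \frac{Y_{n+1} - \bar{Y}_n}{\hat\sigma_n \sqrt{1 + 1/n}}}
#' which follows a Student t distribution with \eqn{n - 1} degrees of
#' freedom exactly, whatever the (finite) history length. Only the subject's
#' own history enters: no population information is used.
#'
#' @param history A [subject_summary()] over the first \eqn{n} values, or a
#'   numeric vector that will be summarised. Needs `n >= 2` and positive SD.
#' @param y_new The new observation \eqn{Y_{n+1}}.
#' @return An object of class `zscore_result` with fields `t_value`, `df`
#'   (\eqn{n-1}) and `n`.
#' @seealso [zscore_range()] for the equivalent interval form.
#' @export
#' @examples
#' zscore_statistic(c(4, 6), 8)$t_value  # sqrt(3)
zscore_statistic <- function(history, y_new) {
  history <- as_subject_summary(history)
  if (!is.finite(y_new)) stop("'y_new' must be finite")
  if (history$n < 2L)
    stop("insufficient history: the statistic can only be calculated ",
         "starting from the third observation (need n >= 2 prior values)")
  sd <- summary_sd(history)
  if (!is.finite(sd) || sd <= 0)
    stop("degenerate history: zero variance, statistic undefined")
  t_value <- (y_new - history$mean) / (sd * sqrt(1 + 1 / history$n))
  structure(list(t_value = t_value, df = history$n - 1L, n = history$n),
            class = "zscore_result")
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("<zscore_result> t = %.4f on %d df (history n = %d)\n",
              x$t_value, x$df, x$n))
  invisible(x)
}

#' Adaptive reference range from a subject's own history (Z-score method)
#'
#' Inverts the Student-t Z-score into a prediction interval for the next
#' observation:
#' \deqn{\bar{Y}_n \pm t_{1-\alpha/2,\,n-1}\, \hat\sigma_n \sqrt{1 + 1/n}.}
#' The one-sided variant puts all the significance in the upper tail
#' (\eqn{t_{1-\alpha,n-1}}) and clamps the lower limit to 0, the convention
#' for nonnegative markers where only elevations matter. Classifying a value
#' against this range agrees exactly with thresholding [zscore_statistic()]
#' at the corresponding t quantile.
#'
#' @inheritParams zscore_statistic
#' @param alpha Significance level in (0, 1); `alpha = 1` yields the
#'   degenerate zero-width range at the history mean.
#' @param sidedness `"two_sided"` or `"upper_only"`.
#' @param occasion Occasion index the range applies to (defaults to `n + 1`).
#' @return A [reference_range()] with `method = "zscore"`.
#' @export
#' @examples
#' zscore_range(c(4, 6), alpha = 0.05)  # 5 +/- 12.7062 * sqrt(3)
zscore_range <- function(history, alpha = 0.05,
                         sidedness = c("two_sided", "upper_only"),
                         occasion = NULL) {
  history <- as_subject_summary(history)
  sidedness <- match.arg(sidedness)
  if (!(alpha > 0 && alpha <= 1)) stop("'alpha' must lie in (0, 1]")
  if (history$n < 2L)
    stop("insufficient history: the range can only be calculated ",
         "starting from the third observation (need n >= 2 prior values)")
  sd <- summary_sd(history)
  if (!is.finite(sd) || sd <= 0)
    stop("degenerate history: zero variance, range undefined")
  scale <- sd * sqrt(1 + 1 / history$n)
  if (is.null(occasion)) occasion <- history$n + 1L
  if (sidedness == "two_sided") {
    q <- stats::qt(1 - alpha / 2, df = history$n - 1L)
    lower <- history$mean - q * scale
    upper <- history$mean + q * scale
  } else {
    q <- stats::qt(1 - alpha, df = history$n - 1L)
    lower <- 0
    upper <- max(history$mean + q * scale, 0)
  }
  reference_range(lower, upper, alpha = alpha, sidedness = sidedness,
                  occasion = occasion, method = "zscore")
}

# Coerce numeric history vectors for convenience; summaries pass through.
as_subject_summary <- function(history) {
  if (inherits(history, "subject_summary")) return(history)
  if (is.numeric(history)) return(subject_summary(history))
  stop("'history' must be a subject_summary or a numeric vector")
}
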