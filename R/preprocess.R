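#' Subtract the constant instrument background
#'
#' Removes the average background (dark-count) level from every bin.
#' Values may become negative; no clipping is applied.
#'
#' @param signal A [dl_signal()].
#' @param background Background level in counts per bin (>= 0; default 9).
#' @return A [dl_signal()] with the background removed.
#' @export
subtract_background <- function(signal, background = 9) {
  stopifnot(inherits(signal, "dl_signal"), background >= 0)
  out <- signal
  out$values <- signal$values - background
  out$meta$background_subtracted <- background
  out
}

#' Centered sliding-average smoothing
#'
#' Replaces each value by the mean over a centered window of `window`
#' bins. At the edges the window shrinks to the available samples, so the
#' output has the same length as the input.
#'
#' @param signal A [dl_signal()].
#' @param window Odd window width in bins, `1 <= window <= length(signal)`
#'   (default 5).
#' @return A smoothed [dl_signal()].
#' @export
moving_average <- function(signal, window = 5L) {
  stopifnot(inherits(signal, "dl_signal"))
  window <- as.integer(window)
  n <- length(signal$values)
  if (window < 1L || window %% 2L == 0L) {
    stop("'window' must be a positive odd integer")
  }
  if (window > n) stop("'window' must not exceed the signal length")
  half <- (window - 1L) %/% 2L
  # cumulative-sum rolling mean with truncated windows at both edges
  cs <- c(0, cumsum(signal$values))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  out <- signal
  out$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out$meta$smoothed_window <- window
  out
}

#' Standard preprocessing chain
#'
#' Background subtraction followed by width-`window` sliding-average
#' smoothing, in that order.
#'
#' @inheritParams subtract_background
#' @inheritParams moving_average
#' @return A preprocessed [dl_signal()].
#' @export
preprocess_signal <- function(signal, background = 9, window = 5L) {
  moving_average(subtract_background(signal, background), window)
}
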