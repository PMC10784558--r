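#' Delayed-luminescence signal container
#'
#' A `dl_signal` is a uniformly sampled photon-count (or counts-equivalent
#' real-valued) time series: times in seconds with constant step `dt`,
#' one value per bin, plus free-form provenance metadata.
#'
#' @param values Numeric vector of counts per bin (finite, length >= 1).
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first bin (default 0).
#' @param meta Named list of provenance tags (e.g. class label, seed).
#'
#' @return An object of class `dl_signal` with elements `times`, `values`,
#'   `dt`, `meta`.
#' @export
#' @examples
#' s <- dl_signal(c(10, 8, 6), dt = 0.1)
#' s$times
dl_signal <- function(values, dt = 0.1, t0 = 0, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must have length >= 1")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("'dt' must be a single positive number")
  }
  structure(
    list(
      times = t0 + dt * (seq_along(values) - 1L),
      values = values,
      dt = dt,
      meta = meta
    ),
    class = "dl_signal"
  )
}

#' @export
print.dl_signal <- function(x, ...) {
  cat(sprintf(
    "<dl_signal> %d bins, dt = %g s, t in [%g, %g] s\n",
    length(x$values), x$dt, x$times[1L], x$times[length(x$times)]
  ))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  invisible(x)
}

#' @export
length.dl_signal <- function(x) length(x$values)

#' Read / write a signal as a two-column CSV
#'
#' The on-disk format is `time_s,counts`, one row per bin, header required.
#'
#' @param path File path.
#' @return `read_signal_csv` returns a [dl_signal()]; `write_signal_csv`
#'   returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df))) {
    stop("signal CSV must have columns 'time_s' and 'counts'")
  }
  tt <- df$time_s
  if (length(tt) < 2L) {
    dt <- 0.1
  } else {
    steps <- diff(tt)
    dt <- steps[1L]
    if (any(abs(steps - dt) > 1e-9 * max(1, abs(dt)))) {
      stop("time column must be uniformly spaced")
    }
  }
  dl_signal(df$counts, dt = dt, t0 = tt[1L], meta = list(source = path))
}

#' @rdname read_signal_csv
#' @param signal A [dl_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "dl_signal"))
  utils::write.csv(
    data.frame(time_s = signal$times, counts = signal$values),
    path,
    row.names = FALSE
  )
  invisible(path)
}
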