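#' Kaiser window
#'
#' Kaiser window of length `n` with shape parameter `shape` (>= 0);
#' `shape = 0` gives the rectangular window. Uses the zeroth-order
#' modified Bessel function of the first kind.
#'
#' @param n Window length (>= 1).
#' @param shape Dimensionless shape parameter (>= 0).
#' @return Numeric vector of `n` window weights in (0, 1].
#' @export
kaiser_window <- function(n, shape = 5) {
  stopifnot(n >= 1L, shape >= 0)
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  arg <- shape * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2))
  besselI(arg, 0) / besselI(shape, 0)
}

#' One-sided Kaiser-windowed periodogram
#'
#' Mean-centers the signal (optional), applies a Kaiser window of the
#' original length, zero-pads to the next power of two, and converts the
#' FFT to periodogram values `P_j = |X_j|^2 / (W * n_fft)`, where `W` is
#' the mean squared window weight computed over the original (unpadded)
#' window. One-sided bins `j = 0..n_fft/2` are retained, with
#' `f_j = j * fs / n_fft` and `fs = 1/dt`.
#'
#' @param signal A [dl_signal()] of length >= 4.
#' @param kaiser_shape Kaiser shape parameter (>= 0; default 5).
#' @param center Mean-center before windowing (default `TRUE`); removes
#'   the dominant DC pedestal of a decay signal.
#' @return A `spectrum_estimate`: `frequencies` (Hz), `power`,
#'   `window_norm` (W), `n_fft`, `fs`, `all_zero` flag.
#' @export
periodogram <- function(signal, kaiser_shape = 5, center = TRUE) {
  stopifnot(inherits(signal, "dl_signal"))
  x <- signal$values
  n <- length(x)
  if (n < 4L) stop("signal must have at least 4 points")
  if (center) x <- x - mean(x)
  w <- kaiser_window(n, kaiser_shape)
  W <- mean(w^2)
  n_fft <- 2L^ceiling(log2(n))
  xp <- c(x * w, rep(0, n_fft - n))
  X <- stats::fft(xp)
  P <- Mod(X)^2 / (W * n_fft)
  half <- n_fft %/% 2L
  fs <- 1 / signal$dt
  structure(
    list(
      frequencies = (0:half) * fs / n_fft,
      power = P[1:(half + 1L)],
      window_norm = W,
      n_fft = n_fft,
      fs = fs,
      all_zero = all(P == 0)
    ),
    class = "spectrum_estimate"
  )
}

#' Spectral centroid (global instantaneous frequency)
#'
#' Power-weighted mean frequency over the one-sided bins: the global
#' spectrum reduction of the instantaneous-frequency curve to a single
#' scalar feature.
#'
#' @param spectrum A `spectrum_estimate` from [periodogram()].
#' @return Frequency in Hz, in `[0, fs/2]`.
#' @export
instantaneous_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  tot <- sum(spectrum$power)
  if (tot <= 0) stop("zero total power: instantaneous frequency undefined")
  sum(spectrum$frequencies * spectrum$power) / tot
}

#' Spectral entropy (bits)
#'
#' Normalizes the one-sided periodogram to a probability distribution
#' over frequency bins in `[0, fs/2]` and returns its Shannon entropy in
#' base 2. Zero-power bins contribute zero by the `0 * log(0) = 0`
#' convention.
#'
#' @inheritParams instantaneous_frequency
#' @return Entropy in bits, `<= log2(number of bins)`.
#' @export
spectral_entropy <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  tot <- sum(spectrum$power)
  if (tot <= 0) stop("zero total power: spectral entropy undefined")
  p <- spectrum$power / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Approximate entropy
#'
#' Regularity statistic `ApEn(m, r, N) = H^m(r) - H^(m+1)(r)`, where
#' `H^m(r)` is the mean natural-log proportion of m-length embedding
#' vectors within Chebyshev distance `r` of each vector. Matches are
#' counted with `<= r` and include self-matches, so every proportion is
#' positive and the logarithm is always defined.
#'
#' @param x Numeric series of length `N > m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance radius (> 0).
#' @return Dimensionless non-negative entropy estimate.
#' @export
approximate_entropy <- function(x, m = 2L, r) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (n <= m + 1L) stop("series too short for the requested embedding")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("'r' must be positive")
  D <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    nv <- n - mm + 1L
    M <- D[1:nv, 1:nv, drop = FALSE]
    if (mm > 1L) {
      for (k in seq_len(mm - 1L)) {
        M <- pmax(M, D[(1L + k):(nv + k), (1L + k):(nv + k), drop = FALSE])
      }
    }
    C <- rowSums(M <= r) / nv
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' Robust location and scale statistics
#'
#' `median_value` uses the usual even/odd rule (mean of the two middle
#' order statistics for even length). `quartile_deviation` computes
#' `Q3 - Q1` with quartiles interpolated linearly at order-statistic
#' positions `0.25*(n+1)` and `0.75*(n+1)` (clamped to `[1, n]`).
#' `mean_deviation` is the mean absolute deviation about the arithmetic
#' mean.
#'
#' @param x Non-empty numeric series.
#' @return A single numeric value.
#' @export
median_value <- function(x) {
  stopifnot(length(x) >= 1L)
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' @rdname median_value
#' @export
quartile_deviation <- function(x) {
  stopifnot(length(x) >= 1L)
  s <- sort(x)
  n <- length(s)
  at <- function(pos) {
    pos <- min(max(pos, 1), n)
    lo <- floor(pos)
    frac <- pos - lo
    if (lo >= n) s[n] else s[lo] + frac * (s[lo + 1L] - s[lo])
  }
  at(0.75 * (n + 1)) - at(0.25 * (n + 1))
}

#' @rdname median_value
#' @export
mean_deviation <- function(x) {
  stopifnot(length(x) >= 1L)
  mean(abs(x - mean(x)))
}

#' Names of the ten classification features, in canonical order
#' @export
feature_names <- function() {
  c("I0", "beta", "tau", "E_T", "inst_freq", "spec_entropy",
    "ap_en", "median", "quartile_dev", "mean_dev")
}

#' Assemble the ten-component feature vector of one sample
#'
#' Combines the four hyperbolic-fit features (I0, beta, tau, E(T)) with
#' six statistics of the preprocessed series: spectral centroid, spectral
#' entropy, approximate entropy (m = 2, r = `apen_r_factor` times the
#' sample standard deviation of the series), median, quartile deviation
#' and mean deviation, in the fixed order given by [feature_names()].
#'
#' @param signal The preprocessed [dl_signal()].
#' @param fit A converged `hyper_fit` for the same signal.
#' @param kaiser_shape Kaiser window shape for the periodogram.
#' @param apen_m ApEn embedding dimension.
#' @param apen_r_factor ApEn tolerance as a fraction of the series sd.
#' @param center Mean-center the series before the periodogram.
#' @return Named numeric vector of 10 finite components; the signal's
#'   class label (if any) is carried in the `"label"` attribute.
#' @export
extract_features <- function(signal, fit, kaiser_shape = 5, apen_m = 2L,
                             apen_r_factor = 0.2, center = TRUE) {
  stopifnot(inherits(signal, "dl_signal"), inherits(fit, "hyper_fit"))
  if (!fit$converged) stop("hyperbolic fit did not converge")
  spec <- periodogram(signal, kaiser_shape = kaiser_shape, center = center)
  x <- signal$values
  r <- apen_r_factor * stats::sd(x)
  v <- c(
    fit$params["I0"], fit$params["beta"], fit$params["tau"], fit$e_T,
    instantaneous_frequency(spec),
    spectral_entropy(spec),
    approximate_entropy(x, m = apen_m, r = r),
    median_value(x),
    quartile_deviation(x),
    mean_deviation(x)
  )
  names(v) <- feature_names()
  if (!all(is.finite(v))) stop("non-finite feature computed")
  attr(v, "label") <- signal$meta$label
  v
}

#' Z-score normalization statistics from training data
#'
#' Column means and sample standard deviations (denominator `n - 1`) of
#' a training feature matrix; statistics must come from training data
#' only so held-out samples see no leakage.
#'
#' @param X Numeric matrix, rows = samples, columns = features (>= 2
#'   rows).
#' @return A `norm_stats` object with `mu` and `sigma`.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  bad <- which(sigma <= 0)
  if (length(bad) > 0L) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance feature component(s): ", paste(nm, collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma), class = "norm_stats")
}

#' Apply z-score normalization
#'
#' @param X Numeric vector (one sample) or matrix (rows = samples).
#' @param stats A `norm_stats` from [zscore_fit()].
#' @return Normalized vector or matrix of the same shape.
#' @export
zscore_apply <- function(X, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (is.matrix(X)) {
    sweep(sweep(X, 2L, stats$mu, "-"), 2L, stats$sigma, "/")
  } else {
    (X - stats$mu) / stats$sigma
  }
}
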