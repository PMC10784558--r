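test_that("kaiser window limits and symmetry", {
  expect_equal(kaiser_window(16, 0), rep(1, 16))
  w <- kaiser_window(33, 5)
  expect_equal(w, rev(w))
  expect_equal(which.max(w), 17L)
  expect_true(all(w > 0 & w <= 1))
})

test_that("periodogram concentrates a pure tone and pads to 2^n", {
  # tone at an exact bin: 64 points, 8 cycles, rectangular limit
  n <- 64
  x <- sin(2 * pi * 8 * (0:(n - 1)) / n)
  sp <- periodogram(dl_signal(x, dt = 0.1), kaiser_shape = 0)
  expect_equal(sp$n_fft, 64L)
  expect_gt(sp$power[9] / sum(sp$power), 0.99)  # bin j = 8 (1-based 9)
  expect_equal(sp$frequencies[9], 8 * 10 / 64)
  # 1000-point acquisition pads to 1024
  sp2 <- periodogram(dl_signal(rnorm(1000), dt = 0.1))
  expect_equal(sp2$n_fft, 1024L)
  expect_length(sp2$power, 513L)
  expect_equal(range(sp2$frequencies), c(0, 5))
})

test_that("periodogram matches a brute-force DFT at N = 16", {
  set.seed(11)
  x <- rnorm(16)
  shape <- 3
  sp <- periodogram(dl_signal(x, dt = 0.1), kaiser_shape = shape,
                    center = FALSE)
  w <- kaiser_window(16, shape)
  X <- brute_dft(x * w)
  P_full <- Mod(X)^2 / (mean(w^2) * 16)
  expect_equal(sp$power, P_full[1:9])
  # Parseval-type reassembly: two-sided sum equals normalized energy
  expect_equal(sum(P_full), sum((x * w)^2) / mean(w^2))
})

test_that("instantaneous frequency is the spectral centroid", {
  f <- seq(0, 5, by = 0.5)
  one_bin <- make_spectrum(f, replace(numeric(11), 5, 3))  # all power at 2 Hz
  expect_equal(instantaneous_frequency(one_bin), 2)
  two_bin <- make_spectrum(f, {p <- numeric(11); p[c(3, 7)] <- 1; p})
  expect_equal(instantaneous_frequency(two_bin), 2)  # symmetric 1 and 3 Hz
  set.seed(12)
  p <- runif(11)
  expect_equal(instantaneous_frequency(make_spectrum(f, p)),
               sum(f * p) / sum(p))
  expect_error(instantaneous_frequency(make_spectrum(f, numeric(11))),
               "zero total power")
})

test_that("spectral entropy matches direct Shannon-entropy summation", {
  f <- seq(0, 5, by = 0.5)
  expect_equal(spectral_entropy(make_spectrum(f, replace(numeric(11), 4, 7))), 0)
  f64 <- seq(0, 5, length.out = 64)
  expect_equal(spectral_entropy(make_spectrum(f64, rep(0.3, 64))), 6)
  set.seed(13)
  p9 <- runif(9)
  q <- p9 / sum(p9)
  expect_equal(spectral_entropy(make_spectrum(seq(0, 4, by = 0.5), p9)),
               -sum(q * log2(q)))
  # never exceeds log2(bin count)
  for (i in 1:5) {
    pk <- runif(33)
    expect_lte(spectral_entropy(make_spectrum(seq(0, 16, by = 0.5), pk)),
               log2(33))
  }
})

test_that("approximate entropy equals the brute-force oracle", {
  expect_equal(approximate_entropy(rep(2.5, 30), m = 2, r = 0.1), 0)
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(50)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r), brute_apen(x, 2, r))
  }
})

test_that("approximate entropy ranks periodic below random", {
  set.seed(15)
  for (i in 1:20) {
    per <- rep(c(1, 2), 30) + rnorm(60, 0, 1e-6)
    ran <- runif(60, 1, 2)
    r <- 0.2 * sd(ran)
    expect_lt(approximate_entropy(per, 2, r), approximate_entropy(ran, 2, r))
    expect_gte(approximate_entropy(ran, 2, r), 0)
  }
  expect_error(approximate_entropy(rnorm(3), 2, 0.5), "too short")
  expect_error(approximate_entropy(rnorm(50), 2, -1), "positive")
})

test_that("order statistics follow the stated conventions", {
  expect_equal(median_value(c(3, 1, 2)), 2)
  expect_equal(median_value(c(1, 2, 3, 4)), 2.5)
  expect_equal(mean_deviation(c(1, 2, 3)), 2 / 3)
  expect_equal(quartile_deviation(1:8), 6.75 - 2.25)
  set.seed(16)
  for (i in 1:10) {
    x <- rnorm(sample(5:200, 1))
    expect_equal(median_value(x), median(x))
    qs <- quantile(x, c(0.25, 0.75), type = 6, names = FALSE)
    expect_equal(quartile_deviation(x), qs[2] - qs[1])
    expect_equal(mean_deviation(x), sum(abs(x - mean(x))) / length(x))
  }
})

test_that("extract_features assembles the ten components in order", {
  acq <- acquisition_config(noise_mode = "none")
  truth <- c(I0 = 2907, beta = 0.724, tau = 4.47)
  s <- subtract_background(generate_signal(truth, acq, label = "SW2015"), 9)
  fit <- fit_hyperbolic(s)
  fv <- extract_features(s, fit)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv[1:3]), unname(truth), tolerance = 1e-4)
  expect_equal(unname(fv["E_T"]),
               quad_integral(fit$params["I0"], fit$params["tau"],
                             fit$params["beta"], 100),
               tolerance = 1e-6)
  expect_equal(attr(fv, "label"), "SW2015")
  # deterministic: identical signals give identical vectors
  expect_identical(fv, extract_features(s, fit))
  # ApEn component matches a standalone call at m = 2, r = 0.2 sd
  expect_equal(unname(fv["ap_en"]),
               approximate_entropy(s$values, 2, 0.2 * sd(s$values)))
  expect_equal(unname(fv["median"]), median_value(s$values))
})

test_that("z-score statistics come from training data only", {
  set.seed(17)
  X <- matrix(rnorm(60, 5, 2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  ns <- zscore_fit(X)
  Z <- zscore_apply(X, ns)
  expect_equal(colMeans(Z), c(a = 0, b = 0, c = 0))
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1, c = 1))
  # single-feature arithmetic example
  ns1 <- zscore_fit(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(zscore_apply(3, ns1)), 1)
  # held-out data need not normalize to zero mean (no leakage)
  held <- matrix(rnorm(30, 9, 2), 10, 3)
  expect_gt(abs(mean(zscore_apply(held, ns))), 0.1)
  Xbad <- cbind(X, d = 1)
  expect_error(zscore_fit(Xbad), "d")
})
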