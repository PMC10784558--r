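# Independent oracles, deliberately written as plain double loops /
# direct summations so they share no code path with the implementation.

# Approximate entropy by literal double-loop embedding comparison.
brute_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1L
    logs <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0L
      for (j in seq_len(nv)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      logs[i] <- log(cnt / nv)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1L)
}

# O(N^2) discrete Fourier transform by direct summation.
brute_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(j) {
    sum(x * exp(-2i * pi * j * (0:(n - 1L)) / n))
  }, complex(1L))
}

# Quadrature oracle for the integral of the hyperbolic decay law.
quad_integral <- function(I0, tau, beta, T) {
  stats::integrate(function(t) I0 / (1 + t / tau)^beta, 0, T,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

# Central finite-difference gradient check over a random subset of the
# entries of every parameter. Returns TRUE when for each checked entry
# |analytic - numeric| <= tol_rel * max(|analytic|, |numeric|) or the
# absolute difference is below the finite-difference noise floor.
fd_grad_ok <- function(model, X, Y, lambda, n_train,
                       n_entries = 8L, tol_rel = 1e-5, tol_abs = 1e-9) {
  fw <- bilstm_forward(model, X)
  gr <- bilstm_backward(model, fw, Y, lambda, n_train)
  for (p in names(gr)) {
    th <- model[[p]]
    ks <- sample(length(th), min(n_entries, length(th)))
    for (k in ks) {
      h <- 1e-6 * max(1, abs(th[k]))
      mp <- model; mp[[p]][k] <- th[k] + h
      mm <- model; mm[[p]][k] <- th[k] - h
      lp <- bilstm_loss(bilstm_forward(mp, X)$outputs, Y, mp, lambda, n_train)
      lm <- bilstm_loss(bilstm_forward(mm, X)$outputs, Y, mm, lambda, n_train)
      gn <- (lp - lm) / (2 * h)
      ga <- gr[[p]][k]
      if (abs(ga - gn) > tol_rel * max(abs(ga), abs(gn)) &&
          abs(ga - gn) > tol_abs) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Build a random small model + batch + targets for one head mode.
random_bilstm_case <- function(mode, hidden = 3L, seq_len = 6L, batch = 2L) {
  n_classes <- 5L
  cb <- walsh_codebook(n_classes, 8L)
  out_dim <- if (mode == "onehot") n_classes else cb$order
  model <- new_bilstm(1L, hidden, out_dim, mode)
  X <- matrix(stats::rnorm(seq_len * batch), seq_len, batch)
  lab <- sample(0:(n_classes - 1L), batch, replace = TRUE)
  Y <- if (mode == "onehot") {
    Z <- matrix(0, n_classes, batch)
    Z[cbind(lab + 1L, seq_len(batch))] <- 1
    Z
  } else {
    t(cb$codewords[lab + 1L, , drop = FALSE])
  }
  list(model = model, X = X, Y = Y,
       lambda = stats::runif(1L, 0, 1), n_train = sample(5:50, 1L))
}

# Hand-built spectrum object for feature-level tests.
make_spectrum <- function(frequencies, power) {
  structure(
    list(frequencies = frequencies, power = power,
         window_norm = 1, n_fft = 2L * (length(power) - 1L),
         fs = 2 * max(frequencies), all_zero = all(power == 0)),
    class = "spectrum_estimate"
  )
}

# Shared small fixtures
table1_params <- function() {
  list(
    SW2015 = c(I0 = 2907, beta = 0.724, tau = 4.47),
    SW2016 = c(I0 = 2837, beta = 0.653, tau = 4.46),
    SW2017 = c(I0 = 3080, beta = 0.663, tau = 4.58),
    SW2018 = c(I0 = 3434, beta = 0.796, tau = 3.08),
    SW2019 = c(I0 = 2876, beta = 0.744, tau = 5.63)
  )
}
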