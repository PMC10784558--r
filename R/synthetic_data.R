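#' Per-class generative profile for synthetic DL signals
#'
#' A class profile holds the hyperbolic-decay parameter centers for one
#' storage-year class together with a relative spread (coefficient of
#' variation) that models biological variability across kernels of the
#' same vintage.
#'
#' @param label Class name, e.g. `"SW2015"`.
#' @param mean_I0 Mean initial intensity, counts per bin (> 0).
#' @param mean_beta Mean decay exponent, dimensionless (> 0).
#' @param mean_tau Mean relaxation timescale, seconds (> 0).
#' @param rel_spread Coefficient of variation applied to each parameter,
#'   in `[0, 0.5]`.
#'
#' @return A `class_profile` object.
#' @export
class_profile <- function(label, mean_I0, mean_beta, mean_tau,
                          rel_spread = 0.05) {
  stopifnot(
    is.character(label), length(label) == 1L,
    mean_I0 > 0, mean_beta > 0, mean_tau > 0,
    rel_spread >= 0, rel_spread <= 0.5
  )
  structure(
    list(
      label = label, mean_I0 = mean_I0, mean_beta = mean_beta,
      mean_tau = mean_tau, rel_spread = rel_spread
    ),
    class = "class_profile"
  )
}

#' Default storage-year class profiles
#'
#' Five wheat storage-year classes (SW2015..SW2019) with hyperbolic
#' parameter centers taken from single-sample fits reported for each
#' vintage: I0 in counts/0.1 s, beta dimensionless, tau in seconds.
#'
#' @param rel_spread Coefficient of variation applied to every parameter
#'   of every class (default 0.05; see the methods vignette for the
#'   rationale behind this choice).
#' @return A list of five [class_profile()] objects.
#' @export
#' @examples
#' profs <- default_class_profiles()
#' sapply(profs, `[[`, "label")
default_class_profiles <- function(rel_spread = 0.05) {
  centers <- list(
    list("SW2015", 2907, 0.724, 4.47),
    list("SW2016", 2837, 0.653, 4.46),
    list("SW2017", 3080, 0.663, 4.58),
    list("SW2018", 3434, 0.796, 3.08),
    list("SW2019", 2876, 0.744, 5.63)
  )
  lapply(centers, function(cc) {
    class_profile(cc[[1L]], cc[[2L]], cc[[3L]], cc[[4L]],
                  rel_spread = rel_spread)
  })
}

#' Acquisition configuration
#'
#' Describes the photon-counting acquisition: 0.1-s bins over 100 s
#' (1000 points), a constant instrument background of 9 counts per bin,
#' and the counting-noise model.
#'
#' @param dt Sampling interval in seconds (default 0.1).
#' @param total_time Total acquisition time in seconds (default 100);
#'   `total_time / dt` must be a positive integer.
#' @param background Constant background, counts per bin (default 9).
#' @param noise_mode `"none"` (deterministic expected rates) or
#'   `"poisson"` (integer Poisson draws per bin).
#' @return An `acquisition_config` object with an `n_bins` element.
#' @export
acquisition_config <- function(dt = 0.1, total_time = 100,
                               background = 9,
                               noise_mode = c("poisson", "none")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(dt > 0, total_time > 0, background >= 0)
  n <- total_time / dt
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) {
    stop("total_time/dt must be a positive integer")
  }
  structure(
    list(
      dt = dt, total_time = total_time, background = background,
      noise_mode = noise_mode, n_bins = as.integer(round(n))
    ),
    class = "acquisition_config"
  )
}

#' Draw hyperbolic parameters for one sample
#'
#' Each parameter is drawn independently from a normal distribution with
#' the profile mean and standard deviation `rel_spread * mean`, redrawing
#' any non-positive value so all parameters are strictly positive.
#' Uses the current R random stream; seed externally for reproducibility.
#'
#' @param profile A [class_profile()].
#' @return Named numeric vector `c(I0, beta, tau)`.
#' @export
sample_parameters <- function(profile) {
  stopifnot(inherits(profile, "class_profile"))
  draw1 <- function(mu) {
    sd <- profile$rel_spread * mu
    if (sd == 0) return(mu)
    repeat {
      x <- stats::rnorm(1L, mean = mu, sd = sd)
      if (x > 0) return(x)
    }
  }
  c(
    I0 = draw1(profile$mean_I0),
    beta = draw1(profile$mean_beta),
    tau = draw1(profile$mean_tau)
  )
}

#' Generate one DL signal from hyperbolic parameters
#'
#' For bin k at `t_k = k*dt` (k = 0..N-1) the expected rate is
#' `lambda_k = I0/(1 + t_k/tau)^beta + background`. With
#' `noise_mode = "none"` the expected rates are returned exactly
#' (real-valued); with `"poisson"` each bin is an independent Poisson
#' draw with mean `lambda_k`.
#'
#' @param params Numeric vector or list with elements `I0`, `beta`, `tau`
#'   (all > 0), e.g. from [sample_parameters()].
#' @param acq An [acquisition_config()].
#' @param label Optional class label stored in the signal metadata.
#' @return A [dl_signal()] of `acq$n_bins` bins.
#' @export
#' @examples
#' acq <- acquisition_config(noise_mode = "none")
#' s <- generate_signal(c(I0 = 2907, beta = 0.724, tau = 4.47), acq)
#' s$values[1]  # 2907 + 9 at t = 0
generate_signal <- function(params, acq, label = NULL) {
  stopifnot(inherits(acq, "acquisition_config"))
  params <- as.list(params)
  I0 <- params$I0; beta <- params$beta; tau <- params$tau
  stopifnot(I0 > 0, beta > 0, tau > 0)
  tk <- acq$dt * (seq_len(acq$n_bins) - 1L)
  lambda <- I0 / (1 + tk / tau)^beta + acq$background
  values <- switch(acq$noise_mode,
    none = lambda,
    poisson = as.numeric(stats::rpois(length(lambda), lambda))
  )
  dl_signal(values, dt = acq$dt,
            meta = list(
              label = label,
              params = c(I0 = I0, beta = beta, tau = tau),
              background = acq$background,
              noise_mode = acq$noise_mode
            ))
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` parameter triples per class profile and renders
#' each into a photon-count signal. Fully reproducible from `seed`.
#'
#' @param profiles Non-empty list of [class_profile()]s with distinct
#'   labels.
#' @param n_per_class Number of samples per class (>= 1).
#' @param acq An [acquisition_config()].
#' @param seed Integer seed for the whole dataset.
#' @return List with elements `signals` (list of [dl_signal()]) and
#'   `labels` (character vector, parallel to `signals`).
#' @export
generate_dataset <- function(profiles, n_per_class, acq, seed = 1L) {
  stopifnot(length(profiles) >= 1L, n_per_class >= 1L)
  labels <- vapply(profiles, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("duplicate class labels in 'profiles'")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  signals <- vector("list", length(profiles) * n_per_class)
  out_labels <- character(length(signals))
  k <- 0L
  for (p in profiles) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      pars <- sample_parameters(p)
      signals[[k]] <- generate_signal(pars, acq, label = p$label)
      out_labels[k] <- p$label
    }
  }
  list(signals = signals, labels = out_labels)
}

# RNG-state helpers so seeded generators do not disturb the caller's stream
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
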