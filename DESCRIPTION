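Package: lumigrain
Title: Delayed-Luminescence Signal Analysis and Storage-Year Classification of Wheat
Version: 0.1.0
Authors@R:
    person("Lumigrain", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for nondestructive grain-quality assessment from delayed
    luminescence (DL) photon-count decay signals. Simulates the acquisition
    chain (hyperbolic relaxation decay, Poisson photon counting, constant
    instrument background), preprocesses signals (background subtraction,
    sliding-average smoothing), fits the hyperbolic relaxation law
    I(t) = I0/(1 + t/tau)^beta with goodness-of-fit metrics and the
    closed-form integral intensity, extracts a ten-component feature vector
    (fit parameters plus spectral centroid, spectral entropy, approximate
    entropy, median, quartile deviation and mean deviation), and classifies
    storage-year classes with a from-scratch bidirectional LSTM trained by
    backpropagation through time, using either plain one-hot softmax labels
    or Walsh (Hadamard) error-correcting codeword labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
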