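Package: organicsr
Title: Dynamics and Stability of Recurrent Divisive-Normalization Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing ORGaNICs-style recurrent
    cortical circuits that implement divisive normalization dynamically
    through gain-modulated recurrence. Computes normalization fixed points
    (analytically for identity recurrence, by fixed-point iteration
    otherwise), certifies local asymptotic stability via the quadratic
    eigenvalue problem and M-matrix / diagonal-Lyapunov machinery,
    evaluates the circuit's Lyapunov energy function, runs randomized
    stability sweeps and 2D phase portraits, and provides a discrete-time
    differentiable circuit cell trainable by plain backpropagation through
    time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
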