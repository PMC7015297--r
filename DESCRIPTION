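Package: srfixp
Title: Reduced-Precision Fixed-Point Arithmetic with Stochastic Rounding
    for Spiking-Neuron ODE Solvers
Version: 0.1.0
Authors@R:
    person("srfixp", "maintainers", email = "srfixp@example.org",
           role = c("aut", "cre"))
Description: Bit-exact emulation of generalized <s,i,p> fixed-point
    arithmetic with round-down, round-to-nearest (ties up) and stochastic
    rounding (full-width and k-bit), mixed-format saturating multiplies,
    and three reproducible uniform pseudo-random number generators
    (KISS99, a 33-bit LFSR and the ranqd1 linear congruential generator).
    On top of the arithmetic layer the package provides a testbench for
    solving the Izhikevich spiking-neuron model with unrolled fixed-step
    Runge-Kutta solvers over five arithmetic backends (binary64, binary32,
    and fixed-point with each rounding mode, in 32- and 16-bit format
    sets), bit-error distributions of atomic multiplies, spike-lag
    analysis against a double-precision arithmetic reference, stochastic
    rounding bit-width sweeps and Gaussian input dither experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
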