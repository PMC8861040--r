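Package: twodelay
Title: Two-Delay Differential Equation Models of the Van der Pol
    Oscillator and Parkinsonian Tremor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis for the family of scalar
    delay differential equations dx/dt = a1 x(t-tau1) + a2 x(t-tau2) -
    x(t)^2 (b1 x(t-tau1) + b2 x(t-tau2)), which contains the linear
    two-delay model, a two-delay representation of the Van der Pol
    oscillator, and a cubic feedback model of parkinsonian tremor.
    Provides a fixed-step Runge-Kutta method-of-steps integrator with
    cubic Hermite dense output, Taylor reduction of the delay models to
    the classical second-order oscillator equations, fixed points and
    analytic linearization, transcendental characteristic equations with
    rightmost-root and Hopf-point computation, a registry of ten
    reference parameter cases with a qualitative trajectory classifier,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
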