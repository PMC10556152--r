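Package: wendyr
Title: Weak-Form Estimation of Parameters in Nonlinear Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-solver-free estimation of parameters in systems of
    ordinary differential equations that are linear in their parameters.
    The strong-form model is converted to its weak form using compactly
    supported C-infinity test functions, turning parameter estimation into
    a linear regression. Because the noisy state measurements enter the
    regression matrix itself (an errors-in-variables problem), ordinary
    least squares is refined by an iteratively reweighted least-squares
    scheme driven by a first-order analytic covariance of the weak-form
    residual, with a Shapiro-Wilk residual-normality stopping rule.
    Includes data-adaptive test-function selection via a Fourier aliasing
    estimate of the quadrature error, an orthonormal multiscale basis built
    by SVD, parameter covariance and confidence intervals, a library of
    benchmark models from population biology, neuroscience and biochemistry,
    and a synthetic-data harness for noise-by-resolution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
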