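# wendyr

Direct, forward-solver-free estimation of parameters in ODE systems that are
linear in their parameters, from noisy uniformly sampled trajectories.

## The problem and the method

Many models in population biology, neuroscience and biochemistry take the
form

    du/dt = Θ(u) W,      Θ(u) = [f₁(u) | … | f_J(u)],

where the feature functions f_j (monomials, constants, saturating terms) are
known but the rate coefficients W are not. The conventional route —
repeatedly solving the ODE inside a nonlinear least-squares loop — is slow
and sensitive to solver error and initial guesses, and substituting
derivative estimates of noisy data into the model fails at realistic noise
levels.

This package estimates W directly by testing the equation against smooth,
compactly supported test functions φ (the weak form). Integration by parts
removes the data derivative:

    −∫ φ̇ u dt = ∫ φ Θ(u) W dt,

and discretizing the integrals with trapezoidal quadrature over the sample
grid turns estimation into a linear regression G w ≈ b with

    G = [I_d ⊗ (φ𝒬 Θ(U))],   b = −vec(φ̇𝒬 U).

Because the noisy measurements U enter the regression matrix G itself, this
is an errors-in-variables problem and ordinary least squares is biased. The
estimator therefore linearizes the residual r(U, w) = Gw − b in the
measurement noise, giving an analytic first-order covariance
C(w) = L_w L_wᵀ, and solves a weighted least-squares problem iteratively
(IRLS), reweighting with C at the current iterate. Iteration stops at a
fixed point, at an iteration cap, or when a Shapiro–Wilk test says the
whitened residual C^(−1/2)(Gw − b) has stopped looking Gaussian.

Test functions are built from the data: translates of the C∞ bump
ψ(t; a) = C exp(−η/[1−(t/a)²]₊) at a minimum radius chosen from a Fourier
aliasing estimate of the quadrature error (changepoint of its log against
the radius), stacked over radii m̲_t·(1, 2, 4, 8) and orthonormalized by a
truncated SVD; derivatives are computed spectrally. The response covariance
also yields a parameter covariance (a sandwich formula) and per-parameter
confidence intervals.

Five benchmark systems ship with the package: logistic growth,
Lotka–Volterra, FitzHugh–Nagumo, Hindmarsh–Rose and a five-compartment
protein transduction model (PTB).

## A worked example

```r
library(wendyr)

model <- get_model("logistic")          # du/dt = w1 u + w2 u², w* = (1, −1)
truth <- simulate_truth(model, 512)     # RK45 at tolerance 1e-12
noisy <- subsample_series(corrupt(truth, noise_spec(0.1, seed = 42)), 8)

fit <- wendy_fit(noisy, model)
print(fit)
```

```
<wendy_fit> model logistic: 2 parameters, K = 17 test functions (min radius 6)
  3 reweighting iterations, stopped on fixed_point
 slot state feature  estimate std_err ci_lower ci_upper
    1     1      u1  0.967600  0.1107  0.75065  1.18460
    2     1    u1^2 -0.942527  0.1376 -1.21220 -0.67284
  estimated noise sd: 0.06875
```

With 64 samples carrying 10% noise, both rates are recovered within a few
percent (true values 1 and −1; the relative coefficient error here is
`error_metrics(fit$w_hat, model, compute_efs = FALSE)$E2` ≈ 0.047), the
noise standard deviation is estimated at 0.069 (truth: 0.066), and each
estimate comes with a 95% confidence interval from the learned parameter
covariance. `fit$w_ols` holds the unweighted weak-form solution for
comparison, and `run_trials()` / `summarize_trials()` repeat such
experiments over noise levels, resolutions and seeds.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/wendy.R fit --data series.csv --model logistic --output_dir out
Rscript inst/cli/wendy.R benchmark --model logistic --sigma_nr 0.1 --n_points 64 --n_trials 10
Rscript inst/cli/wendy.R diagnose --data series.csv
```

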