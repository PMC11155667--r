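---
title: "Composite lineshape fitting: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite lineshape fitting: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakfitr)
```

## The problem

Spectroscopic measurements — X-ray absorption near-edge spectra,
photoemission lines, optical absorption bands — are routinely decomposed
into sums of analytic lineshapes so that peak positions, intensities and
widths can be compared across samples. `peakfitr` implements this
deconvolution as bounded nonlinear least squares over a declaratively
specified composite model,

$$ y(x) \;=\; \sum_{m} f_m(x;\,\theta_m) + \varepsilon, $$

where each component \(f_m\) is a peak (Gaussian, Lorentzian,
pseudo-Voigt, Voigt), a step/edge function, or a background term, and
\(\varepsilon\) is treated as homoscedastic noise (the fit statistic is
the unweighted residual sum of squares; the package's target data are
normalized intensities without per-point error estimates).

## Lineshape conventions

All peak models are parameterized by their full width at half maximum
(FWHM) and by an **area** amplitude: the integral of every peak over an
unbounded axis equals its `amplitude` parameter. Area amplitudes make
intensity comparisons meaningful across kinds — a Gaussian and a
Lorentzian with equal `amplitude` carry equal integrated intensity even
though their heights differ. The conversions used are
\(\sigma = \mathrm{fwhmg}/(2\sqrt{2\ln 2})\) for the Gaussian and
\(\gamma_L = \mathrm{fwhml}/2\) for the Lorentzian half width.

The Voigt profile is evaluated through the real part of the Faddeeva
function \(w(z)\) with \(z = (x - c + i\gamma)/(\sigma\sqrt{2})\), where
\(\sigma\) derives from `fwhmv` and `gamma` defaults to `fwhmv/2`. The
implementation uses the complex error function for \(|z| \le 4\) and a
40-level continued fraction beyond, accurate to better than \(10^{-8}\)
across the transition; as \(\gamma \to 0\) it reduces to the Gaussian of
the same FWHM.

The pseudo-Voigt is the standard chemometrics mixture
\(A\,[\eta L(x) + (1-\eta) G(x)]\) with **one shared FWHM** (`fwhmv`) and
an explicit mixing `fraction` \(\eta \in [0,1]\), default 0.5. A
two-width parameterization (separate Gaussian and Lorentzian FWHM) was
the open alternative; the single-width form was chosen because it keeps
the profile a genuine one-parameter interpolation between its limits,
which is what the mixing fraction is usually asked to mean.

Edge jumps are modeled by monotone step functions rising from 0 to
`amplitude` — the cumulative Gaussian is the conventional choice for the
ionization step in X-ray absorption — plus arctangent, error-function,
logistic and Heaviside variants. Missing attributes take the defaults
`amplitude = 1`, `center = 0`, width `= 1`.

## Declarative models and constraint expressions

A model document (JSON, YAML or TOML — all three parse to the identical
project) carries a `settings` block (column names, energy shift and
range, optimizer method and keyword arguments) and a `fitting` block
whose `peaks` map string-integer indices to one lineshape each, every
attribute carrying `{min, max, vary, value, expr}`.

Parameters are registered under deterministic names
`<kind>_<attribute>_<index>`. An `expr` string ties a parameter to an
arithmetic expression of other parameters — the classic use case is a
fixed branching ratio between related peak intensities, e.g.
`"gaussian_amplitude_1 / 2"`. The expression grammar is deliberately
small: the arithmetic operators (`+ - * / **`), parentheses, unary
minus, parameter names and the functions `sin`, `cos`, `exp`, `log`,
`sqrt`, `abs`. Expressions are parsed into an AST that is validated
node-by-node; calls to anything outside the whitelist, indexing,
namespace access or any other construct are refused before evaluation.
Expression-bound parameters are excluded from the free-parameter count
and re-evaluated in topological order (registry order breaks ties);
cycles are reported with the offending names.

## Fitting and uncertainties

The default engine is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), selected by the method names `least_squares`,
`least` or `leastsq`; `nlminb` selects the PORT quasi-Newton minimizer
on the residual sum of squares. Method keyword arguments are forwarded
unmodified. Convergence tolerances default to `ftol = ptol = 1e-12`
with 300 iterations. Optimizer non-convergence is reported as
`success = FALSE` on the result — never as an exception — so the
statistics report can always be printed.

For the least-squares family the covariance of the free parameters is
estimated as \(\hat\sigma^2 (J^\top J)^{-1}\), with \(J\) the numerical
Jacobian of the residual at the optimum (central differences, one-sided
at an active bound) and \(\hat\sigma^2 = \chi^2/(N-k)\); standard errors
are the square roots of its diagonal. For other methods no covariance is
claimed and standard errors stay absent.

Profile confidence intervals (`confidence_intervals()`) step each free
parameter away from its optimum, refit all others, and convert the
\(\chi^2\) increase into a probability with an F statistic
\(F = (\chi^2_f/\chi^2_0 - 1)(N-k)\) on \((1, N-k)\) degrees of freedom;
the bound at each level (default 1, 2, 3 Gaussian sigmas) is located by
bracketing in stderr-sized steps and root finding. A side that cannot be
bracketed — typically a parameter pinned at a box bound — is reported as
`NA` rather than extrapolated. On a linear test model the 1-sigma
profile interval reproduces the analytic regression standard error to
about 1%.

## Simultaneous fitting

When several spectra share one physical model, `fit_simultaneous()`
duplicates every parameter per spectrum (suffix `_s<j>`) and freezes the
peak energies of every spectrum beyond the first onto the first
spectrum's centers through autogenerated identity expressions, so center
values are bitwise equal across spectra at the optimum while amplitudes
and widths stay free. The free-parameter count is therefore
\(nP - (n-1)C\) for \(n\) spectra, \(P\) parameters and \(C\) centers
per spectrum. Whether widths should also be shared is genuinely
ambiguous in practice; they default to free, and `tie_widths = TRUE`
freezes them too. Spectra may live on different grids — residuals are
evaluated per point on each native grid, with no interpolation.

The joint \(\chi^2\)/AIC/BIC are computed on the concatenated residual
with the expanded model's free-parameter count, while regression metrics
(MAE, MSE, RMSE, \(R^2\), explained variance) are computed per spectrum
against its own slice, since they answer a per-spectrum question.

## The statistics suite

Every fit can be summarized in six tables: descriptive statistics of the
input (count, mean, sd, extremes, deciles with linear-interpolation
quantiles), the fit-statistics block, the variables-and-values table,
Pearson correlation among the fitted components, the overall linear
correlation including the abscissa, and the regression metrics.

AIC and BIC use the least-squares likelihood form
\(\mathrm{AIC} = N\ln(\chi^2/N) + 2k\),
\(\mathrm{BIC} = N\ln(\chi^2/N) + k\ln N\), so
\(\mathrm{BIC} - \mathrm{AIC} = k(\ln N - 2)\) identically; \(\chi^2\)
is floored at \(10^{-250}\) before the logarithm so a numerically
perfect fit yields a finite documented sentinel instead of \(-\infty\).
Correlation entries for zero-variance series are reported as undefined
(`NA`), never silently zero. A metric ledger (`metric_history()`)
records a configurable metric list — default AIC, BIC, MSE — per fit
cycle so successive model refinements can be compared.

## Synthetic data: what it emulates, and what it does not

`make_xas_pair()` generates two 146-point spectra on a 7105–7130 eV grid
in the shape class of a transition-metal K-edge: two weak pre-edge
Gaussians (7112.6, 7114.4 eV; areas 0.055 and 0.070), three
rising-edge/charge-transfer Gaussians (7117.2, 7120.0, 7125.6 eV) and a
cumulative-Gaussian edge jump (7122.3 eV, area 1), plus homoscedastic
Gaussian noise of sd 0.005 on the normalized-intensity scale. The two
spectra share all centers by construction while the second's peak
amplitudes are scaled by 1.2 — the situation simultaneous fitting is
designed for. All constants are synthetic package choices, documented as
such.

The component layout was chosen so the composite is statistically
well-posed: the broad rising-edge peaks and the edge step are separated
by at least ~2 eV, which keeps the Fisher information matrix
well-conditioned and makes the asymptotic standard errors meaningful. An
earlier, more congested layout (a broad peak nearly coincident with the
step) produced a practically unidentifiable parameter subspace — a
useful reminder that coverage statements are statements about the
model–data geometry, not just about the optimizer. Under the shipped
defaults, all twelve true centers of a pair fall within three reported
standard errors in ~98% of seeded replicates, and noiseless spectra are
recovered to machine precision from truth initialization.

What the generator does **not** emulate: energy-dependent (e.g.
counting) noise, instrument lineshape asymmetry, background curvature,
multiplet structure, or calibration drift between spectra. Tests passing
on this generator therefore demonstrate the correctness of the fitting
and statistics machinery under the stated noise model, not robustness to
every artifact of real beamline data.

`six_gaussian_truth()` provides a separate model-selection benchmark:
six partially overlapping Gaussians (amplitudes 0.6–1.0, FWHM 1.0–1.3)
on a 200-point grid with noise sd 0.02, i.e. a few percent of the
smallest peak height — a realistic signal-to-noise for normalized
spectra. Fitting nested models with 4–7 peaks (smaller models drop the
lowest-amplitude truth peaks; the larger one adds a low-amplitude extra
peak) and comparing BIC selects the true six-peak model in essentially
all replicates: missing a real peak costs far more than \(\ln N\) per
parameter, while a seventh peak only chases noise.

## Reproducibility: the lock report

`write_lock()` exports the entire fitting project — input echo, data,
results — as one TOML document whose `id` is a SHA-256 over a canonical
rendering: keys sorted, floats at 17 significant digits, the `id` and
`timestamp` fields excluded. Seventeen significant digits round-trip
IEEE doubles exactly, so write → read → write is byte-stable and the ID
is independent of key order and whitespace in the file; re-exports of
identical science carry identical IDs, and any value perturbation — down
to \(10^{-9}\) in one intensity — changes the ID. Verification
(`verify_lock()`) distinguishes a tampered file (parses, hash mismatch)
from a damaged one (parse error). The TOML subset used (tables, arrays
of tables, inline arrays, strings/numbers/booleans with `inf`/`nan`) is
written and parsed by the package itself.

## Numerical choices and degenerate inputs

* Spectra must be strictly increasing in the abscissa after ingestion;
  descending files are sorted with a notice, duplicate abscissa values
  keep the first occurrence with a warning (fitting needs a
  function-like sample), and non-numeric rows are dropped with a count.
* The energy shift applies before the range window in `preprocess()`,
  which is idempotent for fixed arguments.
* Under-determined problems (points ≤ free parameters) and zero degrees
  of freedom raise classed errors instead of producing misleading
  statistics.
* Problem sizes used throughout the test suite — 146-point pair fits at
  50 replicates, 25 model-selection ladders — were chosen to give stable
  rate estimates while keeping a full run in well under a minute for the
  heavy checks.

## Known limitations

Weighted fits (per-point uncertainties) and robust loss functions are
out of scope, as are 2D lineshapes and instrument convolution kernels
beyond the Voigt profile. Profile confidence intervals assume an
otherwise unconstrained, converged model; parameters at bounds report
one-sided non-convergence. The AIC/BIC convention matches least-squares
likelihood fitting; values are comparable within this package (and to
tools using the same convention), not across arbitrary likelihood
definitions.
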