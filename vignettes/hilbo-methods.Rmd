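---
title: "Methods: human-in-the-loop optimization of step frequency against metabolic cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: human-in-the-loop optimization of step frequency against metabolic cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hilbo)
```

`hilbo` implements an online search over walking step frequency driven by
breath-by-breath metabolic measurements, the gradient-descent method it is
compared against, and the post-hoc analyses that score both. This vignette
documents the models, the tunable constants and why they have the values
they do, the numerical choices, and what the synthetic subject does and
does not capture.

## Measurement model

Indirect calorimetry yields per-breath O2 uptake and CO2 production rates.
These convert to metabolic power via the Brockway linear combination
(16.58 J per mL O2, 4.51 J per mL CO2; `brockway_coefficients`, overridable).
The measured respiratory response lags the true energetic demand; we model
the lag as a first-order discrete recursion over breaths,

$$ r_i = \left(1 - \tfrac{h_i}{\tau}\right) r_{i-1} + \tfrac{h_i}{\tau}\, c, $$

with $h_i$ the inter-breath interval and $\tau = 42$ s. Solving for the
drive gives the per-breath *instantaneous cost*

$$ c_i = r_{i-1} + \tfrac{\tau}{h_i}(r_i - r_{i-1}), $$

implemented in `invert_dynamics()`. Two conventions are fixed here and
verified by round-trip tests: the first breath seeds the state (the
recursion needs an initial condition, so inversion starts at breath two),
and the inversion is exact — `invert_dynamics(forward_response(...))`
recovers any drive sequence to machine precision on any valid breath
schedule.

Inversion amplifies noise. Writing $k = \tau/h$, each inverted sample is
$(1-k)r_{i-1} + k\,r_i$, so i.i.d. breath noise of SD $s$ inflates to
$s\sqrt{(1-k)^2 + k^2} \approx \sqrt{2}\,k\,s$ for $\tau \gg h$ — about an
order of magnitude at typical breathing rates. Downstream estimators
therefore average: `estimate_cost_zero_order()` is the OLS constant fit
(mean) of the inverted samples over a 40-breath window, and
`estimate_cost_linear()` regresses them on measured step frequency to get
the slope $\lambda_1$ and intercept $\lambda_0$ of the linear cost model
$c(x) = \lambda_1 x + \lambda_0$. The default linear fit is plain OLS on
inverted samples; a forward-model least-squares route (fit $\lambda$ by
minimizing squared error on the raw response) is available via
`method = "forward"` and agrees exactly on noiseless data. No outlier
rejection is applied by default (an optional 3-SD trim exists), since the
estimators are already averaging and trimming would complicate the noise
accounting.

Step frequency is read from thigh flexion angle: stride time is the
interval between consecutive angle maxima, step frequency twice its
reciprocal (left/right symmetry assumed), averaged over the most recent
two strides (four steps). The detector smooths with a short symmetric
moving average (0.1 s — well above the sampling period, well below a
stride), enforces a 0.3 s refractory period, and discards peaks whose
topographic prominence is under 10% of the signal range. The smoothing
window is odd-length and symmetric so peak positions do not shift;
refractory and prominence guards prevent double-counting on noisy signals.

## The Gaussian-process surrogate

Costs over step frequency are modelled as a GP with squared-exponential
kernel $k(x,x') = \sigma^2 \exp(-(x-x')^2/2l^2)$ and i.i.d. observation
noise $\sigma_n^2$. The noise variance enters the Gram matrix diagonal
once — adding it to every kernel entry *and* to the posterior's
$K + \sigma_n^2 I$ would double-count it — and the reported predictive
variance is the latent function-value variance without the noise term,
because the acquisition targets the underlying cost, not a future noisy
measurement.

The prior mean is zero, but raw metabolic costs are far from zero, so `y`
is centered by its sample mean before conditioning and the offset restored
in predictions (`center = TRUE`, overridable). Hyperparameters maximize
the log marginal likelihood by bound-constrained L-BFGS-B over
log-parameters with analytic gradients, restarted from 10 initializations
drawn log-uniformly within the bounds; the bounds scale with the data
($l \in [0.02, 2] \times$ domain width, $\sigma^2 \in [10^{-4}, 10^2]
\times \mathrm{var}(y)$, $\sigma_n^2 \in [10^{-6}, 1] \times
\mathrm{var}(y)$, with $\mathrm{var}(y)$ falling back to 1 when
degenerate). A jitter of $10^{-10}\,\mathrm{tr}(K)/n$ stabilizes the
Cholesky factorization. Posterior and likelihood are verified against a
dense explicit-inverse oracle to $10^{-8}$ relative error.

## The two optimizers

**Bayesian optimization.** Three initial frequencies are drawn uniformly,
one from each third of 75–125% of the preferred cadence (75–91.7%,
91.7–108.3%, 108.3–125%), presented in random order. Each evaluation is a
40-breath zero-order cost estimate. After every evaluation (from $n = 2$
onward) hyperparameters are refit; the next command maximizes expected
improvement, $EI = s_*(u\Phi(u) + \phi(u))$ with
$u = (\mu_{best} - E[c_*])/s_*$ and $EI \equiv 0$ where $s_* = 0$. The
incumbent $\mu_{best}$ is the minimum *posterior mean* over evaluated
points — with noisy estimates the minimum raw observation is biased low.
The acquisition is maximized by multi-restart local search (10 random
starts, both endpoints, and the best point of a 1001-point screening grid,
each refined by L-BFGS-B); exact ties break to the lowest frequency for
determinism, and if EI is numerically zero everywhere the maximum-variance
point is proposed. The search domain is 75–125% of preferred — the
envelope of the initial design — which is an assumption, since only the
initial-design intervals are prescribed; proposals are clipped to it. The
default budget is 3 initial + 17 EI evaluations (20 total); the bout
structure could also be read as 20 EI iterations after initialization,
so the count is configurable (`bo_config(n_iterations = )`).

**Gradient descent.** Initialized at 20% above or below preferred (sign by
seeded coin flip), 15 iterations. Each iteration walks 30 breaths at 5%
below then 5% above the current command; the linear cost model is fitted
across all 60 breaths and its slope $\lambda_1$ is the gradient estimate —
under the linear model this equals the symmetric finite difference across
the two perturbed frequencies exactly, which also makes the
commanded-vs-measured distinction at the perturbed points immaterial. The
update is $x_{n+1} = \mathrm{clip}(x_n - \alpha_n \lambda_1)$ with
$\alpha_n = A_0\alpha_0/(A_0 + n\gamma)$, $A_0 = 3$,
$\alpha_0 = 4\times10^{-4}$ Hz·(mL/min)$^{-1}$, $\gamma = 1$. The units of
$\alpha_0$ imply costs expressed as an O2-rate equivalent, so the GD
evaluator works in gross mL O2/min (gross power divided by 20.1/60 W per
mL/min, the standard gross energetic equivalent of oxygen); a watt-based
mode exists (`gd_config(cost_units = "W")`).

## Post-hoc analyses

The landscape baseline simulates the nine-condition sweep (preferred ±5,
10, 15, 25%, order randomized), averages power over the final two minutes
of each six-minute bout, subtracts the standing mean (same windowing, for
consistency), normalizes by mass, and fits a GP; the posterior-mean argmin
is located on a 2001-point grid refined by golden-section search to
$10^{-4}$ Hz, ties to the lowest frequency.

Termination criteria are applied post hoc to logged trajectories: the run
converges at the first iteration $j \ge 2$ with
$|x_j - x_{j-1}|/x^{pref} < \epsilon_{sf}$ (step-frequency kind;
thresholds 1% for BO, 0.41% for GD) or $|c_j - c_{j-1}|/|c_{j-1}| <
\epsilon_{mc}$ (cost kind, 2%, read as a relative change since the
threshold is dimensionless). For BO only EI-driven evaluations count as
iterations; the initial design's duration can be included in the reported
time (both times are reported, EI-only being the default comparison
column). Percent errors at convergence divide by the preferred frequency
for both the sweep-fit and preferred references, keeping the two columns
on one dimensionless scale (the reference-relative alternative is a flag).
Energy expenditure integrates the landscape's net cost at each visited
frequency over iteration durations (J → kcal by 4184); a gross flag adds
the standing cost back, since the integration could be read either way.

Iteration durations come from simulated breath counts at the subject's
breath rate — about 2.2 min per 40-breath BO evaluation and 3.3 min per
60-breath GD iteration — and rest periods are excluded from
time-to-convergence, which compares active optimization time.

## The synthetic subject

`subject_profile()` fixes the study conditions:

| parameter | default | rationale |
|---|---|---|
| net landscape | $3.0 + 16\,d^2$ W/kg, $d$ = relative deviation | +1 W/kg at ±25% cadence; bowl magnitudes typical of treadmill walking (an optional cubic term mimics skewed landscapes) |
| landscape argmin | at preferred cadence | sweep-fit optima cluster near preferred |
| standing cost | 1.5 W/kg | typical quiet standing |
| $\tau$ | 42 s | the time constant used throughout |
| breath rate | 0.3 breaths/s, interval SD 0.5 s, floor 1 s | upper end of the stated 0.2–0.3 physiologic range, consistent with 40 breaths ≈ 2 min; truncated-normal intervals |
| breath noise | 0.31 W/kg per breath | calibrated by Monte Carlo so the 40-breath zero-order net estimate has SD ≈ 0.2 W/kg — the one bridging constant between breath-level noise and realistic estimate noise, fixed a priori |
| tracking error | 2% SD per breath | imperfect metronome following |
| cohort | $x^{pref} \sim U(1.7, 2.0)$ Hz, mass $\sim N(65.8, 9.7^2)$ kg truncated positive | young healthy cohort anthropometrics |

Bouts carry respiratory state: runs start from the preferred-cadence
steady state (a warm-up walk), consecutive bouts chain their state, and a
rest of five minutes or more is modelled by resetting to `state = NULL`.
The short (~2 min) rests between sweep bouts are not simulated; the
two-minute averaging window sits late enough in each six-minute bout that
the carried-over transient is negligible there.

What the simulator deliberately omits: cardiovascular drift, adaptation
and fatigue (the landscape is stationary), respiratory-exchange-ratio
dynamics, asymmetric gait, and any structure in the breath noise beyond
additive i.i.d. Gaussian (chosen to match the GP's noise assumption).
Passing tests therefore demonstrate correctness of the algorithms and
their behavior under the stated noise model — not robustness to
nonstationary human physiology, which is a known limitation of the
surrogate and of stationary-GP approaches generally.

## Simulation study sizes and reproducibility

The packaged simulation study (`cohort_benchmark()`, also run by
`scripts/acceptance.R`) uses 25 replicate cohorts of 8 subjects — 200
runs per method — with all seeds derived deterministically from one master
seed; the test suite uses the same machinery with smaller replication for
the property checks (e.g. 20 seeds for noiseless recovery, 20 per noise
level for the degradation ordering). Convergence-iteration means are
taken over converged runs; runs that never meet a threshold within the
iteration budget are reported as non-converged rather than imputed, and
the convergence rates are reported alongside. Every stochastic path
consumes R's global generator, so a single `set.seed()` (or the
`--seed` flag) reproduces a run byte for byte; nothing reads the wall
clock.

```{r, eval = FALSE}
bench <- cohort_benchmark(n_subjects = 8, n_seeds = 25, seed = 1)
summarize_benchmark(bench)
```
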