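# hilbo

Human-in-the-loop optimization of a gait parameter — walking step
frequency — against metabolic cost measured breath by breath.

## The problem

Tuning a wearable device (or, as here, a walking cadence) to minimize a
person's metabolic cost is hard because the objective is expensive and
noisy: cost must be inferred from respiratory gas exchange, each estimate
takes minutes of walking, and the respiratory signal lags the true
energetic demand with a time constant of roughly 42 s. `hilbo` implements
and compares two online search strategies around that measurement model,
together with the synthetic subject needed to study them end to end
without human data:

* **Cost estimation.** Breath-by-breath VO2/VCO2 is converted to
  metabolic power with the Brockway equation,
  `P = (16.58 · V̇O2 + 4.51 · V̇CO2) / 60` W. The *instantaneous* cost
  `c` driving the lagged respiratory response `r_i` is recovered by
  inverting the first-order dynamics
  `r_i = (1 − h_i/τ) r_{i−1} + (h_i/τ) c`, where `h_i` is the time since
  the previous breath. A constant (zero-order) fit of the inverted
  samples feeds the Bayesian optimizer; a linear fit
  `c(x) = λ1 x + λ0` over paired perturbed frequencies feeds gradient
  descent.
* **Bayesian optimization.** A Gaussian process with squared-exponential
  kernel `k(x,x′) = σ² exp(−(x−x′)²/2l²)` plus i.i.d. observation noise
  σn² models cost over step frequency; hyperparameters maximize the log
  marginal likelihood (10 random restarts). The next frequency maximizes
  expected improvement `EI = s*(uΦ(u) + φ(u))`, `u = (μ_best − E[c*])/s*`,
  with the incumbent `μ_best` the minimum posterior mean over evaluated
  points. Three random initial frequencies cover 75–125% of the preferred
  cadence.
* **Gradient descent.** The comparator estimates the cost slope from ±5%
  perturbations (30 breaths each) and steps
  `x_{n+1} = x_n − α_n J_n` with the schedule
  `α_n = A0 α0 / (A0 + n γ)`, `A0 = 3`, `α0 = 4·10⁻⁴` Hz·(mL/min)⁻¹,
  `γ = 1`, from a ±20% initialization.
* **Post-hoc analysis.** A nine-condition discrete grid search
  (preferred ±5, 10, 15, 25%), averaged over the last two minutes per
  bout, standing-subtracted and mass-normalized, is fit with a GP; its
  argmin is the baseline "sweep fit" optimum. Termination criteria on
  iteration-to-iteration change in commanded frequency (or cost) give
  iterations/time to convergence, percent error and integrated energy
  expenditure.
* **Synthetic subject.** A quadratic net-cost bowl (3 W/kg at the
  optimum, +1 W/kg at ±25% cadence), standing cost 1.5 W/kg, first-order
  respiratory lag, irregular breaths (0.3 breaths/s), additive breath
  noise calibrated so a 40-breath cost estimate has SD ≈ 0.2 W/kg, and
  imperfect metronome tracking.

## Worked example

```r
library(hilbo)

subj <- subject_profile(x_pref = 1.85, mass = 70)   # synthetic subject

# Day 1: discrete grid search -> landscape baseline
grid <- run_condition(subj, "grid", seed = 42)
grid$landscape
#> <hil_landscape> 9 conditions over 1.39-2.31 Hz, argmin 1.860 Hz (3.06 W/kg net)

# Day 2: Bayesian optimization, then apply the 1% step-frequency criterion
bo <- run_condition(subj, "bo", seed = 43, landscape = grid$landscape)
bo$reports$step_frequency
#> <convergence_report> bo / step_frequency eps = 1%: converged at iteration 4 (9.1 min), x = 1.943 Hz

head(as.data.frame(bo$trajectory)[, c("iter", "phase", "x_cmd", "cost")], 4)
#>   iter phase    x_cmd     cost
#> 1    1  init 1.537053 4.611702
#> 2    2  init 1.976653 4.431048
#> 3    3  init 2.021949 4.493592
#> 4    4    ei 1.936848 4.390086
```

The landscape argmin (1.860 Hz) sits next to the subject's true optimum
(1.85 Hz, its preferred cadence); BO's commanded frequency settles within
four EI-driven evaluations, about 9 minutes of simulated walking, and the
report carries the percent error against the sweep fit (4.5% here) and
the energy expended getting there. `run_condition(subj, "gd", ...)` runs
the gradient-descent day; `compare_methods(n, seed)` runs all three
conditions over a whole synthetic cohort.

A command-line wrapper (`inst/scripts/hilbo`) exposes the same
operations: `hilbo synth`, `hilbo run`, `hilbo analyze`,
`hilbo compare`.

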