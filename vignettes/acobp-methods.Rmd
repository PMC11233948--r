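---
title: "Hybrid ant-colony / backpropagation training for exercise-load models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ant-colony / backpropagation training for exercise-load models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acobp)
```

## The problem

Athlete monitoring programmes collect panels of physiological indicators —
heart rate, blood lactate, blood urea, urinary protein, training volume —
and want a single continuous *exercise-load score* predicted from them. No
single biochemical marker tracks load reliably, so the mapping from
indicators to load is treated as an unknown smooth nonlinear function and
fitted with a small three-layer feedforward network (`t` inputs, one
hidden layer of `g` sigmoid units, a linear output).

Backpropagation (BP) fits such a network by gradient descent, but on small
noisy panels it is sensitive to its random starting weights and prone to
local minima. The remedy implemented here initialises BP with a *global*,
gradient-free search: an ant colony explores a discretised weight space and
hands its best weight vector to BP for fine-tuning.

## The ant system

The optimiser is the basic ant system. A solution is built component by
component; the probability of picking component $i$ from the allowed set is

$$p_i \propto \tau_i^{\alpha}\,\eta_i^{\beta},$$

where $\tau_i$ is the pheromone on the component, $\eta_i$ a prior
"visibility" (for tours, inverse distance), and $\alpha,\beta$ importance
exponents. After each cycle every pheromone decays by the evaporation
fraction $\rho\in(0,1)$ and completed solutions deposit pheromone on the
components they used:

$$\tau' = (1-\rho)\,\tau + \textstyle\sum_l \Delta\tau_l .$$

Two conventions exist for this update — residual factor $1-\rho$
versus persistence factor $\rho$ — and they coincide under
$\rho_{\text{persistence}} = 1-\rho_{\text{evaporation}}$; the package
standardises on the evaporation form.

**Deposit normalisation.** The classic ant-cycle deposit is $Q/c_l$ for an
ant with cost $c_l$ ("the shorter the path, the more pheromone").
Tour lengths are order 10, but training mean-squared errors are order
$10^{-3}$–$10^{-1}$, so a raw $Q/c$ deposit would exceed the unit initial
pheromone by 10–1000× after a single cycle and freeze the colony on the
first passable solution it finds. `run_colony()` therefore normalises by
the cycle's best cost,

$$\Delta\tau_l = Q\,\frac{c^{\text{cycle}}_{\min}}{c_l},$$

so the cycle's best ant deposits exactly $Q$ (default 1) and worse ants
deposit proportionally less. This is scale-free — the same rule drives
tours and weight search — and it preserved both oracle properties in
testing (exhaustive tour optimum recovered in 20/20 seeded runs;
exhaustive grid optimum in 50/50).

Remaining defaults: uniform initial pheromone $\tau_0 = 1$ (no path is
preferred before evidence), floor $\tau_{\min}=10^{-9}$ (no component
becomes permanently unreachable), evaporation $\rho = 0.5$ (a common
basic-ant-system value; a development sweep showed the oracle properties
are insensitive between 0.2 and 0.5), colony size 30.

## Weight search and fine-tuning

Each of the network's $g(t{+}1) + p(g{+}1)$ parameters (biases included)
gets the same candidate set: the interval $[-3, 3]$ divided into $k = 50$
evenly spaced values, endpoints included. An ant selects one candidate per
slot using the pure-pheromone rule ($\beta = 0$; no heuristic term exists
for weight values), the assembled network is scored by training MSE, and
deposits reinforce the chosen (slot, candidate) pairs. With uniform initial
pheromone the first cycle samples every candidate with probability $1/k$.

The best weight vector after 50 colony cycles (a package default) seeds
full-batch gradient
descent, which runs until the training MSE reaches the target `R_0`
(default 0.004) or the iteration cap `Y_BP` (default 13000). The
discretisation error of the 50-point grid is exactly what this phase
removes.

**Why the hybrid's fine-tuner defaults to momentum.** Candidate values as
large as ±3 can saturate hidden sigmoids, and plain gradient descent
crawls on saturated units: in the package's benchmark the plain-BP
baseline overtook a plain-BP fine-tune of the ant start by iteration 800.
With the standard momentum update
($v \leftarrow 0.9v - \eta\,\nabla$, $w \leftarrow w + v$) the hybrid
retains its head start, and the expected ordering — hybrid below
momentum-BP below plain BP at matched checkpoints — held at the final
checkpoint in 20-replicate paired comparisons at three independent panel
seeds. Plain and momentum BP baselines initialise uniformly on
$[-0.2, 0.2]$.

Other training choices fixed here: logistic-sigmoid
hidden units with a linear output (targets are min–max normalised to
$[0,1]$; a linear output avoids saturation at the range ends); full-batch
gradients (the panels have ~140 training rows, and full batch makes error
traces deterministic per iteration); learning rate 0.3; divergence guard
aborting with an error if the training MSE turns non-finite or exceeds
$10^6$. Reported results use best-so-far semantics: the returned
parameters are the best visited, so the final error never exceeds the
ant-phase incumbent.

Hidden-layer sizing follows the usual empirical rules, default
$g = \mathrm{round}(\sqrt{t+p}) + \alpha$ with $\alpha \le 10$ (default 4);
$\lceil \log_2 t\rceil$ and $\mathrm{round}(\sqrt{tp})$ are selectable, as
are the literal forms $t+1+\alpha$ and $tp$ for completeness.

## Preprocessing

The chain mirrors standard practice for small monitoring panels:

* **Imputation** — monitoring rows are time-ordered, so missing cells are
  linearly interpolated along row order, with nearest-value fill at the
  boundaries. Idempotent.
* **Min–max normalisation** — $(x-\min)/(\max-\min)$ per column, with the
  fitted state kept so predictions can be mapped back exactly
  (round-trips are exact to machine precision). A train-fitted scaler
  applied to test data can produce values outside $[0,1]$; that
  extrapolation is deliberate and invertible. Constant columns map to 0.
* **Log transform** — $\log(x + \text{offset})$ for right-skewed markers.
* **PCA feature selection** — projection onto leading principal
  components; when no count is given, the smallest set explaining ≥ 95%
  of variance is kept.
* **Outliers** — flagged at $|z|>3$ per column but never removed
  automatically; removal is left to the analyst's judgement.
* **Split** — seeded shuffle into 140 training / 14 test rows for the
  154-row design.

## The synthetic panel

Real athlete panels of this kind are rarely shareable, so the generator
emulates their shape: `n_rows = 154` records; six indicator columns, i.i.d. uniform
on $[0,1]$; a pinned smooth nonlinear latent load

$$f(x) = 0.3\,\sigma(4(x_1{-}0.5)) + 0.3\,x_2x_3 + 0.1\sin(\pi x_4)
+ 0.2\,x_5$$

clipped to $[0,1]$ (a saturating term, an interaction, a periodic bump and
a linear term — enough structure that a three-layer net is needed, smooth
enough that it suffices); Gaussian noise with `noise_sd = 0.02` on the
latent scale; an affine map onto the load scale $(8.5, 10)$, matching the magnitude of
typical athlete load scores (~9); and 2% missing feature cells.
The sixth indicator never enters $f$ — a deliberate nuisance feature so
feature selection and the significance harness have signal-versus-noise
structure to find.

What the generator does *not* emulate: correlated indicators, measurement
drift, heteroscedastic noise, or physiologically mechanistic lactate /
heart-rate dynamics. Tests passing on these panels show the pipeline
recovers a smooth low-dimensional relationship at this sample size and
noise level; they do not certify performance on real athlete data.

**Measuring recovery.** The recovery experiment trains on the noise-free
and the noisy panel (seed 42, 140/14 split) with a single protocol —
momentum 0.9, target error $10^{-5}$, cap 13000 — training essentially to
convergence, because the question is how well the latent relationship is
recovered, not where the operational stopping rule lands. On the noise-free
panel the normalised test MSE is the natural scale. On the noisy panel,
test RMSE is compared against `noise_sd`, which is defined on the latent
$[0,1]$ scale; since min–max refitting of a noisy target stretches that
scale by roughly 1.6× (and the 14 test rows' own noise realisation then
already exceeds any sensible bound before model error enters), the
comparison is made in `noise_sd`'s own units: predictions are denormalised
to the load scale and divided by the generator's span (1.5). The suite
checks RMSE ≤ 2 × `noise_sd` there.

## Evaluation and reporting

* `compare_trainers()` reports mean best-so-far training MSE per trainer
  at iteration checkpoints (default 200/600/800), replicated over derived
  seeds and paired across trainers. Checkpoints count BP iterations; the
  ant phase runs inside its own budget beforehand.
* `prediction_report()` lists per-sample outputs and signed errors on the
  normalised scale with the convention *error = prediction − target* (an
  over-prediction has a positive error), plus denormalised point
  predictions.
* `parameter_significance()` runs the model at a low and a high setting of
  each parameter (others fixed), collects an outcome per replicate, and
  applies Welch's two-sample t-test at level 0.05 — Welch rather than
  pooled because nothing guarantees equal variances across settings. Both
  groups constant and equal yields $p = 1$ by convention. The harness
  accepts any objective function; `surrogate_objective()` is a cheap
  stochastic stand-in used to verify the false-positive rate is ~5% under
  the true null (1000 harness repetitions in the suite).

## Numerical and design notes

* All randomness is scoped with `withr::with_seed`; identical seed,
  configuration and data give bit-identical traces, and saved models
  (JSON at 17 significant digits) reload to bit-identical predictions.
* The hidden-node sizing rules are sometimes quoted without their radical
  signs ($g = t+1+\alpha$, $g = tp$); the standard square-root forms are
  the defaults and the literal variants remain selectable.
* The exhaustive travelling-salesman oracle fixes city 1 first and
  enumerates the rest (closed tours are rotation-invariant); it is capped
  at 10 cities.
* Problem sizes in the test suite — 100 gradient-check cases, a 6-city
  tour fixture with 20 seeded colonies, a 16-combination weight grid over
  10 seeds, 20-replicate trainer comparisons, 1000 calibration repetitions
  on the surrogate — were chosen so the whole suite completes in a couple
  of minutes while leaving each property statistically meaningful.

## Limitations

* One hidden layer only, regression head only; no variable-learning-rate
  BP; no elitist / rank-based / max–min ant variants.
* The ant phase's advantage is an empirical property of small networks on
  small panels; on easier problems plain BP from small random weights can
  match it, and the package makes no claim beyond the benchmarked regime.
* The latent-scale reading of the noisy recovery depends on knowing the
  generator's target span; with real data one would compare against an
  external noise estimate instead.
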