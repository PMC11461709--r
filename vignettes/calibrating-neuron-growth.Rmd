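---
title: "Calibrating resource-driven neuron growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating resource-driven neuron growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`abcgrow` grows three-dimensional neuron morphologies from stochastic,
agent-based rules and infers the rules' parameters from observed
morphologies by likelihood-free Bayesian calibration. This vignette is the
package's account of the science: the growth models and their assumptions,
the morphometric reduction, the statistical distances and the sequential
Monte Carlo ABC sampler, the sensitivity analysis, and the design and
numerical decisions taken where the problem left them open.

## The growth models

A simulated neuron starts as a spherical soma with a few short neurite
stubs. Neurites are discretised into cylindrical agents holding a scalar
*resource* `r`; an agent with no daughters is a *tip*, and only tips act.
Time advances in discrete steps. At each step every *active* tip (one with
`r > r_min`):

1. **elongates** along the unit vector
   $\vec d \propto w_\mathrm{rand}\,\vec u + w_\mathrm{old}\,\vec o +
   w_\mathrm{grad}\,\widehat{\nabla\phi}$,
   a persistent, biased random walk mixing an isotropic random direction
   $\vec u$, the tip's current orientation $\vec o$, and the normalised
   gradient of an external guidance cue $\phi$; the endpoint moves by
   $v\,\vec d$ and the resource drops by $R$;
2. **branches** with probability `p_bra`, independently of elongation.

The two models differ only in the branching rule:

* **Model 1 (symmetric bifurcation, basal-like):** the tip is replaced by
  two daughters deflected by $\pm\theta_b$ from its orientation within a
  random plane; *both inherit the mother's resource*. Resource-sharing is
  symmetric, so the tree is balanced.
* **Model 2 (asymmetric side-branching, apical-like):** the tip continues
  straight (inheriting resource and orientation) and sprouts a lateral
  daughter deflected by $\theta_s$ whose resource is *reset to the fixed
  value* `r_0`. In addition every agent in Model 2 loses $R$ per step
  (global decay), clamped at the floor `r_min - R`. The asymmetric
  allocation produces a dominant main branch with short lateral
  outgrowths.

Agents longer than `l_max` are split into two collinear halves purely as a
discretisation device; all morphometrics are invariant to this splitting
(see below). Resources never increase, so idleness (`r <= r_min`) is
absorbing. The built-in guidance cue is linear, $\phi(x) = \langle x,
g\rangle$ with constant gradient $g = (0,0,1)$ — the simplest attractant
consistent with apical growth away from the soma; the field interface
evaluates `value` and `gradient` at arbitrary points so other
time-invariant linear cues can be configured by direction.

### Parameters, units, defaults

| parameter | meaning | unit | default (Model 2 / Model 1) |
|---|---|---|---|
| `p_bra` | branching probability per tip per step | – | 0.038 / 0.01 |
| `R` | resource consumed per elongation or decay event | resource/step | 7.1e-4 / 4e-3 |
| `v` | elongation length per step | length/step | 100 / 50 |
| `r_init` | initial stub resource | resource | 1.0 |
| `r_min` | idle threshold | resource | 0.1 |
| `r_0` | side-branch initial resource (Model 2) | resource | 0.12 |
| `n_steps` | simulated steps ($T = n_\mathrm{steps}\,\Delta t$) | – | 500 |
| `w_rand, w_old, w_grad` | walk weights | – | 0.4, 0.5, 0.1 |
| `theta_bifurcate_deg` | Model-1 daughter half-angle | degrees | 30 |
| `theta_side_deg` | Model-2 side-branch deflection | degrees | 60 |
| `l_max` | agent length before collinear split | length | 10 |

All rules are parametrised *per step* (`dt` only fixes the meaning of
total time), matching how the rates `p_bra`, `R`, `v` are quoted. The
Model-2 values of `p_bra`, `R`, `v` are the fixed parameter vector used
throughout the synthetic experiments; the remaining constants are package
choices, made once, with the following rationale:

* **`r_min = 0.1`, `r_init = 1`:** the main branch's resource lifetime
  $(r_\mathrm{init}-r_\mathrm{min})/(2R) \approx 634$ steps exceeds the
  500-step window, so the *window* terminates apical growth. This is not
  cosmetic — it anchors the scale of the per-step rates (next section).
* **`r_0 = r_min + 0.02`:** side branches are born barely above the idle
  threshold, living $(r_0 - r_\mathrm{min})/(2R) \approx 14$ steps. This
  keeps the lateral cascade subcritical
  ($p_\mathrm{bra}(r_0-r_\mathrm{min})/(2R) \approx 0.5 < 1$) and yields
  the "long main branch with short side extensions" morphology that
  distinguishes Model 2. Larger `r_0` makes lateral growth supercritical
  and the tree size explodes; a hard `max_nodes` cap (default 1e5 agents)
  converts such runaway simulations into errors that calibration treats
  as automatic misses.
* **walk weights (0.4, 0.5, 0.1):** persistence slightly dominates noise,
  with a weak gradient bias — tips follow smoothly curving, apically
  oriented paths. Branch angles (30°, 60°) are in the range reported for
  pyramidal-cell dendrites; none of the four QoIs depends on angles, so
  these choices affect appearance, not calibration.
* **Model-1 defaults** give three basal stubs about two bifurcation
  generations before exhaustion — compact basal trees.

With the Model-2 defaults a neuron carries roughly 75 segments and 9e4
length units of dendrite; 10^4 neurons simulate in a few seconds.

## Morphometrics

Each neuron is reduced to four quantities of interest (QoIs):

* `m1_n_segments` — number of segments,
* `m2_mean_seg_len` — mean segment length,
* `m3_std_seg_len` — standard deviation of segment length (population
  convention by default; switchable),
* `m4_total_len` — total dendritic length.

A *segment* is a maximal unbranched section between topological nodes
(soma attachment, branch points, tips), and its length is the sum of its
agents' cylinder lengths. Working at the section level — the convention
used by standard morphometry software — makes all four QoIs invariant to
the simulator's `l_max` splitting, a property the calibration requires:
the discretisation must not leak into the data representation. The soma is
excluded; apical (SWC type 4) and basal (type 3) subtrees can be selected
separately, so the two models can be calibrated on their own arbours.
`m2 * m1 = m4` holds exactly, and a brute-force path-enumeration oracle
verifies the section decomposition in the test suite.

Neurons are exchanged in the standard 7-column SWC format; a QoI table is
a plain CSV with one row per neuron.

## Identifiability: why the growth window matters

The growth rules admit an exact scale transformation: multiplying
`p_bra`, `R` and `v` by a common factor $c$ leaves every QoI distribution
unchanged *as long as all resource lifetimes stay below the window*,
because each lifetime scales as $1/c$ while per-step increments scale as
$c$ — counts (rate × lifetime) and lengths (v × lifetime) are invariant.
Data generated in that resource-limited regime therefore cannot identify
the three rates jointly, only their ratios.

The window breaks the degeneracy. If the main branch is still growing
when the simulation ends, its length is `n_steps * v`, pinning `v`; mean
segment length then pins `p_bra`, and the side-branch length scale
$(r_0-r_\mathrm{min})\,v/(2R)$ pins `R`. The default configuration puts
the truth in this window-limited regime, but parameter points with
$c \gtrsim 1.3$ fall back into the resource-limited regime and mimic the
data's QoI *means* almost exactly (their spreads are ~20% tighter — a
difference a 25-neuron simulated dataset cannot resolve). The calibration
profile therefore uses a lean growth window of `n_steps = 200`: since
$200 < (r_\mathrm{init}-r_\mathrm{min})/(2R_\mathrm{max}) = 225$ for the
largest `R` in the prior box, *every* admissible parameter is
window-limited and the mimicking family lies outside the prior entirely.
This choice was made on the a-priori argument above, and the package's
acceptance tests confirm the resulting joint identifiability.

## Statistical distances

Datasets are compared as point clouds in QoI space, bypassing summary
statistics:

* **Wasserstein (default).** Exact 2-Wasserstein distance between the
  uniform empirical measures under the Euclidean ground metric. The
  solver runs successive shortest augmenting paths with column potentials
  (a Jonker–Volgenant-type method generalised to integer column
  capacities after reducing supplies by `gcd(n, m)`); solutions agree
  with an independent Hungarian-algorithm oracle to 1e-10 in the test
  suite, and a 500-vs-25 problem solves in ~2 ms. 1-D inputs use the
  closed-form quantile coupling. Cardinalities should share a large
  common divisor (the solver works in units of `1/lcm(n, m)` and refuses
  pathological sizes).
* **Sliced Wasserstein.** Root-mean of squared 1-D distances over random
  unit projections (default 50).
* **KL divergence.** 1-nearest-neighbour estimator: dimension-scaled mean
  log-ratio of NN radii plus the `log(m/(n-1))` correction. Asymmetric;
  may be negative at small n (passed through unmodified — threshold
  comparisons remain meaningful).
* **γ-divergence.** Plug-in of 1-NN density estimates into the
  γ-cross-entropy terms; approaches the KL estimate as γ → 0 and damps
  the influence of outlying points through its power means.

Exact coincidences between clouds are treated as ties and broken toward
the next neighbour with a 1e-12 radius floor, so identical clouds score
≈ 0 rather than −∞. By default all QoI columns are standardised by the
*observed* data's per-column mean and standard deviation before any
distance is computed, balancing heterogeneous units (counts vs lengths);
the switch `standardize = FALSE` restores raw columns. Whether to
standardise is a genuine design choice — scale balance was judged more
important than metric purity, and the switch preserves the alternative.

## The SMC-ABC sampler

The sampler approximates the ABC posterior
$p_\epsilon(\theta \mid y_\mathrm{obs}) \propto p(\theta)\,
P\!\left[d(y_\mathrm{obs}, y_\mathrm{sim}(\theta)) < \epsilon\right]$
with a weighted ensemble of `N` particles moved through a decreasing
tolerance sequence $\infty = \epsilon_0 > \epsilon_1 > \dots$:

1. **Adaptive tolerance.** $\epsilon_{i+1}$ is the largest value at which
   the effective sample size `ESS = (Σw)²/Σw²` of the
   indicator-reweighted system falls to a fraction α (default 0.6) of
   the current ESS, found by bisection (the ESS is a step function of ε;
   the bisection converges to the jump and is verified against a grid
   oracle to 1e-6).
2. **Reweight and resample.** Weights are multiplied by
   `1(distance < ε)` and renormalised; systematic resampling triggers
   when `ESS < 0.5 N`.
3. **Move: the 2-hit kernel.** Each particle attempts one MCMC move.
   A proposal $\theta' \sim \mathcal N(\theta,\, 2\,\widehat\Sigma_w)$
   (twice the weighted ensemble covariance, the standard adaptive choice)
   is rejected outright if it leaves the uniform prior box. Otherwise
   datasets are simulated until the proposal scores $r = 2$ hits
   (`distance < ε`), taking $N'$ draws, and the current particle scores 1
   hit, taking $N$ draws; the proposal is accepted with probability
   $N/(N'+N-1)$.

**Why $N/(N'+N-1)$.** With hit probabilities $a$ (proposal) and $b$
(current), $N' \sim$ NegBin(2, a) and $N \sim$ Geom(b). Detailed balance
with respect to $p(\theta)\,b(\theta)$ requires
$b\,\mathbb E[A(N',N)] = a\,\mathbb E[A_\mathrm{rev}]$ for the acceptance
function $A$. Writing out the expectation, the substitution
$(n', n) \to (n+1,\, n'-1)$ maps the two sides onto each other provided
$A(n', n)\,(n'-1) = A(n+1, n'-1)\,n$, and $A(n',n) = n/(n'+n-1)$ solves
this functional equation while staying in $[0,1]$. The kernel is
therefore exactly invariant for the ABC target; at $\epsilon = \infty$ it
reduces to acceptance probability exactly 1/2, and a Monte-Carlo
invariance test (50 kernel sweeps over 2000 exact ABC-posterior samples,
two-sample Kolmogorov–Smirnov) confirms it empirically. A naive
"first to two hits wins" race is *not* in detailed balance (a worked
counterexample with hit probabilities 1 and 0.5 gives an acceptance ratio
of 7 where 2 is required), which is why the package implements the
acceptance-probability form.

Three engineering refinements keep the kernel affordable at desk-scale
budgets, none of which changes its invariant law except where stated:

* **Exact early termination.** The acceptance uniform $u$ is drawn before
  the proposal race; acceptance is only possible while
  $N' < N/u - N + 1$, so the race stops at that bound. Paths beyond the
  bound would have been rejected anyway — the kernel law is unchanged,
  but hopeless proposals cost a handful of datasets instead of the full
  cap (about a three-fold saving in practice).
* **Dataset refresh.** The current particle's 1-hit race yields a fresh
  draw from $y \mid \theta$ conditioned on a hit — exactly the
  conditional the extended-space target assigns to the stored dataset.
  Storing it (also on rejection) is a valid Gibbs move and prevents
  particles from surviving on atypically lucky datasets. Without it the
  ensemble can collapse onto copies of one lucky particle, which was
  observed directly during development.
* **Stuck-particle guard.** A move that would exceed `move_cap` simulated
  datasets (default 30; the full-scale profile uses 1e4) counts as a
  rejection, and if even the *current* particle cannot re-hit within the
  cap it is marked stale (distance ∞) and dies at the next reweighting —
  many failed update attempts are treated as the signal of a particle
  trapped in a negligible-probability region. These caps bias the kernel
  in the extreme tails; the bias is the price of bounded iteration cost
  and is confined to particles the posterior would discard.

The run stops when the simulation budget (counted in single neuron
simulations; each dataset costs `M'`) is exhausted — finishing the
iteration in progress — or when an optional `epsilon_target` is reached.
Budgets, not target tolerances, are the primary stopping rule because the
reachable ε is problem-dependent. Per-particle seeds are derived
deterministically per iteration, so single-process runs are exactly
reproducible from the root seed.

## Sensitivity analysis

Global Sobol indices over a parameter box Ω use the Saltelli
cross-sampling design `A, B, AB_i, BA_i` (`K = n_base (2d+2)` model
evaluations), the Saltelli-2010 first-order estimator and the Jansen
total-effect estimator, each averaged over both mixed blocks, with 95%
bootstrap confidence intervals over the base-sample index. The expected
QoI at each design row is a mean over `m_replicates` stochastic
simulations; the bootstrap deliberately does not account for this inner
Monte-Carlo error. Outputs with zero variance yield zero indices with a
flag rather than NaNs. The estimators are validated against
`f(x) = x₁` (S1 = S_tot = (1,0,0)) and the Ishigami function's analytic
variance decomposition.

## Posterior summaries and predictive checking

Marginals are weighted Gaussian KDEs (Silverman bandwidth on the weighted
sample, effective sample size in place of n; a degenerate sample falls
back to a small positive bandwidth). The MAP estimate is the
*per-coordinate marginal mode* on a 512-point grid with ties broken
toward the smaller value — a joint mode is poorly determined by a few
hundred weighted particles, and the marginal convention is recorded in
the result's metadata. The predictive check draws parameters from the
weighted ensemble, simulates datasets, and compares per-QoI marginal
summaries (means, sds, quantiles) of simulation against data; pairing
assigns each observed neuron its nearest simulated neuron in QoI space
after normalising by the data's marginal standard deviations. The
Anderson–Darling test (normal family, estimated parameters) quantifies
the non-normality of QoI marginals.

## The synthetic-data generator

All tests and the acceptance analyses run on data from the package's own
simulators — exactly the synthetic-experiment design: the generator's
defaults *are* the study conditions (the fixed Model-2 vector `p_bra =
0.038, R = 7.1e-4, v = 100` plus the constants above). The generator
emulates the statistical structure of pyramidal-cell arbours that the
QoIs measure: segment-count and segment-length distributions of an
apical-like main branch with laterals (Model 2) and of balanced basal
trees (Model 1), with realistic within-population stochasticity. It does
not emulate reconstruction noise or slicing artifacts of real
microscopy-derived morphologies, diameters (inherited unchanged and
unused by the QoIs), tortuosity differences beyond the persistent-walk
family, interactions between neurons, or activity-dependent growth.
Passing the synthetic-recovery tests therefore demonstrates that the
inference machinery recovers known parameters when the model is
well-specified — it does not certify the growth rules as descriptions of
any particular real dataset; for that, the predictive check against real
QoI tables is the relevant tool.

## Numerical choices and degenerate cases

* **Random numbers.** The C++ simulator uses a splitmix64 counter
  generator with per-neuron child seeds derived arithmetically from the
  root seed, so simulated datasets are reproducible independently of R's
  RNG state; all R-level stochastic steps use R's RNG under `set.seed`.
* **Problem sizes.** The shipped tests and acceptance analyses use
  desk-scale sizes chosen to finish in minutes on one core: 500 observed
  neurons, `N = 256` particles, `M' = 25`, a 5e5-simulation budget, 1e4
  neurons for the stochasticity analysis, `n_base = 1024` for the Sobol
  oracles. The full-scale profile (`inst/configs/paper.yaml`: `N = 1024`,
  `M' = 50`, budget 5e7) is the same code path.
* **Degenerate inputs.** Zero-variance QoI columns make standardisation
  (and pairing) fail loudly. A zero resultant elongation direction (all
  weights zero, or exact cancellation) is an error. Daughters that never
  elongate are pruned before export so zero-length sections cannot occur;
  mid-tree unary nodes (from splits or pruned siblings) are transparent
  to the section decomposition. An all-miss particle population aborts
  with a degenerate-population error carrying the trace (CLI exit
  code 3).
* **Conventions.** Population standard deviation for `m3` (switchable);
  single collinear split per elongation event; SWC cylinders belong to
  the child record; stubs start at the soma centre so SWC round-trips are
  exact.

## Known limitations

Single resource species and a single linear guidance cue; no retraction,
stalling, or contact interactions; diameters carry no information; the
Wasserstein solver targets desk-scale cardinalities (hundreds of points;
its cost grows with `lcm(n, m)`); the sampler is single-process (the
per-particle seed scheme is designed so a process-pool map over particle
moves would leave results order-independent, but no parallel backend is
shipped); `move_cap`-induced kernel bias in extreme tails as discussed
above; and the marginal-mode MAP carries Monte-Carlo noise of order 10%
at `N = 256`, which should be kept in mind when reading single-run point
estimates.
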