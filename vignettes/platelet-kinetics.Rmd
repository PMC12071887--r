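---
title: "Modelling platelet phenotype transitions from aggregometry kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling platelet phenotype transitions from aggregometry kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(plateletkin)
```

## The model

Activated platelets do not form a homogeneous population: they pass through
functionally distinct states, and the balance between those states — not any
single reaction — decides whether a stimulus ends in stable aggregation,
transient aggregation with reversal, or a refractory population that no
longer responds. `plateletkin` represents this as a closed six-state
compartment system, with each state a percentage of the total population:

* `n_rest` — resting discoid platelets;
* `n_sph` — sphered platelets (early shape change);
* `n_gp` — platelets with activated aIIbb3 integrins, competent to bind
  fibrinogen;
* `n_agg` — platelets incorporated in aggregates;
* `n_inh` — platelets inhibited through the cyclic-nucleotide (cAMP/cGMP)
  pathways;
* `n_exh` — exhausted platelets, temporarily refractory to restimulation.

Transitions are first order except aggregation, which is second order in the
integrin-activated fraction (aggregation proceeds by stochastic collisions,
so its rate scales with the square of the colliding population under
stirring):

$$
\begin{aligned}
\dot N_{rest} &= k_{-4} N_{inh} + k_{-1} N_{exh} - (k_1 + k_4)\,N_{rest}\\
\dot N_{sph}  &= k_1 N_{rest} - (k_2 + k_5)\,N_{sph}\\
\dot N_{gp}   &= k_2 N_{sph} - k_3 N_{gp}^2 - k_6 N_{gp}\\
\dot N_{agg}  &= k_3 N_{gp}^2 - k_7 N_{agg}\\
\dot N_{exh}  &= k_5 N_{sph} + k_6 N_{gp} + k_7 N_{agg} - k_{-1} N_{exh}\\
\dot N_{inh}  &= k_4 N_{rest} - k_{-4} N_{inh}
\end{aligned}
$$

The right-hand sides sum to zero, so the six fractions are conserved at
100% — this is asserted to $10^{-6}$ relative tolerance in the test suite
for every simulation the package produces. Simulations start from 100%
resting platelets unless an explicit initial state is given.

## Concentration coupling

Rate constants are not free dials: each concentration-dependent constant is
tied to agonist or inhibitor concentration by a Hill law
(`platelet_params()` holds the full table).

* **Activation** (`k1` shape change, `k2` integrin activation):
  $k = k_{max} A^h / (EC_{50}^h + A^h)$. For ADP, `k1` uses
  $k_{max} = 0.19\ \mathrm{s^{-1}}$, $EC_{50} = 46.8$ nM, $h = 1.27$; `k2`
  uses $k_{max} = 0.03\ \mathrm{s^{-1}}$, $EC_{50} = 589.8$ nM, $h = 3.92$.
  TRAP columns carry the same maxima with their own $EC_{50}$/$h$.
* **Desensitization** (`k5` from the sphered state, `k6` from the
  integrin-activated state) follows the *inhibitory* Hill form in the
  agonist: higher agonist doses protect against exhaustion,
  $k = k_{max} IC_{50}^h / (IC_{50}^h + A^h)$, with
  $(k_{max}, IC_{50}, h) = (0.0028\ \mathrm{s^{-1}}, 1840\ \mathrm{nM}, 1.4)$
  for `k5` and $(0.055\ \mathrm{s^{-1}}, 990\ \mathrm{nM}, 1.9)$ for `k6`.
  Both are zero when no agonist is present.
* **Inhibition** by a prostacyclin-pathway agonist (iloprost) acts
  non-competitively on the forward constants: `k1` and `k2` are multiplied
  by $IC_{50}^h/(IC_{50}^h + (e\,I)^h)$, with the shape-change factor using
  $IC_{50} = 0.048$ nM, $h = 1.52$ and the aggregation factor
  $IC_{50} = 0.21$ nM, $h = 2.14$.

### Inhibitor onset dynamics

Receptor-mediated PKA activation is fast but not instantaneous: a few
seconds of iloprost exposure fully blocks aggregation, while suppression of
shape change requires pre-incubation on the order of two minutes. The
package therefore gives each inhibitor species a per-pathway *effect level*
$e(t) \in [0, 1]$ that relaxes first order toward the inhibitor's Hill
occupancy with onset rate $0.31\ \mathrm{s^{-1}}$ (shape-change and
aggregation pathways; a calcium-linked onset rate of
$0.085\ \mathrm{s^{-1}}$ is recorded in the table for completeness but does
not enter the light-scatter model). The non-competitive factor is evaluated
at the effective concentration $e(t)\,I$. This makes pre-incubation
experiments come out right: an inhibitor added 60 s before the agonist has
$e \approx 1$ when stimulation arrives, whereas co-administration lets the
first seconds of activation escape.

The resting-to-inhibited constant is tied to the same pathway:
$k_4 = 0.31\ \mathrm{s^{-1}} \times$ the inhibitor's aggregation-pathway
Hill occupancy, since no standalone dose law exists for it.

### Aggregation handling

`k3` is second order (units $1/(\%\cdot\mathrm{s})$) and deliberately never
rate-limiting: under the working cell concentrations, collision frequency
exceeds integrin activation, so the model sets
$k_3 = 2 k_{max,2} / 100$ per (% s). At 100% integrin-activated platelets
the pseudo-first-order aggregation rate is then exactly twice the
integrin-activation maximum; dimensional consistency is what forces the
$1/100$ scale. Stopping the stirrer sets $k_3 = 0$ and nothing else —
desensitization continues during a stir pause, which is precisely what the
stir-pause protocol exploits to measure `k6`.

### Disaggregation

Aggregates are reversible for a limited time: inhibitor arriving within
about three minutes of activation still reverses aggregation, later it does
not. The package implements this as a hard window: `k7` (scaled by the
inhibitor's aggregation-pathway occupancy) is active only while inhibitor
is present *and* simulation time is within `disagg_window` (180 s, a user
argument) of the most recent agonist addition; afterwards `k7` is zero and
aggregation is irreversible. A consequence worth knowing: when the
inhibitor arrives within seconds of the agonist, almost no aggregate has
formed yet, the 1-degree signal stays near baseline, and the
percent-disaggregation readout on such a trace is dominated by the slow
residual trickle of the suppressed forward reactions rather than by `k7`.
Disaggregation quantification is therefore most meaningful when the
inhibitor arrives after the aggregation signal is established (offsets of
roughly 30 s and beyond).

## Numerical choices

* Integration uses a stiff-capable adaptive solver (`deSolve::lsoda`) with
  `rtol = 1e-8`, `atol = 1e-10` by default; the trajectory-fitting path
  relaxes this to `1e-5`/`1e-7`, which changes fitted constants by far less
  than their confidence intervals.
* Protocol events are hard restarts: concentrations are step functions
  (additions are cumulative; dilution and agonist degradation are ignored
  on the ten-minute scale simulated), and the integrator is re-initialized
  at every event time plus at each disaggregation-window boundary.
* Output is sampled on a uniform grid, default 0.1 s — comparable to the
  sub-second half-times of the fastest (inhibition-onset) reactions.
* Solver-level negatives above $-10^{-6}$ are clipped to zero for
  reporting; the conservation identity is tested, not enforced by
  renormalization.
* Exhausted platelets recover to rest only (`k_m1`); there is no direct
  path between the inhibited and exhausted pools.

## Trace readouts and rate extraction

Instrument-like channels are an affine map of the state (`observables()`):
the 1-degree scatter channel follows the aggregated fraction, the 12-degree
channel the sum of sphered and integrin-activated fractions (both are
spherical and scatter alike at 12 degrees).

* `fit_exponential_rise()` fits
  $I(t) = I_m - (I_m - I_o)\,e^{-k (t - t_0)}$ by Levenberg-Marquardt with
  an analytic Jacobian, initialized at $I_m = \max I$, $I_o = I(t_0)$ and
  $k = \ln 2$ / time-to-half-range. Flat signals are rejected as
  degenerate; fits with $R^2$ below 0.5 (configurable) are flagged rather
  than silently returned.
* `initial_rate()` is a tangent slope from local linear regression in a
  ±2 s window (configurable). A chord slope from onset was the alternative
  reading of the instrument convention; the tangent was chosen and the
  window exposed, so a chord can be emulated by widening it. On a curved
  rise the default window carries a small curvature bias (about
  $k^2 w^2/6$, ~2% at $k = 0.19$, $w = 2$ s) — the price of noise
  robustness.
* `trace_auc()` is a trapezoidal area over a stated window after baseline
  subtraction; `disaggregation_percent()` is the percentage drop of a
  channel from its maximum, affine-invariant by construction.
* When event times are unknown, `detect_onset()` places the onset at the
  first sample exceeding the pre-event median by three pre-event noise
  standard deviations (baseline span 5 s); protocols with known event
  times pin the onset explicitly.

## Dose-response and decay fitting

`fit_hill()` fits $(k_{max}, EC_{50}\ \text{or}\ IC_{50}, h)$ by weighted
nonlinear least squares. Hill fits have flat, banana-shaped valleys in the
half-effect concentration, so the optimizer is multi-started from five
log-spaced half-effect seeds, with bounds
$EC_{50} \in [\min \mathrm{dose}/100,\ \max \mathrm{dose} \times 100]$ and
$h \in [0.3, 10]$ (the steepest printed coefficient is 6.68, well inside).
Weights are inverse-variance when per-point spreads are supplied —
synthetic datasets generated with multiplicative noise record their true
spreads — and uniform otherwise.

One numerical caveat deserves emphasis: a three-parameter Hill fit to
exactly three dose points is exactly determined, and its solution is
hypersensitive to rounding of the responses. Perturbing a response in its
last printed digit can move the fitted half-effect concentration by tens of
percent. Fits to minimal printed tables are therefore reproductions of the
table (the fitted law returns the inputs essentially exactly), but their
parameters should not be over-interpreted; four or more doses are needed
for stable parameter estimates, which is why
`generate_dose_response_dataset()` defaults to 8 log-spaced doses spanning
a decade either side of the half-effect concentration.

`fit_decay_constant()` assumes the restimulation response decays as a
single exponential in the imposed delay,
$\mathrm{response}(\Delta) = 100\,e^{-k\Delta}$, anchored at the
zero-delay control (100%, not fitted). The decay law is an assumption: the
source experiments report only rate constants and half-times, which is
consistent with first-order decay but does not prove it.
`dose_dependence_of_decay()` chains these fits across agonist doses and
fits the inhibitory Hill law to the resulting $(A, k)$ pairs.

## Estimating the inaccessible constants

The recovery constants `k_m1` (exhausted to resting) and `k_m4` (inhibited
to resting) and the disaggregation constant `k7` cannot be read from
light-scatter traces: resting, inhibited and exhausted platelets scatter
alike. `fit_model()` estimates them by matching simulated observables to
traces, with a loss summing squared residuals over both channels after
per-channel range normalization (equal weighting was an open choice; range
normalization keeps a 100-AU aggregation channel from drowning a 30-AU
shape-change channel). The search is a seeded multi-start in log-parameter
space with basin-hop-style perturbations (greedy acceptance), each start
polished by bounded L-BFGS-B on $\log_{10}$ parameters with numerical
gradients. Identifiability reporting is mandatory: each parameter is pushed
to its bounds with the others held at the optimum, and the relative loss
rise is reported — near-zero means the data do not constrain that constant
(e.g. `k_m4` is structurally unidentifiable in any protocol without an
inhibitor).

Because no deposited experimental curves exist for these constants, the
package validates the estimator on synthetic suites where truth is known by
construction. The shipped defaults (`default_fitted_constants()`:
`k_m1 = 0.001`, `k_m4 = 0.005`, `k7 = 0.05` $\mathrm{s^{-1}}$) are
plausible magnitudes — exhaustion recovery on a ten-minute scale, reversal
of inhibition within minutes, disaggregation fast enough to empty an
aggregate inside the three-minute window — chosen once as the generator's
study conditions, not tuned. The validation suite uses three protocols
(low ADP 500 nM over 600 s; high ADP 5000 nM over 300 s; iloprost 0.1 nM
pre-incubated 30 s before ADP 5000 nM over 600 s): the low-dose trace
exposes `k_m1` through late repopulation of the shape-change signal, and
the inhibitor trace exposes `k_m4` and `k7` simultaneously. The inhibitor
dose matters for identifiability: at 0.1 nM the 30-s pre-incubation
inhibits only part of the resting pool, so a strong aggregate still forms
(giving `k7` a large decaying signal inside the reversibility window)
while a large inhibited pool recycles visibly through `k_m4`; stronger
pre-incubation doses empty the resting pool before stimulation, the
aggregation channel stays near baseline, and `k7` becomes nearly
unidentifiable under range-normalized loss. Traces are sampled at 2 s for fitting — dense enough for
dynamics with half-times of tens of seconds — and the recovery study runs
20 noise seeds at 2% additive noise per channel range; median recovery
errors are a few percent for all three constants.

```{r recovery, eval = FALSE}
suite <- list(
  stimulus_protocol(add_agonist(0, "ADP", 500), t_end = 600),
  stimulus_protocol(add_agonist(0, "ADP", 5000), t_end = 300),
  stimulus_protocol(add_inhibitor(0, "iloprost", 0.1),
                    add_agonist(30, "ADP", 5000), t_end = 600)
)
obs <- lapply(suite, function(pr) {
  list(protocol = pr,
       trace = generate_trace(pr, noise = noise_model(seed = 1), sample_dt = 2))
})
prob <- fit_problem(list(k_m1 = c(1e-4, 1e-2), k_m4 = c(5e-4, 5e-2),
                         k7 = c(5e-3, 5e-1)), obs, sample_dt = 2)
fit <- fit_model(prob, seed = 1)
tidy(fit)
```

## What the synthetic generator does and does not emulate

`generate_trace()` wraps simulation, the channel map and a seeded noise
model, and every noisy fixture carries its noiseless twin so estimator
tests quantify bias against truth rather than against one noise
realization. The default noise is additive Gaussian with standard
deviation 1% of the channel range and no drift — conservative relative to
visible instrument trace quality, and small enough that exponential-rate
recovery from a default fixture stays within 5%.

The generator reproduces the *kinetic structure* the analysis assumes:
exponential shape-change rises, sigmoidal dose dependence, second-order
aggregation, first-order desensitization and the inhibition/disaggregation
timing. It does not attempt raw angular-scattering physics, particle-size
distributions, optical calibration, stirring artifacts, baseline drift
(available but off by default) or donor-to-donor variability. Passing
tests therefore certify the estimators and the model implementation, not
instrument-specific behavior on real traces.

## A worked simulation

```{r fig10-like, eval = FALSE}
pr <- stimulus_protocol(add_agonist(0, "ADP", 2000), t_end = 300)
traj <- simulate_phenotypes(pr, sample_dt = 0.5)
autoplot(traj)
```

A moderately high ADP dose drives strong aggregation followed by visible
disaggregation-free exhaustion; rerunning with 100 nM produces shape change
only, and adding `add_inhibitor(0, "iloprost", 5)` suppresses aggregation
entirely while a weak shape-change response persists.

## Known limitations

* Procoagulant, secretory and apoptotic phenotypes, microparticles, clot
  formation, coagulation chemistry, flow and spatial structure are out of
  scope; the model describes a stirred, diluted suspension.
* The combination rule for concurrent activating and inhibitory stimuli
  (non-competitive multiplication at the effective inhibitor level) is a
  reconstruction of behavior the source experiments constrain only
  indirectly; alternative combination rules consistent with the same
  endpoint data exist.
* Desensitization dose laws are calibrated for ADP; protocols using other
  agonists fall back to zero desensitization unless the parameter table is
  extended.
* Concentrations are treated as step functions; secretion feedback
  (released ADP re-stimulating the population) is not modelled.
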