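# plateletkin

Kinetic modelling of platelet phenotype transitions for laser-diffraction
(low-angle light-scattering) aggregometry.

Platelets respond to vascular injury by moving through functionally
distinct states — resting, sphered (shape-changed), integrin-activated,
aggregated — with side exits into an inhibited pool (via cAMP/cGMP
signalling, e.g. iloprost) and an exhausted, temporarily refractory pool.
Aggregometry traces report this cascade only through two scatter channels,
so questions like *how fast do activated integrins deactivate when
collisions stop*, or *for how long after activation can an aggregate still
be reversed*, need a kinetic model to answer. `plateletkin` is for
researchers analysing such traces: it ships the model, the trace readouts,
the dose-response machinery and the estimators as one tested, pipeable
toolkit.

## The model

Six population fractions (percent, summing to 100) evolve by mass-action
kinetics; all transitions are first order except aggregation, which is
second order in the integrin-activated fraction:

```
dN_rest/dt = k-4 N_inh + k-1 N_exh - (k1 + k4) N_rest
dN_sph/dt  = k1 N_rest - (k2 + k5) N_sph
dN_gp/dt   = k2 N_sph - k3 N_gp^2 - k6 N_gp
dN_agg/dt  = k3 N_gp^2 - k7 N_agg
dN_exh/dt  = k5 N_sph + k6 N_gp + k7 N_agg - k-1 N_exh
dN_inh/dt  = k4 N_rest - k-4 N_inh
```

Each concentration-dependent constant follows a Hill law: activating
(`k = kmax A^h / (EC50^h + A^h)`) for the agonist-driven forward steps,
inhibitory (`k = kmax IC50^h / (IC50^h + I^h)`) for the agonist dependence
of the desensitization constants and for the non-competitive suppression
of forward steps by inhibitors. Inhibitor action develops with measured
first-order onset kinetics, aggregation is reversible only within a 180-s
window after stimulation, and stopping the stirrer switches off
aggregation (`k3 = 0`) while desensitization continues. The constants that
traces cannot expose directly (`k-1`, `k-4`, `k7`) are estimated by
fitting simulated trajectories to traces with a seeded global+local
optimizer. See the methods vignette
(`vignettes/platelet-kinetics.Rmd`) for the full account.

## Worked example

Simulate a moderately strong ADP stimulation, map it to instrument
channels and compute the standard readouts:

```r
library(plateletkin)

pr   <- stimulus_protocol(add_agonist(0, "ADP", 2000), t_end = 300)
traj <- simulate_phenotypes(pr, sample_dt = 0.5)
tr   <- observables(traj)

initial_rate(tr, "LSI1", t_eval = 20)   # Vagg: 0.479 AU/s
trace_auc(tr, "LSI1", 120)              # AUCagg: 3105 AU*s
max(traj$n_agg)                         # peak aggregated fraction: 52.8 %

fit_exponential_rise(tr, "LSI12", window = c(0, 20))
#> <exp_fit> LSI12: k = 0.21672 1/s (se 0.0029), Im = 93.22, Io = -1.316, R2 = 0.9989
```

The 12-degree channel rises with shape change at close to the saturating
shape-change rate constant (0.19 1/s; the compound signal fits slightly
above it), the 1-degree channel reports aggregation of about half the
population at this dose, and `autoplot(traj)` draws all six fractions.

Dose-response fitting works on plain tables:

```r
ds <- dose_response_dataset(c(1000, 2000, 5000), c(0.0019, 0.0013, 0.0005))
fit_hill(ds, mode = "inhibition")
#> <hill_fit> mode=inhibition: k_max = 0.0024424, IC50 = 2165.8 nM, h = 1.62, R2 = 1.00000
```

(Three points, three parameters: the fit interpolates the table exactly.
The vignette discusses why such minimal fits are hypersensitive to
rounding of the responses.)

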