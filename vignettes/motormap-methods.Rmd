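---
title: "Models and methods in motormap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in motormap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

motormap simulates how MAP7 decoration of microtubules regulates the
motility of kinesin-1 and dynein, and reimplements the single-molecule
analyses used to characterise that regulation: decoration titrations,
run-frequency dose-response curves, nanometer-precision stepping
trajectories with changepoint step detection, and a kinesin--dynein
tug-of-war direction model. This vignette records the models, the
parameter choices that matter, and the boundaries of what the synthetic
data can and cannot show.

## The lattice and the exclusion rule

A microtubule is modelled as 13 protofilaments of tubulin-dimer sites
with an 8-nm axial repeat, unrolled into a plane: protofilament rows are
6 nm apart laterally and staggered axially by 12/13 nm per row (the
3-start helical rise). We deliberately work in 2D image coordinates
rather than on a cylinder because the stepping analyses we reproduce
operate on 2D tracking data; the seam is kept as geometry metadata but
never crossed, and sideways steps at the outer rows choose among
in-range neighbours only. Runs start in the central half of the lattice,
so edge effects are negligible at the default 300-site length. Axial
boundaries are absorbing: a motor stepping off the end ends its run,
mimicking finite microtubules in an assay.

Each site carries exactly one occupant tag: `EMPTY`, `MAP7`, `KINESIN`
or `DYNEIN`. This mutual exclusion encodes the structural observation at
the model's core -- the MAP7 microtubule-binding domain (MTBD) and a
motor head cannot share a tubulin dimer. `occupy()` on a non-empty site
is an error, never a silent no-op, and the event simulators assert the
rule after every move. Every occupant blocks exactly one dimer site by
default; because a longer MTBD helix cannot be excluded structurally, a
two-site MAP7 footprint can be emulated by doubling `k_on` against a
halved site count, though all shipped analyses use one site.

## Decoration kinetics

MAP binding is a per-site telegraph process: binding at `k_on * c` per
empty site and unbinding at `k_off`, simulated exactly with the
Gillespie algorithm (`simulate_decoration()`). Only the ratio
`K_D = k_off / k_on = 111 nM` is constrained by the full-length MAP7
binding data, so `k_off = 1 /s` is a convention; every equilibrium
observable depends on the ratio alone, and a different `k_off` only
rescales the relaxation time. Steady-state occupancy follows the Hill
isotherm `c^h / (c^h + K_D^h)`; decoration is simulated with `h = 1`
(no cooperativity is reported for MAP7), while the fitting module
estimates `h` freely. During motor runs the decoration is equilibrated
and frozen (quasi-static approximation), which is appropriate because
MAP7 exchange rates are unreported and runs are short.

Construct presets capture the binding logic of the truncation series:
`MTBD_only` binds the lattice but cannot tether; `dMTBD` does not
occupy lattice sites at all, associating only with the flexible tubulin
tails (a constant bound fraction of 0.3, chosen as "significant but
well below lattice binding"; it is zeroed on the subtilisin condition);
`MAP7_C` has no microtubule binding; the tau chimera behaves like
full-length MAP7. `binding_assay()` reproduces the
construct-by-condition intensity matrix from these flags.

## Motor runs and tethered diffusion

`simulate_run()` is an exact continuous-time event simulation of one
motor. Stepping attempts occur at `k_step` (default 1 /s, the
limiting-ATP regime in which individual steps are resolvable);
direction is forward/sideways/backward with probabilities
0.88/0.09/0.03, the stepping statistics measured on undecorated
lattices. The labelled head advances two dimer sites (16 nm) per cycle,
matching hand-over-hand tracking of a single motor domain; the 8-nm
centre-of-mass picture is not modelled. Spontaneous detachment at
`k_detach0 = 1/60 /s` gives roughly 60 steps (~1 um) per run.

When a step targets a MAP7-occupied site, what happens next depends on
the motor--MAP pair. Without a projection-domain interaction (K490,
dynein, MTBD-only decoration) the motor detaches: an obstacle ends the
run. With it (K560 or full-length kinesin on full-length MAP7), the
motor enters a tethered state anchored at the obstacle: it leaves the
lattice but remains linked to the MAP7. At `k_rebind = 5 /s` it rebinds
an empty site within `reach_nm = 50` of the anchor (spanning the
observed 16--64 nm trajectory jumps); at `k_release = 0.5 /s` the
tether lets go and the run ends. Spontaneous detachment is likewise
rescued into the tethered state with probability equal to the local
MAP7 occupancy within reach.

The rebinding *kernel* -- which reachable empty site the motor takes --
is the one genuinely free piece of the model: neither the tether's
compliance nor the diffusion of the released head is measured. A
uniform choice among reachable sites is untenable: with 6-nm row
spacing and a 50-nm reach, over 80% of uniform jumps would change
protofilament, whereas the measured sideways share of steps at
near-saturating MAP7 is ~35%. We therefore use a separable Gaussian
weight centred on the motor's release position, with lateral width
4.3 nm, axial width 24 nm, and an axial centre 16 nm (one step) behind
the release point -- the last compensating the forward offset created
by anchoring the reach at the obstacle, one step ahead of the motor.
These three numbers are a calibration: they were chosen, once, so that
the full simulate-image-detect-classify pipeline at 1000 nM MAP7
(occupancy 0.90) reproduces the measured direction mix (~35% sideways,
~26% backward), and they are exposed in `tether_params()` (both widths
`Inf` recovers the uniform rule).

## Run frequency, dose-response shapes, and the tug of war

`run_frequency()` composes a landing rate with a Monte-Carlo completion
probability. Landing is `k_land_basal * (1 + 20 * theta_proj) *
a(theta) * (1 - theta)`: recruitment by the projection domain
(`recruitment_gain = 20`), an autoinhibition activity factor, and
empty-site availability. A landed kinesin scores a processive run after
5 productive relocation events -- kymograph analyses count runs, not
landings, and 5 steps (~80 nm at 16 nm/step) is a reasonable
resolvability cut. The opposing concentration dependences -- recruitment
rising with occupancy, completion and landing falling as empty sites
vanish -- produce the biphasic run-frequency curve with an interior
maximum, the package's central qualitative claim, which
`fit_biphasic_hill()` recovers with an AIC margin over a single Hill
fit.

Dynein is never tethered and is far more obstacle-sensitive: a landed
DDR scores a run only if `n_clear` consecutive sites ahead are free, so
its normalised frequency falls as `(1 - theta)^(n_clear + 1)` (one
extra factor from landing-site availability). `n_clear` is the model's
one free integer, fixed by requiring that a Langmuir fit of the
simulated curve on the standard concentration grid return the measured
10 nM half-inhibition constant given `K_D = 111 nM`. That calibration
gives `n_clear = 6`: the commonly quoted closed-form half-occupancy
argument (`(1-theta)^8 = 1/2` at ~10 nM) ignores both the landing
factor and the systematic downward pull of fitting a Langmuir form to a
steeper-than-Langmuir curve, and with those included the exponent 8
lands near 7 nM instead.

`assembly_direction()` draws each kinesin--dynein cargo's direction
with probability `f_k / (f_k + f_d)` of moving plus-end-directed, the
simplest frequency-weighted tug-of-war. Full-length kinesin's
autoinhibition enters as a landing-competence factor `a(theta)` rising
from `activity0 = 0.272` -- solved in closed form so that the assembly
is 80% minus-end-directed on bare lattices -- toward 1 with
half-effect at occupancy 0.1. At 10 nM MAP7 the model switches the
majority to plus-end-directed; the printed 93% plus-end figure is
steeper than this interpretive model reproduces, and we treat the
majority switch, not the exact fraction, as the model's claim.

## Step detection

`find_steps()` fits each coordinate with a piecewise-constant function
by greedy chi-square insertion: at each iteration the single step that
most reduces the residual sum of squares is added, until the best
insertion's improvement falls below `penalty * 2 * log(n) * sigma^2`,
with `sigma` estimated robustly from the median absolute deviation of
frame-to-frame differences (insensitive to the steps themselves).
Inserted changepoints are then locally re-optimised between their
neighbours and weak ones pruned against the same threshold; on traces
of up to 200 frames and 5 steps this pipeline matches an exact
dynamic-programming changepoint oracle (implemented independently in
the test suite) in >= 95% of cases. The default `penalty = 1.3` is
calibrated against the package's false-positive requirement -- fewer
than 5% of flat Gaussian traces (sd 2 nm, 200 frames) may yield any
step -- while keeping power for one-frame plateaus; 16-nm steps under
2-nm noise carry ~60x the threshold's chi-square improvement, so
detection power for dwells of 10 frames exceeds 95%.

Changepoints found independently in x and y that fall within one frame
are fused into a single 2D step event (one physical step seen in both
coordinates); changepoints within one coordinate are never fused, so
one-frame plateaus remain resolvable. Steps are classified sideways
when |dy| >= 4 nm (protofilament rows are 6 nm apart, and plateau means
suppress the 2-nm noise well below that), otherwise backward when
dx <= -8 nm (half a step), otherwise forward; displacements beyond
20 nm are flagged as the 16--64 nm tethered-diffusion band. The
measured thresholds are config-exposed since the original analysis does
not print its own.

## Synthetic data: what it does and does not emulate

`make_trajectory()` samples the simulated head position at 0.1-s frames
and adds independent 2-nm Gaussian localization noise per coordinate --
the statistical structure of nanometer-precision tracking at limiting
ATP (~10 frames per ~1-s plateau). Ground truth travels in a sidecar
`.truth.csv`, never in the analysis input. `make_titration()` adds
multiplicative Gaussian noise (cv 0.1) to a named dose-response curve
and reports per-concentration mean, sd and n, emulating the replicate
structure of binding titrations. `make_kymograph()` rasterises runs
deterministically for visual regression. Not emulated: camera
integration/motion blur, photophysics (blinking, bleaching), drift
beyond what a linear detrend would remove, and localisation outliers.

One consequence deserves emphasis. With ~1-s dwells sampled at 0.1-s
frames, about 10% of true steps fall within a single frame interval of
their neighbour and are unresolvable in principle; rare-direction steps
pay that tax visibly. The detected backward share on bare lattices
therefore plateaus near 2.2--2.7% even though the generator's truth is
3% -- the printed 3% is itself a detected fraction at the original
(unpublished) frame rate. We report the honest detected value rather
than compensating for it.

## Problem sizes and numerical choices

The shipped analyses run at desk scale, single-core, in minutes: 13x300
lattices (13x770 for the 10,000-site titration check), 8-point
titrations with ~45 relaxation times of Gillespie simulation per point,
2000 landing trials per dynein frequency point, and 200 trajectories
(truncated at 120 s, a typical movie length) per stepping condition.
Dose-response fits use multi-start Levenberg--Marquardt least squares
(5 log-spaced half-max starts; all pairs for the biphasic model) with
1/sd^2 weights when uncertainties are present; concentration zero is
retained (all models are defined there). Non-convergence and
non-identifiability are flags on the result object, not exceptions.
Bootstrap standard errors resample standardised residuals so
heteroscedastic points are shuffled on a common scale. All simulators
are deterministic given a seed.

## Limitations

The model has no force dependence, no load-sharing cargo mechanics
beyond the binary direction draw, no microtubule dynamics or GTP-state
heterogeneity, no MAP7 cooperativity or lattice diffusion, and
one-site footprints throughout. The tether kernel is an effective
model whose anisotropy is calibrated, not measured; conclusions that
depend on its details beyond the reproduced direction mix should be
treated accordingly. The biphasic functional form is one reasonable
parameterisation (activation times inhibition) of a curve whose
original equation is not printed.

```{r example}
library(motormap)

# decoration titration and Hill fit
tit <- decoration_titration(map_params("FL_MAP7"),
                            c(10, 20, 50, 111, 250, 500, 1000, 3000),
                            seed = 1)
fit <- fit_hill(tit)
tidy(fit)
autoplot(fit)

# one noisy stepping trajectory and its step fit
rec <- simulate_run(lattice_state(), motor_params("K560"),
                    map = map_params("FL_MAP7"), concentration = 1000,
                    max_time = 60, seed = 2)
traj <- make_trajectory(rec, noise_model(), seed = 3)
steps <- find_steps(traj)
classify_steps(steps)
autoplot(traj, steps = steps)
```
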