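# motormap

Stochastic lattice simulation and single-molecule analysis of kinesin-1
regulation by the microtubule-associated protein MAP7.

MAP7 is a required cofactor for kinesin-1-driven transport, yet its
microtubule-binding domain (MTBD) occupies the same tubulin-dimer site
as the motor. motormap implements the mechanistic model that reconciles
these facts: MAP7 and motors bind a 13-protofilament dimer-site lattice
under strict mutual exclusion; the MAP7 projection domain recruits
kinesin, rescues it from autoinhibition, and — when a stepping motor
collides with an MTBD obstacle — tethers it to the microtubule so it
can rebind a nearby empty site ("tethered diffusion") instead of
diffusing away. Activation dominates at low MAP7 and obstruction at
high MAP7, so kinesin run frequency is **biphasic** in MAP7
concentration, while dynein, which is not tethered, is simply
inhibited. The package is aimed at single-molecule biophysicists who
want to simulate these regimes, test analysis pipelines against ground
truth, or fit their own titration and trajectory data.

The quantitative backbone:

- decoration equilibrium: Hill isotherm `θ(c) = c^h / (c^h + K_D^h)`
  with `K_D = 111 nM` for full-length MAP7, simulated exactly by
  per-site Gillespie kinetics;
- motor runs: continuous-time event simulation (stepping 16 nm per
  cycle with forward/sideways/backward probabilities 0.88/0.09/0.03,
  detachment, obstacle encounters, tethered rebinding within a 50-nm
  reach);
- dose-response fits: Hill, biphasic Hill
  `A·[c^h1/(c^h1+EC50^h1)]·[IC50^h2/(c^h2+IC50^h2)] + f0`, and
  Langmuir inhibition `f0·IC50/(IC50+c)`, by multi-start weighted
  least squares with broom-style `tidy()`/`glance()` accessors;
- trajectory analysis: greedy chi-square changepoint step detection
  with robust-noise stopping, refinement and pruning, validated
  against an exact dynamic-programming oracle, plus direction
  classification and step-size histograms;
- synthetic data: seeded generators for noisy trajectories (with
  hidden ground-truth sidecars), titration tables and kymographs.

## Worked example

Fit a simulated MAP7 decoration titration, then detect steps in a
noisy kinesin trajectory on a nearly saturated lattice:

```r
library(motormap)

tit <- decoration_titration(map_params("FL_MAP7"),
                            c(10, 20, 50, 111, 250, 500, 1000, 3000),
                            seed = 1)
fit <- fit_hill(tit)
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 rmax     1.000   0.00133
#> 2 kd     111.      0.792
#> 3 h        1.00    0.00561
```

The Gillespie titration recovers the 111-nM dissociation constant with
a sub-nanomolar standard error. Now a single run at 1000 nM MAP7
(lattice occupancy 0.90), imaged with 2-nm localization noise at 10
frames/s:

```r
rec <- simulate_run(lattice_state(), motor_params("K560"),
                    map = map_params("FL_MAP7"), concentration = 1000,
                    max_time = 60, seed = 2)
rec
#> <run_record> K560: 21 productive events, 54 nm in 28.45 s (2 nm/s),
#>   ended by spontaneous

traj  <- make_trajectory(rec, noise_model(), seed = 3)
steps <- find_steps(traj)
classify_steps(steps)
#> # A tibble: 1 × 7
#>   n_steps forward_pct backward_pct sideways_pct large_jump_count ...
#> 1      15        33.3           40         26.7                6
```

On the crowded lattice the detected mix is dominated by sideways and
backward tether jumps (6 of 15 steps fall in the 16–64 nm jump band),
and the net velocity collapses — the high-concentration arm of the
biphasic curve seen one molecule at a time. `autoplot(traj, steps =
steps)` overlays the fitted plateaus on the trajectory; pooled over
hundreds of runs, `classify_steps()` reproduces the bare-lattice
(~9% sideways, ~3% backward) and saturating (~35%/~26%) stepping
statistics.

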