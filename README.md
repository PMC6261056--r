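# motorcargo

Simulation and single-particle-tracking analysis of intracellular cargo
transport by molecular motors on microtubules, centred on **non-Markovian
detachment kinetics**: motors whose detachment rate decreases with the time
since they last attached.

A cargo moves in 2D under overdamped Langevin dynamics driven by fractional
Gaussian noise (Hurst exponent `H = 0.35` by default, giving sub-diffusive
free motion) and is pulled by a motor through an elastic tether. The motor
steps 8 nm at a force-dependent rate with a square-root stall law, detaches
with either a constant (Markovian) or run-time-dependent (non-Markovian)
hazard times an Arrhenius load factor, and reattaches at constant rate. The
run-time-dependent hazard produces power-law run durations (tail exponent
`mu = 1.4`), which makes the cargo super-diffusive at long times: its
time-averaged variance (TAVAR, the TAMSD with drift removed per lag) grows
as `lag^(3 - mu)`.

The package provides:

* **noise** — exact (Hosking) and spectral (circulant-embedding) fractional
  Gaussian noise generators, validated against the closed-form
  autocovariance;
* **kinetics** — detachment/residence-time models (`markov_rate`,
  `nonmarkov_rate`, `gamma_mixture`, `discrete_mixture`,
  `cooperative_model`) with rates, survival functions, densities, exact
  samplers and a Hill-type tail-exponent estimator;
* **dynamics** — the motor–cargo simulator (`sim_config`,
  `simulate_cargo`, `simulate_many`), optional blocking filament geometry,
  measurement noise;
* **analysis** — TAMSD / TAMD / TAVAR / detrended TAMSD, anomalous-exponent
  fits, mean first passage times, pooled window-velocity histograms and
  peak detection;
* **scenarios** — run-and-rest renewal ensembles, the blocked-filament
  comparison of Markovian vs non-Markovian kinetics, free-run distance
  matching, neighbouring-filament reach probabilities;
* **I/O and CLI** — lossless trajectory CSV, YAML configs that round-trip
  bit-exactly, result tables with metadata headers, run manifests, and a
  command-line interface (`inst/cli/motorcargo`).

## Worked example

```r
library(motorcargo)

cfg <- sim_config(duration = 60, dt = 1e-4,
                  detachment = nonmarkov_rate(1.4, 1), seed = 42)
cfg
#> sim_config: T = 60 s, dt = 0.0001 s, H = 0.35, D* = 0.002
#>   motor: v0 = 4 um/s, d = 8 nm, F_s = 2.5 pN, F_d = 3 pN, backstep = 0.25
#>   tether: l = 100 nm, k = 0.32 pN/nm; drag beta = 0.72 pN s/um
#>   attachment rate = 1 /s; detachment: nonmarkov_rate

traj <- simulate_cargo(cfg)
traj
#> trajectory: 600001 samples, dt = 0.0001 s, duration = 60 s
#>   attached fraction: 0.336
#>   x range [-0.01276, 23.81] um, y range [-0.3523, 0.3651] um

# super-diffusive long-lag TAVAR exponent (ensemble average -> ~1.5;
# a single 60-s trajectory is noisier and biased low at these lags)
curve <- tavar(traj, lag_grid(traj, 0.5, 6))
round(as.numeric(anomalous_exponent(curve, c(0.5, 6))), 3)
#> [1] 1.419

# dominant non-zero peak of the pooled window-velocity distribution
vh <- velocity_distribution(traj, breaks = seq(0, 80, by = 0.05))
dominant_peak(vh)
#> [1] 1.175

# the non-Markovian detachment rate starts at mu/tau_d and decays
detachment_rate(nonmarkov_rate(1.4, 1), tau = c(0, 1, 4))
#> [1] 1.40 0.70 0.28

# run-time samples from the equivalent gamma rate mixture have a
# power-law tail whose exponent is recoverable from data
runs <- sample_run_time(gamma_mixture(1.4, 1), n = 1e4, seed = 1)
fit_tail_exponent(runs, tail_fraction = 0.02)
#> [1] 1.367175
#> attr(,"k")
#> [1] 200
#> attr(,"xmin")
#> [1] 16.37608
```

## Command line

```sh
inst/cli/motorcargo fixture  --kind full_model --out traj.csv --seed 5 --duration 10
inst/cli/motorcargo analyze  --traj traj.csv --stat tavar --out tavar.csv \
                             --fit-lo 0.5 --fit-hi 1 --lag-min 0.001 --lag-max 1
inst/cli/motorcargo ensemble --mu 1.4 --tau-d 1 --n 50 --duration 100 --out-prefix ens
```

Every stage writes a YAML manifest (`*.manifest.yaml`) recording the
configuration, package version, seeds and outputs needed to re-run it
bit-identically.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model
equations, units, noise-amplitude conventions, the per-lag detrending
behind the TAVAR identity, the velocity-peak definition, the scenario
rules, and the finite-duration and velocity-peak analyses behind the two
deliberate deviations noted above.
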