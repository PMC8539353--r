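# seedkin

Water-dynamics kinetics of germinating seeds: from per-seed mass time series
to velocity/acceleration of water uptake, Fick-diffusion coefficients,
bootstrap confidence intervals, seed-vigor indices and correlation screening.

## The problem

Seed physiologists and seed-testing laboratories want cheap, fast,
non-destructive predictors of seed-lot vigor. Weighing individual seeds
hourly during germination *sensu stricto* (from imbibition to embryo
protrusion) yields per-seed mass trajectories \(M_t\) whose dynamics carry
that information. **seedkin** turns those trajectories, plus standard
germination/seedling assay counts, into the quantitative traits used to
compare seed lots:

- normalized mass \(m_t = M_t/M_0\), interpolated by cubic splines;
- uptake **velocity** \(v = dm/dt\) and **acceleration** \(a = d^2m/dt^2\),
  with time averages over the germination window \([0,\tau]\)
  \[ v_m = \frac{1}{\tau}\int_0^\tau v\,dt, \qquad
     a_m = \frac{1}{\tau}\int_0^\tau a\,dt \]
  computed by exact piecewise-polynomial integration;
- the **initial diffusion coefficient** \(D/\rho^2\) (h⁻¹) and saturation
  uptake \(M_\infty\), fitted by Levenberg–Marquardt least squares to the
  spherical series solution of Fick's second law
  \[ \frac{M_t}{M_\infty} = 1 - \frac{6}{\pi^2}\sum_{n=1}^{N}
     \frac{1}{n^2}\, e^{-D n^2 \pi^2 t/\rho^2} \]
  on the early, purely physical imbibition window;
- percentile-bootstrap confidence intervals (B = 1000) for sample means;
- vigor measurements from assay counts: biological activity
  \(A = G\cdot V/100\), seedling vigor index \(SVI = 100\cdot AA/NS\),
  seed–seedling transition yield index \(SSYI = 100\cdot NS/G\), and
  low/intermediate/high quality classification;
- residual-standardized Pearson correlations between kinetic and vigor
  characteristics, with Student-t screening at α = 0.01 and magnitude
  labels.

A synthetic-lot generator (`lot_preset()`, `simulate_lot()`) emulates the
measurement design — 50 seeds weighed hourly until 2 h after each seed's
protrusion — with known injected parameters, so the whole pipeline is
testable end to end without laboratory data.

## Worked example

Simulate a high-quality lot and analyze it:

```r
library(seedkin)

spec <- lot_preset("high")            # injected truth: D/rho^2 = 0.0016 1/h
lot  <- simulate_lot(spec, seed = 42) # trajectories + assay + truth

k <- seed_kinetics(lot$trajectories)  # one row per seed: tau, v_m, a_m
dplyr::summarise(k, n = dplyr::n(), v_m = mean(v_m), a_m = mean(a_m))
#>       n    v_m     a_m
#> 1    50 0.0453 -0.0140

bootstrap_mean(k$v_m, B = 1000, seed = 42, label = "v_m")
#> v_m = 0.0452564, 95% percentile bootstrap CI (0.0443312, 0.0460644), B = 1000, n = 50

fit_fick(lot$trajectories, t_cut = 3, loss = "relative")
#> Spherical Fick-diffusion fit (uptake mode)
#>   D/rho^2: 0.000935054 1/h   M_inf: 0.200644 g
#>   window: [0, 3] h, 4 points, 50 series terms
#>   SSE: 9.021e-05   converged: TRUE

summarize_assay(lot$assays)[, c("sample_id", "G", "V", "NS", "AA", "A", "SVI", "SSYI")]
#>   sample_id     G     V    NS    AA     A   SVI  SSYI
#> 1 high       98.5  98.5  98.5  96.5  97.0  98.0   100
```

The kinetic rows say: averaged over its germination window, each seed of
this lot gained about 0.045 g of water per hour per gram of initial mass,
decelerating at −0.014 g h⁻²; the bootstrap interval localizes the lot mean
tightly. The diffusion fit, from only 4 hourly points, recovers the order of
magnitude of the injected 0.0016 h⁻¹ (this weak identifiability is a feature
of the measurement design, discussed in the vignette). The assay block
reproduces the high-quality profile: near-complete germination and
viability, \(SVI\) close to 100 (stressed seeds almost as capable as
unstressed), \(SSYI = 100\) (every germinated seed produced a normal
seedling).

The full pipeline — all stages plus CSV outputs and a markdown summary —
is one call:

```r
run_pipeline(lot$trajectories, lot$assays, out_dir = "out", seed = 1)
```

or, from a shell, `Rscript inst/cli/seedkin.R simulate|run ...`.

## Package layout

- `R/io.R` — CSV readers/writers, validation, normalization, quality bands
- `R/kinetics.R` — splines, derivatives, exact time averages
- `R/fick.R` — series solution, truncation-order selection, LM fitting
- `R/resample.R` — percentile bootstrap, convergence check, interval overlap
- `R/vigor.R` — A, SVI, SSYI, assay summaries
- `R/correlate.R` — residualization, Pearson screening, magnitude labels
- `R/synth.R` — lot presets and simulators
- `R/pipeline.R` — `run_pipeline()` orchestration
- `vignettes/seed-water-dynamics.Rmd` — models, assumptions, numerical
  choices, limitations
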