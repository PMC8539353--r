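---
title: "Water dynamics in germinating seeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water dynamics in germinating seeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedkin)
```

## The measurement and the quantities of interest

A germinating seed takes up water in phases: a fast, physically driven
imbibition of the dry tissue, then a metabolically controlled phase that ends
with embryo protrusion (the root or cotyledon breaking through the coat —
the endpoint of germination *sensu stricto*). Weighing each seed on a
laboratory balance every hour, from sowing until two hours after its
protrusion, yields one mass trajectory per seed. Everything this package
computes derives from those trajectories plus standard germination-assay
counts.

Per seed, the mass recordings $M_t$ are normalized by the initial
(hygroscopic-equilibrium) mass, $m_t = M_t / M_0$, making seeds of different
size comparable. Three kinetic quantities summarize a trajectory:

* **velocity** $v = dm/dt$ (g H~2~O h^-1^ per unit initial mass) — the water
  flux into the seed, an energy-*input* measurement;
* **acceleration** $a = d^2m/dt^2$ (g H~2~O h^-2^) — the rate of change of
  that flux, an energy-*use* measurement;
* their **time averages** over the germination window $[0, \tau]$,
  $v_m = \tfrac{1}{\tau}\int_0^\tau v\,dt$ and
  $a_m = \tfrac{1}{\tau}\int_0^\tau a\,dt$, where $\tau$ is the last
  recorded time.

Acceleration is deliberately reported in h^-2^: it is the second time
derivative of a dimensionless mass ratio, so only time units appear.

## Spline interpolation and exact time averages

`fit_spline()` interpolates $m_t$ with a cubic spline: the interpolant passes
through every recording and has continuous first and second derivatives, so
$v(t)$ and $a(t)$ are smooth. The end condition is the
Forsythe–Malcolm–Moler rule (an exact cubic through the four points at each
end). We chose it over natural end conditions for a concrete reason: it
reproduces polynomials up to degree 3 *exactly*, so data sampled from a line
or parabola return their slope and curvature to machine precision — a clean
oracle for testing — whereas natural splines force $a = 0$ at both ends and
bias the acceleration curve there.

`time_average()` integrates the piecewise cubic analytically, interval by
interval, instead of quadrature on a grid. Consequently the calculus
identities

$$ v_m = \frac{m(\tau) - m(0)}{\tau}, \qquad
   a_m = \frac{v(\tau) - v(0)}{\tau} $$

hold to floating-point accuracy for every fitted seed; the test suite
verifies them on 100 randomly generated trajectories at relative tolerance
$10^{-8}$.

Each seed is integrated over its **own** $\tau$ (its last recording, i.e.
protrusion + 2 h for germinating seeds, the observation horizon otherwise).
The alternative — one common $\tau$ per sample — would require extrapolating
censored seeds beyond their data, which the spline deliberately refuses to
do. Sample-level $v_m$, $a_m$ are means of the per-seed values.

```{r kinetics-example}
traj <- tibble::tibble(seed_id = "s1", time_h = 0:10,
                       mass_g = 0.15 * (1 + 0.058 * (0:10)))
seed_kinetics(traj)
```

## The spherical diffusion model of imbibition

Early uptake is modeled by the series solution of Fick's second law for a
sphere of radius $\rho$:

$$ \frac{M_t}{M_\infty} = 1 - \frac{6}{\pi^2} \sum_{n=1}^{N}
   \frac{1}{n^2} \exp\!\left(-\frac{D n^2 \pi^2 t}{\rho^2}\right) $$

The rate constant is estimated as the ratio $D/\rho^2$ (h^-1^), the *initial
diffusion coefficient*, which absorbs seed size and partially compensates
shape-approximation errors. `fit_fick()` estimates $D/\rho^2$ and the
saturation level $M_\infty$ by Levenberg–Marquardt least squares
(`minpack.lm`), restricted to the imbibition window `[0, t_cut]` — before
metabolic uptake contaminates the physical signal. Tunables, with defaults:

* `t_cut = 3` h. The model describes only imbibition *per se*; three hours
  of hourly data (4 points) is the shortest window that still identifies two
  parameters while staying safely inside the physical phase for soybean-like
  seeds. It is configurable because faster- or slower-imbibing species move
  the phase boundary.
* `n_terms = 50`. Truncation order of the series. Fifty terms make the
  truncation residue negligible against measurement noise on this window;
  `select_n_terms()` implements the SSE-plateau rule (smallest order whose
  SSE matches the largest candidate's to a relative $10^{-6}$) when a
  data-driven choice is wanted.
* `mode = "uptake"` (default) fits the mass *gain* $M_t - M_0$ with
  $M_\infty$ reinterpreted as saturation uptake. The raw series implies
  $M(0) = 0$, but a real seed starts at $M_0 > 0$; referencing both data and
  model to $t = 0$ respects the series' boundary condition while matching
  real recordings. `mode = "strict"` fits raw $M_t$ for comparison. In
  uptake mode the model subtracts its own truncated $t=0$ value (about
  $6/(\pi^2 N)$), so a noise-free round trip is exact rather than
  tolerance-limited.
* `loss = "absolute"` minimizes squared residuals on the mass scale, the
  classical objective. `loss = "relative"` minimizes squared *log* residuals
  — the maximum-likelihood objective when noise is multiplicative, which is
  what a balance with fixed relative precision produces. Under 1%
  multiplicative noise the relative loss estimates $D/\rho^2$ about an order
  of magnitude more precisely, because the early, small-uptake points that
  carry most of the information about $D$ are no longer drowned out by the
  large late values.
* Start values: $M_\infty \leftarrow 1.5\times$ the largest uptake in the
  window; $D/\rho^2 \leftarrow 0.001$ h^-1^. The $(D, M_\infty)$ objective
  has a long flat valley (early-time uptake constrains mainly
  $M_\infty\sqrt{D}$), so the optimizer is restarted from a deterministic
  ladder of $D$ guesses ($\times 0.1$ to $\times 10$) and the lowest-SSE
  solution kept. On clean data any start within a factor 10 of the truth
  reaches the global minimum; this is tested.

Per-sample coefficients are fitted on the sample's mean uptake curve
(pooled), one $D/\rho^2$ per sample; `per_seed = TRUE` exposes per-seed fits,
which also feed the correlation stage. Non-convergence is flagged in the
result, never raised, so one refractory seed cannot abort a batch.

## Bootstrap confidence intervals

Sample means of $v_m$ and $a_m$ carry percentile-bootstrap confidence
intervals (`bootstrap_mean()`): seeds are resampled with replacement
$B = 1000$ times — `convergence_check()` implements the rule used to justify
that count, the smallest $B$ whose interval endpoints move less than 1%
against the next larger candidate — and the 2.5% and 97.5% empirical
quantiles of the resampled means form the 95% interval. The seed (not the
time point) is the resampling unit: it is the only exchangeable unit in the
design, since within-seed recordings are strongly serially dependent.
Overlapping intervals are read as non-significant differences
(`ci_overlap()`).

Two properties anchor the implementation. At $n = 3$ the bootstrap
distribution can be enumerated exhaustively ($3^3 = 27$ equally likely
resamples); the percentile interval equals the inverse CDF of that exact law.
And over 500 simulated 50-seed lots, the 95% intervals cover the true mean
90–98% of the time (percentile intervals undercover slightly at this $n$,
which the band acknowledges).

## Vigor measurements

From assay counts (`summarize_assay()`), with all quantities in percent:

* **Biological activity** $A = G \cdot V / 100$, the germinability–viability
  product, analogous to thermodynamic activity = concentration × activity
  coefficient. $A \le \min(G, V)$ always; this package always computes the
  product form.
* **Seedling vigor index** $SVI = 100 \cdot AA / NS$: normal seedlings from
  stressed (accelerated-ageing) seeds relative to normal seedlings from
  unstressed seeds.
* **Seed–seedling transition yield index** $SSYI = 100 \cdot NS / G$: how
  many germinated seeds became normal seedlings.

$SVI$ is undefined at $NS = 0$ and $SSYI$ at $G = 0$; `summarize_assay()`
records these as `NA` plus a flag instead of failing. Reported percentages
are rounded to 2 decimals, half away from zero. Sample quality bands:
*high* when both $G$ and $V$ exceed 90%, *low* when $V \le 60$% and
$G \le 50$%, *intermediate* otherwise.

```{r vigor-example}
counts <- tibble::tibble(
  sample_id = "high", n_seeds = 200, germinated = 196, viable = 196,
  normal = 196, abnormal = 0, dead = 2, hard = 0,
  normal_after_ageing = 188, n_ageing = 200
)
summarize_assay(counts)
```

## Correlation screening

`correlation_matrix()` relates characteristics across seeds or replicates.
Values are first **residualized** (centered within sample) so that
correlations reflect within-sample association, not between-sample mean
differences; correlating raw values across samples of very different quality
would mostly restate the quality gradient. Pairwise Pearson coefficients are
tested with the Student $t$ statistic
$t = r\sqrt{(n-2)/(1-r^2)}$ at $\alpha = 0.01$, and labelled with magnitude
adjectives on $|r|$: negligible, low, moderate, substantial, very high,
perfect. The conventional band edges are printed to two decimals
(0.09/0.10, 0.29/0.30, ...), leaving gaps; the classifier uses the midpoints
(0.095, 0.295, 0.495, 0.695) as half-open boundaries so that every value in
$[-1, 1]$ receives exactly one label. Exact collinearity is snapped to
$|r| = 1$ (floating-point $r$ otherwise lands a few ulp short and would be
labelled "very high"). The residuals are per-seed or per-replicate values:
with only a handful of samples, correlating sample summaries would leave no
degrees of freedom for the $t$ test.

## The synthetic lot generator

No reference measurements ship with the package, so `lot_preset()` and
`simulate_lot()` generate lots that emulate the measurement design: 50 seeds
weighed hourly (assays on 200 seeds), each germinating seed censored at its
protrusion + 2 h, non-germinators at a 14 h horizon. The default mass model
is

$$ M(t) = M_0\,[\,1 + U \cdot \mathrm{ratio}(t; D/\rho^2) + L(t)\,] $$

Fickian imbibition plus a logistic metabolic surge $L$ switching on one hour
before protrusion — the classical three-phase picture is the exception
rather than the rule, and setting the surge amplitude to 0 recovers pure
imbibition, so both regimes are testable. Multiplicative lognormal noise
(sd 1%) emulates balance precision; the $t = 0$ recording is the
normalization reference and is left noise-free. Defaults chosen once as
realistic for soybean: $M_0 \sim \mathcal{N}(0.15, 0.01)$ g, diameter
$6.9 \pm 0.3$ mm, saturation uptake fraction $U = 1$, protrusion times
$\mathcal{N}(8, 1)$ / $\mathcal{N}(10, 1.5)$ / $\mathcal{N}(12, 2)$ h for
high/intermediate/low quality (truncated at 2 h).

The three presets inject reference kinetic values for low-, intermediate-
and high-quality soybean lots as ground truth ($D/\rho^2$ = 0.0014, 0.0018,
0.0016 h^-1^; $v_m$ = 0.055, 0.058, 0.055; $a_m$ = −0.0184, −0.0182,
−0.0164) together with band-consistent outcome probabilities, so recovery
tests can compare pipeline output against what was injected. `linear` and
`quadratic` trajectory modes produce data whose $v_m$/$a_m$ are known in
closed form. Assay outcomes are coupled draws: viable $\sim$ Bin($n$, $V$),
germinated among the viable, normal seedlings among the germinated — so
germinated $\subseteq$ viable by construction.

What the generator does **not** emulate: tegument damage physics, TTC
staining chemistry, the ageing-chamber protocol (AA enters only as a
probability), seed-to-seed correlation of noise, or balance drift. Passing
recovery tests therefore show the *estimators* are correct and well
calibrated under the stated noise model — not that real soybean lots satisfy
that model.

## Numerical choices and degenerate inputs

* Splines require ≥ 4 distinct knots; fewer is a degenerate-input error.
  Extrapolation beyond a seed's recorded window is refused.
* `fick_ratio()` is never clipped; its $t = 0$ value is the truncation
  residue and converges to 0 as $N$ grows.
* The SSE-plateau rule uses an absolute floor of $\sqrt{\epsilon}$ when the
  reference SSE is exactly 0 (noise-free data), keeping the plateau
  detectable.
* Bootstrap intervals use the type-7 empirical quantile; with a fixed RNG
  seed every interval is reproducible, and the pipeline reports the seed in
  its outputs.
* Zero-variance inputs to the correlation are an explicit
  undefined-correlation error, not `NA` propagation.
* Trajectory CSVs are written with round-trip (17 significant digit)
  formatting and re-parsed with base `strtod`, so write/read cycles are
  bit-exact.

## Problem sizes used by the test suite

The suite exercises: 100 random splines for the calculus identities, 500
simulated lots for interval coverage, 3000 replicates for the correlation
type-I rate, 200 noisy refits for diffusion-coefficient recovery, and
exhaustive enumeration (27 resamples) for the bootstrap oracle. These sizes
give each stochastic check a comfortable margin relative to its binomial
sampling error while keeping a full run fast on a single CPU.

## Known limitations

* With hourly sampling, the default 3 h imbibition window gives the pooled
  per-sample fit only 4 points for 2 parameters; under 1% multiplicative
  noise $D/\rho^2$ is then identified only to within roughly a factor of 2
  (the objective's flat $M_\infty\sqrt{D}$ valley). Denser early sampling or
  a longer uncontaminated window sharpens it — the 12-point, 12 h
  noisy-recovery benchmark reaches a median error of about 1.5% with the
  relative loss. Treat single-sample $D/\rho^2$ values from the default
  design as indicative.
* Only spherical geometry is implemented; non-spherical diaspores would need
  a different eigenfunction series.
* The assay stage reports raw percentages with the derived indices; it does
  not refit binomial GLMs or run multiple-comparison procedures on assay
  proportions.
* Published index values are not always reproducible from their printed
  inputs; where a simple formula and a printed value disagree, this package
  always computes the formula ($A = G\cdot V/100$, $SVI = 100\,AA/NS$,
  $SSYI = 100\,NS/G$) and leaves reconciliation to the analyst.
* Bootstrap intervals are percentile-only; no BCa or studentized variants.
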