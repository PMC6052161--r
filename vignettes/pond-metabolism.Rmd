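---
title: "Estimating whole-ecosystem metabolism under changing ice cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole-ecosystem metabolism under changing ice cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondmetab)
```

## The diel oxygen balance

`pondmetab` estimates daily whole-ecosystem gross primary production (GPP)
and ecosystem respiration (ER) from 10-minute dissolved-oxygen records in
shallow, polymictic ponds. The forward model steps modeled DO through one
day:

$$mO_i = mO_{i-1} + \frac{GPP}{z_{mix}}\,\frac{PAR_i}{\sum_j PAR_j}
       + \frac{ER}{z_{mix}}\,\Delta t
       + f\,K_i\,(O_{sat,i} - mO_{i-1})\,\Delta t$$

with three flux terms per step:

* **Production.** The day's areal GPP (g O~2~ m^-2^ d^-1^), divided by the
  mixing depth $z_{mix}$, is apportioned across steps in proportion to PAR.
  We read the PAR normalizer as the *daily sum* of per-step PAR, so the
  weights sum to one and the whole daily rate enters the water column
  exactly — the explicit $\Delta t$ on the ER term corroborates this
  dimensional reading, and it makes GPP interpretable without reference to
  the grid. An all-dark day contributes no production term at all. GPP is
  strictly linear in the PAR fraction; there is no light-saturation
  (P–I) curve, by design.
* **Respiration.** ER is stored as a non-positive areal rate and *added*,
  scaled by $\Delta t$ — a constant drain around the clock.
* **Exchange.** $K_i$ (d^-1^) is the depth-normalized, temperature-corrected
  oxygen exchange rate and $O_{sat,i}$ the equilibrium concentration. The
  entire exchange term is multiplied by $f$, the fraction of pond area open
  to the atmosphere (0 under complete ice, 1 ice-free); $K_i$ itself is the
  ice-free rate. Under full ice the model therefore reduces to
  $\Delta DO = (GPP + ER)/z_{mix}$ per day exactly, the under-ice
  accumulation limit.

The update is the explicit (Euler-style) recursion exactly as written rather
than an exponential integrator: fidelity to the printed recursion is worth
more here than numerical elegance, and the per-step stability condition
$K_i \Delta t < 1$ (enforced with an informative error) is far from binding
at realistic exchange rates. Internally the affine recursion is solved with
a vectorized cumulative-product form when all step multipliers exceed 0.5,
and with a literal loop otherwise; both are the same recursion to
floating-point round-off, and the telescoping mass balance holds to 1e-10.

## Gas-exchange physics

* **K600 from wind**: the Cole–Caraco relation
  $k_{600} = 2.07 + 0.215\,U_{10}^{1.7}$ (cm h^-1^). The wind model is
  configurable (a constant-K600 alternative is built in) because small,
  sheltered ponds are at the edge of any wind parameterization's domain.
  Station wind is taken as $U_{10}$ with no height correction, and no
  fetch/sheltering correction is applied.
* **Schmidt scaling**: $k_{O_2} = k_{600}\,(Sc_{O_2}/600)^{n}$ with
  $n = -0.5$ by default (wavy, low-wind surfaces; $-2/3$ available), using
  the freshwater Sc(O~2~) polynomial (about 530 at 20 °C).
* **Saturation**: Benson–Krause (the USGS tables' formulation), with a
  multiplicative barometric-pressure ratio and an exponential salinity
  correction (salinity 0 by default). The unit tests pin these against an
  independently evaluated Garcia–Gordon oracle.
* $K_i = k_{O_2} \cdot 0.24 / z_{mix}$ converts cm h^-1^ to m d^-1^ and
  normalizes by the mixing depth, which varies daily with ice thickness.

DO and PAR sensors sit mid-column in these well-mixed ponds; readings are
treated as representative of the mixed column with no depth correction.

## Inference

The observation model is independent Gaussian error with standard deviation
$\sigma$ (g O~2~ m^-3^), estimated as a third parameter rather than fixed —
"best fit" alone does not define a posterior, and the noise level of optical
DO sensors is not known a priori. Priors are weakly informative:
GPP ~ N(3, 10), ER ~ N(−5, 10) (both unbounded), σ half-normal with scale 1.
GPP is deliberately *not* constrained positive during sampling; days whose
posterior-median GPP is negative are removed afterwards by the quality
filter, which keeps the sampler's geometry simple and matches how such days
are screened in practice. ER is likewise left unbounded and reported.

**The initial condition is a nuisance parameter.** Each pond-day is fitted
independently, anchored at its first DO observation. Fixing the initial
state *equal* to that observation, however, treats a noisy reading as exact:
its error propagates down the whole modeled day and inflates GPP/ER error
well beyond the posterior width (in simulation, 95% intervals covered truth
only ~30% of the time). We therefore sample the initial DO as a fourth
parameter with a flat prior, initialized at the first observation and
informed by it through the likelihood (its residual is in the Gaussian
product like any other point). That keeps the observation model coherent
and restores nominal interval coverage (~95% in simulation).

Because the forward model is linear in (GPP, ER, initial DO) for fixed
forcing, `fit_day()` evaluates the likelihood through precomputed sufficient
statistics of that decomposition — identical to the direct computation to
round-off (a unit test replays chain states through `log_posterior()`), and
fast enough that a 10 000-iteration day fits in a fraction of a second. The
residual sum of squares is clamped at zero to absorb floating-point
cancellation in near-perfect fits.

**Sampler.** Random-walk Metropolis with symmetric Gaussian proposals;
10 000 iterations with the first 1 000 discarded as burn-in. A pre-run
tuning phase (blocks of 100, at most 15) adapts the proposal towards a
20–45% acceptance rate; when a block accepts often enough to be informative
the proposal is reshaped to the chain's local covariance with the classic
$2.4/\sqrt{d}$ scaling, which is what lets the sampler follow the strong
GPP–ER–initial-DO ridge. Tuning requires two consecutive in-window blocks
after at least five, so scales frozen during the initial transient do not
stick; tuning draws are discarded and never count toward the 10 000. All
randomness is seeded: a fixed seed reproduces every chain bit-for-bit.

**Convergence and QC.** Summaries are posterior medians and central 95%
intervals after burn-in; convergence is checked with the split-$\hat R$
statistic (the retained chain's two halves; pass at $\hat R \le 1.05$; a
zero-variance chain has undefined $\hat R$ and is flagged rather than
erroring). Day-level filters then flag: `negative_gpp` (posterior-median
GPP < 0), `poor_fit` (r² < 0.5 or RMSE > 0.5 g m^-3^ between measured and
modeled DO at the posterior median; thresholds are package defaults exposed
in `qc_config()` since "poor fit" is not otherwise quantified; boundary
values are kept), `no_convergence`, and `data_gap` (forcing gaps longer
than 30 minutes invalidate a pond-day; shorter gaps are linearly
interpolated and flagged). A day is retained iff it has no flags.

## The synthetic experiment

`generate_experiment()` emulates a replicated spring ice-removal experiment:
4 control + 4 treatment ponds of mean depth 1.48 m, three periods (10 days
with 10% of the treatment ponds' ice removed, 10 days at 50%, 11 days
ice-free), a 10-minute sensor grid (144 points per day), and one shared wind
record. Its defaults are the package's statement of the study conditions:

* **Ice and mixing.** Treatment ponds step 0.10 → 0.50 → 1.0 in open-area
  fraction; control ponds follow a smooth exponential melt ramp reaching 1
  exactly at the ice-free period's start. Ice thickness (0.5 m under full
  cover) thins proportionally, and $z_{mix}$ is the mean depth minus ice
  thickness.
* **Forcing.** PAR is a truncated half-sine with seasonally lengthening days
  and growing amplitude (peak 600 µmol m^-2^ s^-1^ at an underwater sensor),
  a lognormal daily cloudiness factor and per-step noise; temperature ramps
  1 → 8 °C with a small afternoon-peaked diel cycle; wind is a positive
  AR(1) process (mean 3 m s^-1^, sd 1, lag-1 correlation 0.7).
* **CO2.** Dissolved CO2 starts supersaturated under ice (150 ± 8 µmol L^-1^
  between ponds) and relaxes towards atmospheric equilibrium (20 µmol L^-1^)
  at a daily rate proportional to the open-area fraction (0.25 d^-1^ fully
  open) plus small daily noise. This is deliberately phenomenological — a
  first-order vent-to-atmosphere, not carbonate chemistry — because the
  analysis only needs realistic covariation between ice treatment and CO2.
  Absolute concentrations are order-of-magnitude choices for boreal
  under-ice conditions, not measured values.
* **Coupling.** True daily GPP = 0.3 + 0.02·CO2 + N(0, 0.5), floored at 0;
  the noise scale is set so the daily GPP–CO2 correlation lands around
  0.85–0.9, inside the 0.7–0.95 band the generator is meant to produce.
  A linear-with-noise coupling is the simplest mechanism consistent with
  analysing the relationship by linear correlation. ER is drawn near
  −3.2 ± 0.4 and capped at 0. DO observations come from the package's own
  forward model plus N(0, 0.05) sensor noise, chained across days through
  the clean end-of-day state.

What the generator does *not* emulate: vertical structure or stratification,
light attenuation responding to ice (PAR is independent of treatment, which
is also what makes the PAR treatment tests null), nutrient or food-web
dynamics, carbonate equilibria and pH, sensor drift and fouling, or data
gaps. Passing tests on this generator therefore demonstrate that the
estimator and statistics behave correctly when the model that generated the
data is the model being fitted — they cannot certify robustness to the
structural surprises of real sensor records.

## Treatment statistics

Analysis runs on pond × period means of retained day-fits and the measured
drivers (`period_means()`), mirroring a design where the pond is the
experimental unit.

* **Per-period t-tests.** The default `paired` mode pairs the 4 control with
  the 4 treatment ponds by the rank of the response within each group and
  tests the mean pairwise difference (df = n − 1 = 3). A 4-pair design is
  what reproduces df = 3 with n = 4 per group; since no explicit pairing
  rule is available, within-group rank is this package's convention, and the
  unpaired Welch test is one switch away. Rank pairing shrinks the variance
  of the differences, so for responses that are essentially identical across
  ponds the paired statistic can be large while meaningless — zero-variance
  differences are reported as degenerate rather than significant.
* **Repeated-measures ANOVA.** Pond as subject, period within-subject, group
  between-subject; the group × period interaction is the treatment test,
  with df = (periods − 1, (periods − 1)(ponds − groups)) = (2, 12) for the
  default design. The Greenhouse–Geisser epsilon and corrected p-value are
  computed and reported alongside, but the uncorrected integer df remain the
  headline. Missing cells are an explicit error; nothing is imputed.
* **Pearson correlations.** GPP against CO2, PAR and temperature within each
  group, over the pond × period means (12 points per group), with two-sided
  p from the t transform. Tests are two-sided throughout and no
  multiple-testing correction is applied.

## Numerical and interface choices

* Timestamps are a continuous local clock (stored as UTC) with no DST
  handling — the model only needs a uniform $\Delta t$.
* The canonical CSV dialect (`timestamp,value`, ISO times, 10 significant
  digits) round-trips byte-stably.
* Grid-search/posterior-mode comparisons break ties by the first maximum in
  column order; the acceptance machinery uses a 0.05 g O~2~ m^-2^ d^-1^ grid.
* Problem sizes in the tests and acceptance script are chosen to exercise
  the full protocol at desk scale: the complete default experiment is
  8 ponds × 31 days (248 day-fits at 10 000 iterations each), parameter
  recovery uses independent single days at the same chain length, and the
  bit-reproducibility check runs a 2 + 2-pond, 9-day scenario twice.

## Known limitations

* A single well-mixed layer: no metalimnetic oxygen dynamics, no benthic
  boundary layer; GPP and ER are whole-column aggregates.
* Pure process simulation with observation error: the state is never
  re-anchored to observations within a day, and there is no process-error
  (state-space) variant.
* One day is fitted at a time; no hierarchical pooling across days or ponds.
* At very low wind and under heavy ice the GPP–ER ridge flattens and chains
  mix more slowly; the convergence filter catches most such days, at the
  cost of discarding them.
* The paired-by-rank convention is an analysis choice, not an estimated
  pairing; both t-test modes are exposed so the choice is visible.
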