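---
title: "Methods: the 4C reference model, its error budget, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 4C reference model, its error budget, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxa4c)
```

## The model and its assumptions

The four-compartment (4C) model partitions body weight at the molecular
level into fat, water, mineral and protein. Two identities define it:

$$BW = FM + TBW + Mo + Ms + P$$
$$BV = \frac{FM}{d_{fat}} + \frac{TBW}{d_{water}} + \frac{Mo}{d_{Mo}} +
      \frac{Ms}{d_{Ms}} + \frac{P}{d_{protein}}$$

with soft-tissue mineral modelled as $Ms = 0.0129\,TBW$ and osseous mineral
converted from DXA bone mineral content by $Mo = 1.0436\,BMC$. Solving for
$FM$ yields a linear form in $(BV, TBW, Mo, BW)$. The package *derives* the
coefficients from the densities rather than hard-coding the conventional
printed ones: the derived values (2.747, −0.699, 1.129, −2.050) agree with
the convention (2.748, −0.699, 1.129, −2.051) to one unit in the third
decimal, a residue of rounding inside the published coefficients. Deriving
keeps the forward model, the FFM decomposition and the generator's inverse
(`body_volume_from_components()`) exactly consistent, which the round-trip
property tests exploit at machine precision.

Assumptions inherited from the model: the component densities are constant
across subjects and phases; fat is the non-essential lipid pool (in very
lean athletes essential lipids become a non-negligible share of total
lipids, so the criterion itself may understate FM at ~3 %FM); TBW, BMC and
BV are error-free inputs at analysis time (their uncertainty is handled
separately by the TEM machinery).

### Tunable constants

| parameter | default | units | why |
|---|---|---|---|
| water / Mo / Ms / protein density | 0.9937 / 2.982 / 3.317 / 1.34 | g/cc | reference component densities |
| fat density | 0.9007 | g/cc | standard triglyceride value; not printed in the source tables, hence configurable |
| Ms per TBW | 0.0129 | kg/kg | soft-tissue mineral model |
| BMC→Mo | 1.0436 | – | ashed-bone correction |
| LOA multiplier | 1.96 | – | the 95% definition (the "±2 SD" shorthand is not used) |
| normality gate | Shapiro–Wilk at α = 0.05 | – | the source names no test; gate is logged and configurable |

SD uses the sample (n−1) denominator throughout; SEE uses n−2. Masses are
kg, volumes L, densities g/cc, so the kg/L ≡ g/cc equivalence needs no
conversion factors. Non-physiological fat-mass estimates are *flagged*
through the warning channel, never clipped: at the fat levels of interest
(~3 %FM) clipping would silently mask generator or data errors.

## Error propagation

Because the 4C model is linear and squared technical errors of measurement
are independent and additive, the fat-mass TEM is the quadrature sum of the
instrument TEMs weighted by the model coefficients. TEM itself is fixed as
Dahlberg's $\sqrt{\sum d_i^2 / 2n}$ — the standard test-retest definition in
anthropometry; the source names TEM without defining it, and the cited
magnitudes are consistent with Dahlberg. Body-weight TEM defaults to zero
(scale precision is an order of magnitude below the other instruments) and
is configurable. The %FM error needs a body-weight denominator, supplied by
the caller; at the cohort mean (72.8 kg) the laboratory profile
(0.2 L, 0.3 kg, 0.02 kg) propagates to ≈0.81, i.e. ~1 %FM unit. A
1e6-draw Monte-Carlo perturbation oracle in the acceptance suite confirms
the analytic value within 1%.

## Statistical conventions

* Differences are always **DXA − 4C**; changes are always
  **pre-competition − stability**.
* Regression puts the **criterion (4C) on the predictor (DXA)**: with the
  published stability means, slope 1.03 · 12.1 − 3.24 ≈ 9.2 reproduces the
  4C mean, confirming this orientation.
* The Bland–Altman trend is the Pearson correlation of the differences with
  the methods' mean; it is reported with its p-value and flagged
  not-computable when a variance collapses.
* Exact fits (zero residual SE) make the identity t-tests 0/0; the package
  resolves them by contract: a coefficient exactly at its identity value
  reports p = 1, otherwise p = 0 (below the numeric floor).
* No multiple-testing correction by default, matching the unadjusted
  exploratory covariate scan; a Holm flag exists for stricter use.
* Correlation power uses the Fisher-z solution with variance 1/(n−3). At
  n = 27, α = 0.05, power 0.80 this gives 0.5167. The source prints 0.51,
  which corresponds to a 1/(n−2) convention or an exact noncentral-t
  computation; the package keeps the standard 1/(n−3) form and documents the
  0.01 gap rather than matching the printed digit.

## What the synthetic cohort emulates

`generate_cohort()` states a world, calibrated once, from the published
group statistics of an elite male judo cohort (n = 27, two phases one month
apart):

* baseline: BW ~ N(72.8, 7.1) kg, %FM ~ N(9.2, 4.1), FFM hydration
  ~ N(0.72, 0.02), mineral fraction ~ N(0.057, 0.003);
* 4C change scores: Δ%FM ~ N(−1.22, 2.70), ΔBW ~ N(−0.87, 1.93), hydration
  change ~ N(0.006, 0.016), Mo constant across phases (the observed mineral
  fraction change is 0.000);
* DXA: stability %FM error model (bias +2.9, SD 3.1, r 0.78) and a
  conditional-normal change model hitting mean −0.41, SD 1.05 and
  correlation 0.53 with the 4C change.

Three design choices deserve explanation:

**Derived change correlation.** Since ΔBW = ΔFM + ΔFFM, the four change
marginals cannot all be free. The generator draws (Δ%FM, ΔBW) bivariate
normal with a correlation derived by the delta method so the implied ΔFFM
SD matches the configured 2.04 kg (≈0.40 at the defaults). Only the %FM
change carries the explicit DXA error construction; FM and FFM changes
follow from mass closure (`dxa_fm + dxa_ffm = bw` exactly). Analytically the
implied DXA-vs-4C change correlations are then ≈0.61 for FM and ≈0.62 for
FFM against printed 0.60/0.62 — internal consistency is bought at the price
of ~10% slack in the implied FM/FFM change SDs, which no test asserts
tightly.

**Trend as variance shrinkage.** For bivariate-normal changes the
difference-vs-mean covariance is $(\sigma^2_{DXA} - \sigma^2_{4C})/2$. The
trend coefficient is therefore parameterized as
$\tau = 1 - \sigma_{DXA}/\sigma_{4C}$: the default, derived from the SD
targets (≈0.61), reproduces the published significant negative trend ("DXA
overestimates losses, underestimates gains"); $\tau = 0$ gives equal
variances and hence *exact* independence of difference and mean — the true
null used by the type-I-error property test (which also moves the baseline
%FM to 20 so the floor machinery stays inactive).

**Trajectory-shift floors.** Latent %FM is floored at 2.5 (athletes near
3 %FM are realistic; negative fat is not). A plain clamp of the
pre-competition value would distort the realized change moments by more
than 1% (about 13% of trajectories dip under 2.5 at the default
calibration). Instead a violating subject's whole two-phase trajectory is
shifted up by the deficit, preserving the drawn change score exactly;
events are counted in the cohort metadata. The same rule guards DXA %FM
(floor 1.0) and body weight (floor 40 kg, ~1 in 10⁵ draws).

**What it does not emulate** — and therefore what a green test does not
establish: cross-sectional pre-competition DXA moments are implied rather
than targeted (the implied SD is ~3.3 vs the printed 2.8); no dehydration
physiology, panting-maneuver or isotope-dilution detail (BV and TBW are
generated at the final-measurement level; the deuterium 4% dilution-space
correction is upstream of scope); no real DXA beam physics, so the
hydration-related error mechanisms discussed for real instruments arise here
only through the stochastic error model; regional splits are proportional
decorations, not a regional physiology model. Parameter-recovery tests
validate the pipeline against *this* stated world, not against any real
scanner's behaviour.

## Numerical choices and degenerate inputs

* FFM fractions must sum to 1 ± 1e-6; when reconstructing group-level FFM
  density from printed rounded fractions (0.72 + 0.057 + 0.22 = 0.997) the
  protein fraction is taken as the residual 1 − water − mineral, enforcing
  the precondition.
* Zero-variance paired differences: all-zero → t = 0, p = 1; constant
  non-zero → a degeneracy error (a shifted constant has no within-pair
  information for either test). The variance check uses a relative 1e-10
  tolerance because float subtraction of equal-up-to-shift vectors is not
  exactly constant.
* The normality gate subsamples 5000 evenly spaced differences above
  Shapiro–Wilk's n limit.
* Report bundles contain no timestamps, so identical configs produce
  byte-identical files (tested by hash-free line comparison).

## Known limitations

* The generator matches change-score structure exactly and cross-sectional
  structure approximately; studies of cross-sectional bias beyond the
  stability phase should treat its output accordingly.
* The precision-band filter applies to the DXA %FM change (the band *is*
  DXA's CV) with boundary values retained; the source text does not state
  which method's change it filtered on.
* Fisher-z power, identity-regression SEE and the LOA multiplier follow the
  standard conventions named above; alternatives (exact power, Deming or
  Passing–Bablok regression, repeated-measures LOA) are deliberately out of
  scope.
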