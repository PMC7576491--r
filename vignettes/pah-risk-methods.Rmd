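---
title: "Methods: seasonal PAH exposure and probabilistic cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal PAH exposure and probabilistic cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem and the model

Household coal combustion releases polycyclic aromatic hydrocarbons (PAHs)
that sorb to fine particulate matter (PM2.5) and are inhaled. `pahrisk`
models the inhalation cancer risk of school-age children from PM2.5-bound
PAHs, contrasting a coal-heating season with a non-heating season.

The chain has three deterministic links and one probabilistic one.

**Toxic equivalence.** A measured congener mixture is collapsed to a
BaP-equivalent concentration

$$\mathrm{BaP_{eq}} = \sum_i C_i \cdot \mathrm{TEF}_i ,$$

where $C_i$ is the concentration of congener $i$ (ng/m³) and
$\mathrm{TEF}_i$ its toxic equivalency factor relative to benzo[a]pyrene
($\mathrm{TEF}_{BaP} = 1$ by definition). The default TEF table follows the
Nisbet & LaGoy scheme, with one deliberate deviation: `tef(DahA) = 1`
rather than 5. At a DahA TEF of 5, dibenz[a,h]anthracene would dominate the
BaPeq budget at typical coal-combustion levels, which is inconsistent with
BbF being the second-largest contributor in this setting; the table is
config-overridable (`tef:` block) for studies that prefer the original
value.

**Dose.** The lifetime average daily dose, in mg per kg body weight per
day, is

$$\mathrm{LADD} = \frac{C \cdot EF \cdot ED \cdot CF \cdot IR}{BW \cdot AT},$$

with $C$ the BaPeq concentration (ng/m³), $EF$ the exposure frequency
(140 day/yr during heating, 220 day/yr otherwise), $ED = 10$ yr the
exposure duration, $CF = 10^{-6}$ mg/ng, $IR$ the inhalation rate (m³/day),
$BW$ the body weight (kg) and $AT = 25500$ day the carcinogenic averaging
time (70 years). $IR$ comes from spirometry: tidal volume (L/breath) times
breathing frequency (/min) times 1.44, the L/min → m³/day conversion.

**Risk.** $\mathrm{ILCR} = SF \cdot \mathrm{LADD}$ with
$SF = 3.14\,(\mathrm{mg\,kg^{-1}\,day^{-1}})^{-1}$, the standard BaP
inhalation slope factor. An ILCR above $10^{-6}$ is conventionally deemed
unacceptable; exceedance is strict (`>`), so a risk exactly at the
threshold does not flag.

On the choice of $SF$ and $CF$: a conversion factor written as "µg/100 ng"
is dimensionally incompatible with a slope factor per mg/(kg·day). With
$CF = 10^{-6}$ mg/ng and $SF = 3.14$ the deterministic mean-parameter risks
land on the reported seasonal values (≈ 3 × 10⁻⁶ heating, ≈ 5.7 × 10⁻⁸
non-heating), which is why those constants are the defaults. Both are
plain arguments of `exposure_scenario()` / `ilcr_scenario()`.

## Monte Carlo propagation

`run_ilcr_simulation()` samples the three uncertain parameters
independently per iteration — BaPeq, then IR, then BW, a fixed draw order
documented so that a given scenario seed yields a bit-identical draw
vector — and pushes each triple through the dose and risk equations.
Scenario defaults per season:

| parameter | heating | non-heating | units |
|---|---|---|---|
| BaPeq | lognormal(log-mean 2.7, log-sd 0.4) | lognormal(−2.4, 1) | ng/m³ |
| IR | normal(35.1, 15.0), floor 0 | normal(42.1, 12.5), floor 0 | m³/day |
| BW | normal(29.9, 5.6), floor 0 | same | kg |
| EF | 140 | 220 | day/yr |

Three numerical decisions matter here:

- **Lognormal parameters are natural-log moments.** exp(2.7 + 0.4²/2)
  = 16.12 ng/m³ matches the measured heating BaPeq mean (16.3 ± 6.76);
  a base-10 reading would give ≈ 766 ng/m³, off by fifty-fold. The
  non-heating entry "N(−2.4, 1)", though written with a normal-distribution
  letter, sits in the lognormal family: read as lognormal it gives a mean
  of 0.15 ng/m³, consistent with the ≈ 0.2 ng/m³ seasonal BaPeq exposure
  and the reported non-heating risk; read as a normal it would be negative
  more than 99% of the time.
- **Truncation by resampling.** A normal IR with sd 15.0 on mean 35.1
  yields negative inhalation ≈ 1% of the time; draws below the floor
  (default 0) are rejected and redrawn. Among the simple options
  (clamping, folding, resampling), resampling perturbs the stated mean
  least and keeps the density shape above the floor.
- **Independence.** No correlation structure is imposed between C, IR and
  BW; none is available to estimate.

With these defaults the simulated heating-season exceedance of 10⁻⁶ is
≈ 0.93, not the 85% sometimes quoted for comparable conditions; the exact
exceedance is sensitive to truncation and rounding conventions that are
not recoverable, so the package reports the computed value and its tests
assert only the robust contracts (heating exceedance > 0.5, non-heating
< 0.05).

`fit_exposure_distribution()` fits a normal to raw values and a normal to
log values (closed-form maximum likelihood) and selects the family with the
larger Kolmogorov–Smirnov p-value. The KS p-values use estimated
parameters and are therefore approximate; they are used only to rank the
two candidate families, never reported as calibrated significance levels.

## What the synthetic generator emulates

`generator_spec()` encodes the study conditions: four sex-by-season
participant groups (7/9/12/10 children) with group-specific height, weight
and inhalation-rate normals; one valid personal sample per participant;
and two fixed indoor/outdoor sample pairs per season.

Per-sample congener vectors are built top-down: the total ΣPAH is drawn
from a seasonal lognormal matched to the target mean/sd (heating
89.1/47.3 ng/m³; non-heating mean 1.75 ng/m³), then split across the 15
congeners by a season profile with multiplicative lognormal noise (log-sd
0.12) on the shares. Drawing congeners independently would not satisfy the
joint targets — 56% high-molecular-weight share, BaP ≈ 10.3 ± 4.79 within
[3.86, 21.86], IcdP/(IcdP+BghiP) = 0.51 ± 0.02 — so composition is
conditional on the total by construction. The two diagnostic isomer pairs
are re-split at drawn target ratios (pair sums preserved), the heating
IcdP ratio floored just above the 0.5 coal threshold so that every heating
sample carries the coal signature the fixed-seed classification tests
expect; heating BaA ratios are all > 0.42, non-heating ones are 75%
petroleum (< 0.2) and 25% mixed. Heating BaP is clamped to the printed
range [3.86, 21.86]; non-heating BaP is capped at 0.01 ng/m³; the clamp
residual is absorbed by Phe (TEF 0.001, so the BaPeq impact is negligible)
to preserve the drawn total.

Free choices the study does not pin down, made once and documented here:
the non-heating ΣPAH sd (0.9 ng/m³, the same ≈ 0.5 coefficient of
variation as the heating season), the composition-noise log-sd (0.12,
small enough that BaPeq stays approximately lognormal), the fixed-site
outdoor totals (45 and 2.5 ng/m³) and I/O ratio ranges (heating 1.3–3 for
all congeners but Acy, which stays ≤ 1; non-heating 0.3–0.9), and the
naphthalene exclusion (the 15-congener registry drops Nap, which is almost
entirely gas-phase and is absent from the particulate-phase seasonal
composition). One known tension is resolved in the generator: the light
(Ant 23%, Phe 15%, Fla 14%) profile belongs to the *non-heating* season,
since the heating season is explicitly 56% high-molecular-weight.

BaP's share is exempt from composition noise. Because BaP dominates BaPeq
and its range is clamped, noise on its share would couple the total and
the BaPeq/ΣPAH ratio in a way that has no tractable description; with the
share fixed, the generating BaPeq log-moments follow from one-dimensional
quadrature over the ΣPAH lognormal, and `ground_truth.csv` records those
quadrature values. Composition noise on the remaining 14 shares perturbs
only about a third of the BaPeq budget and shifts the log-moments by
< 0.002, an order of magnitude below the 3-standard-error resolution of
the recovery tests.

What the generator does **not** emulate: meteorology, stove-operation and
time–activity patterns, within-child repeated measures (each participant
contributes one sample), gas-phase PAHs, measurement error or nondetect
censoring (the IO layer supports nondetect flags, but generated data are
fully observed). Passing tests therefore demonstrate that the analysis
recovers the statistical structure it assumes — not that field data meet
those assumptions.

## Conventions and edge cases

- **Sample validity:** personal pump samples are valid at 22–26 h runtime
  inclusive; fixed-site samplers (48 h) are always retained.
- **Nondetects** are stored as 0 with an explicit flag (an LOD/2 policy is
  selectable); missing values stay `NA`, never silent zeros.
- **Diagnostic thresholds:** the literature states strict inequalities
  (< 0.2 petroleum, > 0.35 / > 0.5 combustion), leaving boundaries open;
  boundary values fall in the closed middle ("mixed") interval. A ratio
  with a zero pair sum is undefined — a value, not an error — and
  classifies as indeterminate. The combined two-ratio verdict takes the
  shared label on agreement, `mixed` on disagreement, and defers to the
  defined ratio when one is indeterminate.
- **I/O ratio of exactly 1** is indeterminate (the >1 / <1 rule assigns it
  to neither side); a zero outdoor concentration flags the ratio undefined.
- **Dispersion:** all "±" values are sample standard deviations (n − 1);
  single-sample summaries flag the sd as `NA` rather than reporting 0.
- **Tests are two-sided throughout**, with no multiple-testing correction;
  Welch's unequal-variance form is the unpaired default. Zero-variance
  inputs to the t-test or correlation are flagged degenerate instead of
  erroring mid-pipeline.
- **Units:** concentrations and PM2.5 are carried exactly as read
  (ng/m³); doses are reported in both mg/(kg·day) (the SF convention) and
  ng/(kg·day) (the field's display convention) — a presentation choice,
  not a model branch.

## Problem sizes

The shipped test-suite and acceptance runs use 10,000 Monte Carlo
iterations (the analysis default), 10⁵ draws for moment-vs-quadrature
checks, and generated cohorts of up to 10⁴ samples for parameter-recovery
checks; the default cohort mirrors the field study (38 participants, 46
samples). The full suite runs in well under a minute.

## Known limitations

- Inhalation only: no dermal or ingestion routes, no age-dependent potency
  adjustment beyond the single child scenario.
- TEF-based potency summation assumes additivity of congener effects.
- The diagnostic-ratio verdict is a coarse two-ratio rule, not a receptor
  model (no PMF/CMB).
- Seasonal scenario constants treat exposure frequency and duration as
  known; only C, IR and BW carry uncertainty in the Monte Carlo.
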