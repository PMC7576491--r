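# pahrisk

Seasonal exposure of schoolchildren to PM2.5-bound polycyclic aromatic
hydrocarbons (PAHs), and the cancer risk that follows from it.

In regions that heat with household coal, winter concentrations of
particle-bound PAHs indoors can be tens of times higher than summer ones,
and children — with higher inhalation rates per unit body weight than
adults — bear a disproportionate share of the resulting carcinogenic burden.
`pahrisk` implements the standard analysis chain for personal-sampler and
fixed-site PAH measurements in such settings, for exposure scientists and
environmental epidemiologists:

- **BaP-equivalent exposure.** A congener mixture is collapsed to a single
  carcinogenicity-weighted concentration with toxic equivalency factors
  (TEFs) relative to benzo[a]pyrene:
  `BaPeq = Σᵢ Cᵢ · TEFᵢ`.
- **Source attribution.** Indoor/outdoor concentration ratios (I/O > 1 ⇒
  indoor source) and isomer diagnostic ratios — BaA/(BaA+Chr) and
  IcdP/(IcdP+BghiP) with the conventional 0.2 / 0.35 / 0.5 thresholds —
  separate coal/biomass combustion from petroleum signatures.
- **Deterministic dosimetry.** Inhalation rate from spirometry
  (`IR = TV × BF × 1.44` m³/day), lifetime average daily dose
  `LADD = C·EF·ED·CF·IR / (BW·AT)` in mg/(kg·day), and incremental
  lifetime cancer risk `ILCR = SF × LADD` with SF = 3.14 (mg/kg/day)⁻¹
  and the conventional 10⁻⁶ acceptable-risk threshold.
- **Monte Carlo uncertainty propagation.** BaPeq, IR and BW are sampled
  from seasonal lognormal / truncated-normal distributions and propagated
  through the dose equations (10,000 iterations by default), with
  Kolmogorov–Smirnov selection between normal and lognormal exposure fits.
- **Synthetic cohorts.** A seeded generator reproduces the statistical
  structure of the seasonal study conditions (heating ΣPAH ≈ 89.1 ng/m³
  with a 56% high-molecular-weight, coal-signature composition; non-heating
  ΣPAH ≈ 1.75 ng/m³ with a light, petroleum-signature composition), so the
  entire pipeline is testable without any field data.

## Worked example

```r
library(pahrisk)

coh <- generate_cohort(generator_spec(seed = 1))
season_summary(coh$samples, "heating")
#> Season: heating  (n = 16 valid samples)
#>     metric    mean     sd     min    max
#>  sigma_pah  70.250 23.650  38.980 126.90
#>       pm25 227.900 33.730 177.500 294.20
#>        bap   8.121  2.735   4.506  14.67
#>      bapeq  12.040  4.088   6.638  21.93
#> PAH/PM2.5 mass fraction: 0.3083
```

Sixteen valid heating-season personal samples (pump runtime 22–26 h)
average 70 ng/m³ total PAH — a small-cohort draw around the 89.1 ng/m³
seasonal mean — of which 12 ng/m³ is BaP-equivalent, i.e. the mixture
carries the carcinogenic punch of 12 ng/m³ of pure BaP.

```r
run_ilcr_simulation(ilcr_scenario("heating", seed = 1))
#> ILCR Monte Carlo (heating season, 10000 iterations, seed 1)
#>   mean 3.42e-06  median 2.91e-06  sd 2.28e-06
#>   P5 8.45e-07  P95 7.66e-06  P(ILCR > 1e-06) = 0.926
```

The mean heating-season risk is ≈ 3.4 extra cancer cases per million
exposed children, roughly three times the 10⁻⁶ acceptable level, and 93% of
the simulated risk distribution exceeds that level. The same scenario for
the non-heating season gives a mean near 6 × 10⁻⁸, fifty-fold lower.

```r
personal <- coh$samples[coh$samples$sampler_kind == "personal", ]
bq <- setNames(bapeq_by_sample(personal), personal$participant_id)
source_scatter(personal)      # per-sample diagnostic ratios + verdicts
per_participant_risk(coh$participants, bq)
#> Per-participant inhalation cancer risk (n = 38 )
#> Mean ILCR 1.13e-06 (range 3.9e-09 - 5.74e-06); 42% exceed threshold
```

Every heating-season sample classifies as coal/biomass combustion
(BaA/(BaA+Chr) > 0.4 and IcdP/(IcdP+BghiP) > 0.5); the non-heating majority
classifies as petroleum.

A thin CLI wrapping these stages lives at `inst/cli/pahrisk.R`
(`make-fixtures`, `analyze`, `simulate` subcommands).

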