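# gapelimit

Analysis pipeline for field studies of **gape-limited predation**: how
often does a snake predator kill avian prey it cannot actually swallow,
and what do prey and predator body sizes have to do with it?

The motivating system is an invasive arboreal snake (attracted to
endothermic prey once larger than ~900 mm snout–vent length, SVL) preying
on starling fledglings (~60–86 g) tracked by known-fate radio-telemetry.
A failed ingestion attempt leaves a carcass matted in snake saliva
("slimed"), so — unusually for predation data — the failures are
observable. The package is aimed at movement/predation ecologists who have
two flat tables (telemetered prey with fate evidence; snake capture
events) and want the full inferential chain, plus a synthetic-data
generator so the chain is testable without field data.

## What it computes

1. **Cause-of-mortality classification** (`classify_fate`,
   `mortality_table`): deterministic evidence-precedence rules (snake
   saliva dominates cat-scavenging remains; censored birds excluded).
2. **Ingestion-failure rate** (`ingestion_failure_rate`): the binomial
   proportion slimed/(slimed + ingested) with a Wilson score interval,

   p̂ = k/n,  CI = [p̂ + z²/2n ± z√(p̂(1−p̂)/n + z²/4n²)] / (1 + z²/n).

3. **Prey-size effect** (`fit_logistic`, `wald_test`): a from-scratch
   binomial GLM, logit P(ingested) = β₀ + β₁·mass, fitted by IRLS with
   Fisher-information standard errors and a two-sided Wald z test.
4. **Predator-size effect** (`truncate_survey`,
   `bootstrap_mean_distribution`, `compare_observed`): the mean SVL of
   successful ingestors compared against a seeded bootstrap distribution
   of mean SVL for samples of 52 individuals from the >900-mm survey
   population (5000 resamples, type-7 quantile 95% interval).
5. **Relative prey mass** (`compute_rpm`, `rpm_summary`, `fit_ols`):
   RPM = prey mass / predator mass per successful ingestion, summarised as
   mean ± SE and range, plus a Gaussian OLS of prey mass on predator mass
   with a Wald t test.
6. **Synthetic data** (`synthetic_config`, `simulate_*`,
   `run_simulation`): truncated-normal prey masses, truncated-lognormal
   snake SVLs, calibrated size-dependent ingestion success, recapture
   structure, and the structural censoring of failed ingestors.

`run_analysis()` orchestrates everything, writes CSV result tables, a
plain-text report and a seed-stamped manifest. A thin command-line wrapper
with `simulate` / `analyze` / `bootstrap` / `report` subcommands ships in
`inst/scripts/gapelimit-cli.R`.

## Worked example

```r
library(gapelimit)

ingestion_failure_rate(82, 89)
#> 82 / 171 = 47.95% (Wilson 95% CI: 40.59% - 55.40%)

cfg <- synthetic_config(seed = 42L)            # study-scale defaults
run_simulation(cfg, "ex")                      # writes the input CSVs
res <- run_analysis("ex/fledglings.csv", "ex/snakes.csv", "ex/events.csv",
                    out_dir = "ex_out", seed = 42L)
writeLines(res$report)
```

```
[1] Mortality by cause
  total mortalities: 278
  ingested                           97 (35%)
  slimed                             79 (28%)
  cat (predation or scavenging)      75 (27%)
  ...
[2] Ingestion-failure (slimed) rate
  79 slimed of 176 snake-killed = 44.89%
  Wilson 95% CI: 37.73% - 52.27%
[3] Prey-size logistic regression (1 = ingested, 0 = slimed)
  slope per g prey mass: 0.0170 (SE 0.0254), Wald z = 0.670, p = 0.503
[4] Predator-size bootstrap
  population: 129 survey individuals > 900 mm SVL
  5000 resamples of 52: mean of means 1115 mm (1068-1167 mm 95% quantile interval)
  observed consumer mean 1185 mm: OUTSIDE the interval (above)
[5] Relative prey mass (RPM)
  n = 61: mean 38.3% +/- 2.1%, range 16.3% - 86.9%
[6] Prey mass vs predator mass (OLS)
  slope 0.0035 g prey per g predator (SE 0.0082), t(59) = 0.424, p = 0.673
```

Reading it: nearly half the snake-killed birds in this synthetic cohort
were killed but not swallowed; prey mass does not predict the outcome
(z ≈ 0.7, as built into the generator's null); the snakes that *did*
swallow a fledgling average larger than a random draw of
endotherm-attracted snakes (observed mean above the bootstrap interval);
and ingested prey average roughly a third of their predator's body mass.

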