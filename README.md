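# p180curate

Staged, audited curation of targeted metabolomics plate data — from raw
96-well kit exports ("Level 0") to a single curated subject × analyte
matrix ("Level 5") — plus classification of free-text medication records
into subject × drug-class Boolean flags for confounder adjustment.

It is written for analysts curating multi-plate targeted metabolomics
cohorts (acylcarnitines, amino acids, biogenic amines,
glycerophospholipids, sphingolipids, hexose; concentrations in µM with
`<LOD`/`<LLOQ` status flags) who need the preprocessing to be
deterministic, reproducible, and fully accounted for: every removed
analyte and sample is recorded with its metrics and the rule that removed
it.

## What the pipeline does

| Level | Step |
|---|---|
| 0 → 1 | remove listed pre-analytical exclusions (e.g. thawed samples) |
| 1 → 2 | cross-plate scaling: each cell × (global SPQC mean / plate SPQC mean) |
| 2 → 3 | drop analytes with duplicate CV ≥ 20 %, ICC ≤ 0.65, or > 40 % censored |
| 3 → 4 | impute below-LOD cells as plate LOD/2; flag non-fasting / missing-BMI / missing-medication samples |
| 4 → 5 | drop flagged samples, average blinded duplicates per subject, remove PCA outliers (> 7 sd from the score-space centroid over components explaining > 90 % variance), log2-transform analytes with omnibus p < 0.05 and skewness > 2 |

Key estimators: duplicate CV uses the n = 2 bias-corrected two-point sd
(s / c₄, c₄ = √(2/π)); ICC is the one-way random-effects ICC(1,1)
= (MS_B − MS_W)/(MS_B + MS_W); plate LOD = 3 × mean zero-well level;
plate technical validation enforces the ±30 %/75 % calibrator rule, the
±45 %/two-thirds/per-level-50 % kit-QC rule, blank ceilings and
internal-standard windows.

Because the real cohort data sit behind a controlled-access repository,
the package ships a seeded simulator (`simulate_cohort()`) that emulates
the full study design — 11 plates × 76 study wells, 831 study samples
with 20 blinded duplicate pairs, 182 analytes with 44 planted defects,
planted outliers, clinical flags and misspelled medication text — with a
ground-truth manifest, so the whole pipeline is testable end to end.

## Worked example

```r
library(p180curate)

fx <- make_reference_fixture()   # deterministic synthetic cohort
fx
#> synthetic_cohort: 3 plates, 120 study samples (114 subjects,
#>   6 duplicate pairs), 40 analytes (6 planted defects)

res <- suppressWarnings(run_pipeline(
  fx$level0, fx$clinical,
  pipeline_config(exclusion_lists = fx$truth$excluded_samples)))
res
#> curation_result
#> curation_audit
#>   level1: samples 120 -> 118, analytes 40 -> 40
#>   level2: samples 118 -> 118, analytes 40 -> 40
#>   level3: samples 118 -> 118, analytes 40 -> 34
#>   level4: samples 118 -> 118, analytes 34 -> 34
#>   level5: samples 118 -> 106, analytes 34 -> 34
#>   final: 106 subjects x 34 analytes; 2 log2-transformed
```

Reading the audit: 2 listed thawed samples leave at Level 1; 6 analytes
fail the CV/ICC/censoring filters at Level 3; Level 5 loses 12 study
rows — 5 flagged samples (3 non-fasting, 1 missing BMI, 1 missing
medication record), 6 duplicate rows merged into their subjects, and 1
planted score-space outlier.  Per-analyte metrics and verdicts:

```r
head(res$metrics[res$metrics$verdict != "retain", ], 3)
#>    analyte_id pct_below_lod        cv       icc  verdict
#> 2       AC.02      2.542373  3.539255 0.5538009 drop_icc
#> 5       AC.05     57.627119 18.025490        NA drop_icc
#> 10      AA.01     11.864407 22.712450 0.6826729  drop_cv
```

Medication matching, including a misspelling routed to review:

```r
match_term("aricpet", read_lexicon())[1:2, ]
#>     query candidate     score       status
#> 1 aricpet   aricept 0.7142857 needs_review
#> 2 aricpet    tricor 0.4285714     rejected
```

## Command line

A thin wrapper over the same functions is installed at
`exec/p180`:

```sh
p180 simulate --seed 5 --config sim.json --outdir cohort/
p180 validate-plates --cohort cohort/ --report verdicts.csv
p180 run --cohort cohort/ --exclude X00010 --outdir out/
p180 qc-metrics --level2 out/LEVEL2.csv --out metrics.csv
p180 meds --meds cohort/meds.csv --review cohort/review.csv --out classes.csv
```

`p180 run` writes `LEVEL1.csv` … `LEVEL5.csv`, `audit.json`,
`metrics.csv` and `scaling_factors.csv`; it exits 0 only on full success.

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic cohort at the
given seed, validates all 11 plates, runs the full Level 0 → 5 pipeline
and the medication classifier, prints the resulting sample/analyte/
subject counts, and writes the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
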