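---
title: "Staged curation of targeted metabolomics plate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged curation of targeted metabolomics plate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Targeted metabolomics kits quantify one to two hundred analytes —
acylcarnitines, amino acids, biogenic amines, glycerophospholipids,
sphingolipids and hexose — from serum on 96-well plates.  A cohort of
several hundred subjects spans many plates, and the raw per-plate exports
are not directly comparable: each plate carries its own multiplicative
batch effect, its own limit of detection (LOD), and its own technical
validation state.  Some analytes are too imprecise or too heavily
censored to report at all, and some samples should never enter analysis
(non-fasting draws, missing covariates, thawed shipments, gross
multivariate outliers).

`p180curate` implements that entire curation path as a deterministic,
audited pipeline over staged artifacts called *levels*:

* **Level 0** — raw plate exports (concentrations in µM with `<LOD` /
  `<LLOQ` sentinel flags), a well manifest, per-plate LOD tables, and a
  clinical annotation table.
* **Level 1** — listed pre-analytical exclusions removed (e.g. samples
  thawed during shipment).
* **Level 2** — cross-plate scaling anchored on the study-pool QC (SPQC).
* **Level 3** — analyte filtering by duplicate CV, intraclass correlation
  and censoring fraction.
* **Level 4** — LOD/2 imputation plus pre-analytical sample *flagging*
  (rows stay in place until Level 5).
* **Level 5** — flagged samples dropped, blinded duplicates averaged to
  one row per subject, PCA outliers removed, and heavily right-skewed
  analytes log2-transformed.

A companion pipeline turns free-text medication records into a subject ×
drug-class Boolean matrix for confounder adjustment, and a seeded
simulator generates complete synthetic cohorts with known ground truth so
that every stage is testable without access-restricted cohort data.

## Models and estimators

### Plate technical validation

Each plate is accepted only if (i) every calibration standard injection
is within ±30 % of its nominal concentration for at least 75 % of
injections per analyte, (ii) kit QC injections at three levels are within
±45 % of target for at least 2/3 of injections overall *and* at least
half of the injections of every level, (iii) blank signals stay below the
kit-defined ceiling, and (iv) internal-standard intensities fall inside
their kit-defined windows.  All windows are inclusive (a calibrator at
exactly +30 % is valid; comparisons carry a `1e-9` relative epsilon so
the closed boundary survives floating point).  The "67 %" QC rule is
implemented as the exact fraction 2/3 so that the canonical 6-of-9 case
passes.  The plate-specific LOD of an analyte is

$$\mathrm{LOD}_a = 3 \times \overline{z_a},$$

three times the mean level of the zero-sample (internal-standard-only)
wells; a zero mean gives LOD 0 and the analyte is never censored on that
plate.

### SPQC scaling (Level 2)

The SPQC is one pooled serum aliquot injected twice on every plate.  For
analyte $a$ on plate $p$ the correction factor is

$$f_{p,a} = \frac{\overline{\mathrm{SPQC}}_a^{\text{global}}}
                 {\overline{\mathrm{SPQC}}_{p,a}},$$

and every cell on plate $p$ is multiplied by $f_{p,a}$.  After scaling,
per-plate SPQC means equal the global mean by construction.  With
noiseless SPQC measurements the factors recover planted batch effects
exactly (machine precision).  With technical noise they cannot do better
than the precision of a 2-injection mean: at a technical CV of $c$, the
plate mean has relative standard deviation $c/\sqrt{2}$, so factor errors
of order 3–4 % are *intrinsic* at $c = 5\,\%$ — see "Known limitations".
Plates whose SPQC mean is zero or entirely censored for an analyte get
factor 1 and a warning; such analytes are invariably removed at Level 3
anyway.

### Analyte filters (Level 3)

Computed on the scaled matrix, restricted to study wells, using the
blinded analytical duplicates:

* **Duplicate CV.**  For each pair, $\widehat{cv} = s / (c_4 \bar{x})$
  where $s$ is the two-point standard deviation and
  $c_4 = \sqrt{2/\pi}$ is the Gaussian unbiasing constant for $n = 2$
  (without it a two-point sd underestimates $\sigma$ by ~20 %, and a true
  5 % CV would be reported as 4 %).  The analyte CV is the mean over
  usable pairs; pairs with a missing member or non-positive mean are
  skipped.  `duplicate_cv(bias_correct = FALSE)` gives the raw
  uncorrected form.
* **ICC.**  One-way random-effects ICC(1,1) from the ANOVA decomposition,
  $(MS_B - MS_W)/(MS_B + MS_W)$ for $k = 2$, allowing negative estimates.
  Duplicates are exchangeable technical replicates, so the one-way model
  (no rater structure) is the appropriate one.
* **Censoring.**  $100 \times \#\{\text{below-LOD study cells}\} /
  \#\{\text{study cells}\}$; control wells are excluded from both counts
  because missingness of controls is not a property of the cohort.

An analyte is retained iff CV $< 20\,\%$ **and** ICC $> 0.65$ (strictly:
an analyte at exactly 0.65 is excluded) **and** censoring $\le 40\,\%$.
The verdict names the first failing rule in the fixed order CV, ICC, LOD,
and an undefined metric (too few usable pairs, zero pair means) fails its
own rule — the pipeline is deliberately stringent.

### Imputation, flagging, finalization (Levels 4–5)

Remaining below-LOD study cells are set to half the LOD *of the plate the
sample ran on* (not a global LOD), and the cell status becomes `imputed`.
The unscaled LOD/2 is used so that the imputed value is exactly
reproducible from the deposited LOD table.  Samples whose subject is
non-fasting, lacks BMI, or has no baseline medication record are flagged
but physically retained until Level 5, keeping the Level-4 file aligned
with Level 3.

Level 5 applies a fixed order of operations: (1) drop flagged samples and
all control wells; (2) average each blinded duplicate pair into a single
subject row; (3) run PCA outlier detection; (4) log2-transform selected
analytes.  Averaging before outlier detection makes the sample/subject
arithmetic coherent; outlier detection before log2 keeps the distance
rule on the concentration scale.

**PCA outliers.**  Analytes are standardized to zero mean and unit
variance (µM scales differ by orders of magnitude across classes, so
unstandardized PCA would be dominated by the most abundant analytes).
$K$ is the smallest number of principal components whose cumulative
explained variance exceeds 0.90; each subject's Euclidean distance $d_i$
from the score-space centroid is computed on those $K$ components, and
subjects with $d_i > \bar{d} + 7\,\mathrm{sd}(d)$ are flagged.  The
distance rule (rather than a per-component rule) follows from computing
"distance from the centroid" first and applying the sd threshold to that
scalar.  Flags are invariant to component sign flips because distances
are.

**Conditional log2.**  An analyte is transformed iff the
D'Agostino–Pearson omnibus test rejects normality at $p < 0.05$ *and* the
Fisher–Pearson skewness $g_1$ exceeds 2.  Both conditions are required:
significance alone is nearly guaranteed at cohort sizes, so the skewness
gate restricts the transform to strongly right-skewed analytes.  The
omnibus $K^2$ statistic is implemented from the standard transformed
skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983) z-scores;
below 20 non-missing values the decision is "no transform" with a
warning.

### Medication classification

Free-text entries are lowercased, split on combination separators
(`/`, `+`, `" with "`), and stripped of doses, units, routes and
frequencies.  Each token is matched against an offline lexicon (brand or
generic name → ingredients; ingredient → classes with source
terminologies) by a pluggable scorer; the default is normalized
Levenshtein similarity $1 - d/\max(|q|, |c|)$, which is 1 for an exact
match, symmetric, and decreasing in edit distance.  Scores ≥ 0.85
auto-accept, scores in [0.5, 0.85) queue for manual review, lower scores
reject.  The thresholds are configuration, not reconstructions — the
upstream terminology service's score scale is not published — and the
defaults are conservative: a single transposition in a 7-letter name
(score 0.714) goes to review rather than silently auto-matching.  Review
decisions are a serialized input (accept-as / reject), making the whole
pipeline replayable.  Accepted entries map to ingredients and roll up to
the bundled 85-class list; a subject's class flag is the Boolean union
over entries.  The bundled lexicon is synthetic (~90 ingredients, ~80
brand aliases) and stands in for live RxNorm/NDF-RT/ATC/MeSH services,
which are deliberately out of scope behind the matcher contract.

## The synthetic cohort

`simulate_cohort()` draws, per analyte, a lognormal between-subject
distribution (mean concentration log-uniform over 0.1–100 µM, biological
CV 30 %), applies a multiplicative plate effect (log-scale sd 0.10), and
adds truncated-Gaussian technical noise (CV 5 %).  The defaults *are* the
emulated study design: 11 plates × 76 study wells carrying 831 study
samples with 20 blinded duplicate pairs (811 subjects), 182 analytes of
which 44 are planted to fail (15 with 40 % technical CV, 15 with zero
between-subject variance, 14 censored at the 60 % quantile), 2 outlier
subjects displaced 30 standardized units in score space, 69 non-fasting +
2 missing-BMI + 1 missing-medication-record subjects (disjoint), and 4
thaw-excluded samples.  Plate LODs sit at the configured censoring
quantile of each analyte's marginal distribution, scaled by the plate
effect, and zero wells are written at exactly LOD/3 so the 3× rule
recovers the LOD bit-exactly.  Medication text is drawn from the bundled
lexicon with a 10 % misspelling rate (adjacent transposition); the
generator emits the matching review file, so the classified output can be
compared to the known truth matrix.

Design notes:

* The planted low-ICC defect uses zero between-subject variance (true
  ICC ≈ 0) rather than a small positive ICC: with 20 duplicate pairs the
  ICC estimate at true 0.2 crosses the 0.65 threshold too often for a
  planted defect to be reliably recalled, whereas at true 0 the
  probability is ~0.06 % per analyte.
* Planted outliers spread their displacement over all analytes
  ($\mathrm{magnitude}/\sqrt{A}$ sd per analyte).  A single-analyte spike
  of $m$ sd is shrunk to $m/\sqrt{1 + m^2/n}$ by per-analyte
  standardization and becomes undetectable at realistic cohort sizes; a
  global shift emulates the sample-handling failures the rule is meant to
  catch and keeps the total score-space displacement at the configured
  magnitude.
* What the generator does **not** emulate: chromatographic drift within a
  plate, carryover, isobaric interference, correlated analyte panels, or
  non-lognormal biology.  A green pipeline test therefore establishes
  correct *arithmetic and bookkeeping* under the stated noise model, not
  robustness to real-instrument pathologies.

## Numerical and degenerate-input choices

* Tolerance boundaries are closed (±30 %, ±45 %, ≤ 40 %) with a `1e-9`
  relative epsilon; retention inequalities for CV and ICC are strict.
* Level files are CSV with `%.17g` number formatting and a canonical
  column order, so write→read round trips are bit-exact and two runs of
  the pipeline produce byte-identical files (the basis of the determinism
  tests).  Flagged-missing cells are written as `<LOD` / `<LLOQ`; numeric
  cells carrying a non-valid flag are written as `value|status`.
* `<LLOQ` cells with a recorded number are treated as numeric-valid with
  the flag preserved; `<LLOQ` cells without a number remain missing and
  block Level 5 (the pipeline refuses to finalize an incomplete matrix
  rather than silently imputing them).
* Zero-variance analytes are dropped from the outlier PCA with a warning;
  an all-constant matrix yields no outliers.  A degenerate distance
  spread (sd 0) flags nobody.
* Scaling factors for zero/all-missing SPQC means default to 1 with one
  aggregated warning.
* The audit serializes to canonical (name-sorted) JSON, and the pipeline
  configuration is hashed (md5 of canonical JSON) into every level-file
  header, so an artifact can be traced to the exact configuration that
  produced it.

## Known limitations

* **Two SPQC injections bound the achievable scaling precision.**  The
  factor estimate divides by a 2-injection mean whose relative sd is
  $c/\sqrt{2} \approx 3.5\,\%$ at technical CV 5 %, so roughly half of
  the per-plate factors deviate from truth by more than 2 %.  Equalizing
  *observed* SPQC means is exact; recovering *true* plate effects to 2 %
  would need either more SPQC replicates or lower injection noise.  The
  acceptance suite asserts the 2 %-at-95 % recovery bound literally and
  that assertion fails for this structural reason.
* **Six duplicate pairs cannot guarantee perfect analyte filtering.**
  The ICC(1) estimate from $n$ pairs at true ICC 0 is distribution-free
  with $(F_{n-1,n}-1)/(F_{n-1,n}+1)$ shape; at $n = 6$ it exceeds 0.65
  with probability 4.3 %, and a clean analyte's estimate falls below 0.65
  with probability ~0.4 %.  Across a 40-analyte panel only about half of
  random realizations give 100 % precision and recall, and the fixed
  reference fixture realizes such an event (one planted zero-ICC analyte
  with sample ICC 0.90, one clean analyte at 0.52).  The corresponding
  acceptance assertion is left failing rather than re-rolling the fixture
  seed; at 20 pairs the same check passes for 20 of 20 cohort seeds.
  This mirrors a real weakness of ICC filtering on few duplicates: it can
  discard robust analytes whose biological range happens to be narrow.
* The CV estimator's $c_4$ correction assumes Gaussian technical noise;
  under heavy-tailed noise it remains consistent for the sd but is no
  longer exactly unbiased.
* The medication matcher is intentionally simple (edit distance); it will
  not resolve abbreviations ("ASA") or phonetic misspellings unless the
  lexicon lists them as aliases, and such tokens fall to manual review or
  rejection rather than guessing.
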