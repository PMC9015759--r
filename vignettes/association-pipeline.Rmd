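---
title: "From clinical extracts to open association tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical extracts to open association tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opencohort)
```

## The problem

Electronic health record (EHR) data become far more useful for
environmental-health research when each patient record is linked, through
the patient's geocode and encounter dates, to spatiotemporal exposure
estimates: airborne pollutant surfaces, proximity to major roadways (a
proxy for traffic-related pollution), and census socioeconomic
attributes. The same geocodes and dates that make this linkage possible
make the result sensitive: under HIPAA, exposure estimates derived from
them are effectively secondary protected health information. The
compromise this package implements is the one adopted by open
clinical-exposure services: integrate at the patient level inside a
restricted environment, then *bin every value* and strip every
identifier before exposure, so that the open artifact is a feature table
of labels only, on which contingency-table statistics can run freely.

`opencohort` is a desk-scale re-implementation of that pipeline:

1. **`generate_bundle()`** — a seeded synthetic EHR extract (so the whole
   chain is testable without any real patient data);
2. **`select_cohort()`** — four configurable inclusion rules combining
   diagnoses, medications and procedures for an asthma-and-related-conditions
   cohort;
3. **`integrate_exposures()`** — annual PM2.5 and ozone summaries, roadway
   distance, and census block-group attributes per patient;
4. **`deidentify()`** — binning to Safe-Harbor-compliant labels;
5. **`associations_to_all_features()`** — the Pearson chi-square battery
   of one outcome against every feature, with Bonferroni correction and
   contiguous-bin collapsing;
6. a CLI (`cli_main()`) and a small HTTP facade (`serve_api()`) exposing
   the battery as a cohort-query service.

## The statistical model

Every exposed analysis reduces to a 2 x k contingency table: rows are an
outcome dichotomy defined by a constraint such as
`TotalEDInpatientVisits = 0` versus its complement, columns are the bins
of one feature in ordinal order. Rows with a missing outcome or missing
feature value are excluded from that table (and counted); nothing is
imputed. The test is the Pearson chi-square

$$X^2 = \sum_{ij} \frac{(O_{ij} - E_{ij})^2}{E_{ij}},
\qquad E_{ij} = \frac{O_{i\cdot} O_{\cdot j}}{N},$$

with **no continuity correction**, also for 2 x 2 tables — this is
required to reproduce the published reference statistics from their
printed counts, and is verified against an independent direct-formula
oracle in the test suite. All-zero rows and columns are pruned before
testing; degrees of freedom are $(r-1)(c-1)$ on the pruned table. The
battery tests one outcome against every eligible feature and applies a
Bonferroni threshold $\alpha/m$ where $m$ counts only the features that
produced a valid test: features that are constant, entirely missing, or
leave an outcome group empty are skipped with a recorded reason rather
than silently inflating the correction. This is the conservative-power
reading of a correction whose exact denominator the source interface
does not pin down, and $m$ is reported in every battery so users can
audit it. With $\alpha = .05$ and a 50-feature table the adjusted
threshold is $.001$.

Two deliberate interface extensions: degrees of freedom are returned
(the reference service omits them), and tied p-values sort by feature
name so output is deterministic.

## Binning and de-identification

Each feature carries a `binning_scheme` with one of four strategies.
The shipped defaults use *explicit edges* for every exposure feature,
reproducing the published boundaries exactly:

| feature | edges | closure |
|---|---|---|
| median household income (US$) | 7,470 / 36,635 / 46,750 / 59,566 / 78,355 / 250,001 | `[a,b]`, then `(a,b]` |
| P(no insurance) | 0 / 0.0637 / 0.1121 / 0.1644 / 0.5548 | same |
| annual mean PM2.5 (ug/m3) | 3.27 / 6.30 / 7.81 / 10.83 | same |
| annual mean daily-max ozone (ppb) | 27.80 / 39.00 / 42.73 / 46.45 | same |
| roadway distance (m) | 0 / 50 / 100 / 150 / 200 / 250 / Inf | `[a, a+50)` |

The income and insurance edges are frequency quantiles and the pollutant
edges distribution-based cuts *in their original derivation*, but the
printed edges are not reproducible from any dataset we ship, so they are
frozen as explicit edges; `fit_frequency_quantiles()` (type-7 linear
interpolation quantiles, the common default of frequency-binning tools)
and `fit_value_cut()` (equal width) remain available as generic
strategies for new features. Closure follows the printed interval
notation: first interval closed on both ends, subsequent intervals
left-open/right-closed; the integer roadway bins are half-open.

Age is computed in completed years on January 1 of the study year and
binned `<5, 5-17, 18-44, 45-64, 65-89`. Ages above 89 — the oldest
permissible age under Safe Harbor — are **excluded by default** with a
logged count; `cap_age_to_top = TRUE` instead folds them into `65-89`.
The exclusion default was chosen because the source material states the
cap but not the handling of older patients, and dropping is the
conservative privacy choice.

`deidentify()` emits a `feature_table` containing only bin labels,
categories, small counts, the study year and an opaque row key. A
schema-level scan (`assert_no_identifiers()`) runs on every table it
produces, and the test suite applies the same scan to written CSVs and
to raw API response bodies. Small-cell suppression in exposed tables is
available as a concept but off by default, since the reference interface
does not document a threshold.

## Exposure integration

Geometry is planar Euclidean, in meters, over a synthetic
100 km x 100 km region — the integration exercises every join
(point-in-cell, point-to-segment, point-in-extent) without pulling in
geodesy; a haversine variant would slot behind the same interface if
geodetic coordinates were ever supplied. Specific conventions:

* study periods are calendar years; days absent from a surface are
  skipped, not imputed (the simplest defensible annual mean; summaries
  are always bounded by the contributing daily values);
* cell lookup is point-in-rectangle; a point on a shared edge resolves
  to the lowest `cell_id`, so results are deterministic;
* roadway distance is the minimum point-to-segment distance over all
  segments, `NA` (never an error) when the geocode is missing or no
  segments exist;
* the census join prefers the recorded `blockgroup_id` and falls back
  to point-in-extent, mirroring geocode-to-census linkage without a
  geocoder;
* residential density classes follow the census block-group population
  cutoffs: `< 2500` rural, `2500–50,000` urban cluster, `> 50,000`
  urbanized;
* nothing geocode-derived is ever non-missing for a patient with a
  missing geocode.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions of the reference
cohort: N = 157,410, study year 2016, outcome prevalences 16.73%
(ED/inpatient respiratory visits) and 10.84% (prednisone), the published
marginal distributions of age, sex, race, ethnicity, exposures, and
per-feature missingness, and planted per-bin log-odds offsets derived
from the published per-bin event rates (so income, insurance, PM2.5,
ozone and roadway proximity carry monotone effects, age a U-shaped one
on ED visits and a monotone one on prednisone).

Patients are assigned *binned* feature values first; outcomes are drawn
from a logistic model on those bins, with the intercept calibrated by
`uniroot` so the expected prevalence equals the configured one under the
planted offsets (with zero offsets this reduces exactly to
`qlogis(p)`, so prevalence recovery is pure binomial sampling). Raw
data are then constructed to be *bin-faithful*: PM2.5 varies along x
(three bin strips of ten subcells whose daily sinusoid-plus-noise series
are shifted to an exact annual mean inside the bin), ozone along y,
roadway distance is encoded in `x mod 1000` against vertical highways
every kilometer, and census attributes live on a 90-tile block-group
grid covering every density-by-insurance-by-income combination
(including missing-attribute tiles). Planted effects are therefore
exactly recoverable by the chi-square battery, which is the property the
end-to-end recovery test checks.

Missingness is missing-completely-at-random. A missing geocode (10.42%
of patients, the published pollutant missing rate) silences every
geo-derived feature; the higher published missing fractions for density,
insurance and income are reached by additional block-group-level
attribute missingness. The published roadway-distance missingness
(~30%) arises from linkage failures specific to the roadway source
database; the extract schema has no field that could carry such a
failure, and roadway distance is defined to be missing only when the
geocode is missing or no segments exist, so synthetic roadway
missingness equals the geocode rate. Other things real data have that
the generator deliberately does not: real terminology codes (a small
synthetic vocabulary stands in, and the cohort code sets are
configuration), informative missingness, spatial autocorrelation of
demographics, within-year residential moves, and the denominators'
quirks of the published subgroup analyses. Passing tests therefore
demonstrate the pipeline's correctness and sensitivity under clean MCAR
conditions, not robustness to real-world linkage error.

The four cohort rules are exercised with a 70/15/10/5 rule mix plus 5%
non-qualifying patients; "frequent ED visits" defaults to 2 per study
year (a configurable operationalization — the source text does not
define "frequent"), and laboratory-measure criteria fold into the
rule-3 test/procedure code set.

## Numerical choices and degenerate inputs

* Percentages print half-up at 2 decimals (matching cohort-table
  presentation); `round_half_up()` is exported because base R rounds
  half to even.
* Quantile edges use type-7 linear interpolation; duplicate edges merge
  with a warning and reduce the bin count; fewer than `k` distinct
  values is a `degenerate_input_error`.
* Values outside an explicit scheme's span go missing with a warning —
  out-of-range is a data problem, not a crash.
* `collapse_bins()` validates that groups form an ordered partition
  into contiguous runs; conservation of row marginals is tested.
* Cohort ids are `COHORT:` plus a 32-bit FNV-1a hash of the canonical
  constraint set — opaque, stable, and database-free.
* Empty inputs flow through: an empty population yields an empty bundle
  and header-only CSVs; an empty cohort is valid and flagged.

## Problem sizes

The test suite runs the full recovery chain at 150,000 patients (about
half a minute) and everything else at hundreds to tens of thousands of
rows; `scripts/acceptance.R` recomputes the reference statistics from
the bundled counts and one 150,000-patient end-to-end run. These sizes
were chosen so the planted-effect recovery operates at the reference
cohort's scale while the whole suite stays comfortably interactive.

## Known limitations

Only bivariate chi-square statistics are exposed (no multivariate
models, no exact tests); the HTTP facade is a single-threaded local
loop, not a deployment server; geometry is planar; and the reference
age-by-ED-visit statistic printed in the source material is not
reproducible from its own printed counts (the bundled counts are
internally consistent and yield 1184.0; the discrepancy is documented
rather than papered over).
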