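---
title: "Disproportionality signal detection: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting databases collect individual case safety
reports (ICSRs): one report names one patient, one or more drugs (each with a
role — suspected, interacting or concomitant), and one or more reactions coded
as MedDRA preferred terms (PTs). There is no denominator of exposed,
unaffected patients, so incidence cannot be estimated. Signal detection
instead asks whether a drug–event pair is reported *disproportionately*: more
often, relative to the drug's overall reporting, than that event is reported
for all other drugs in the same database. A flagged pair is a hypothesis for
pharmacological follow-up, never a causal claim.

## The 2×2 table and its counting unit

For a drug–event pair the database collapses to

|                | event of interest | all other events |
|----------------|-------------------|------------------|
| drug of interest | A               | B                |
| all other drugs  | C               | D                |

`pvsignal` counts **reports**, not drug–reaction mentions: a report listing
the drug twice (two roles) and the PT twice still contributes exactly 1 to
`A`, and `A + B + C + D = N`, the database total, for every pair. This makes
the per-drug totals in a demographic table the same object as the `A + B`
marginal of every one of that drug's tables, which is what makes marginal
reconstruction (below) possible. The alternative — counting mentions — would
give each table its own effective `N`.

By default all three drug roles enter the analysis; `role = "suspected"`
restricts to suspected drugs only. Reporting databases document all roles,
and restricting is a sensitivity analysis rather than the primary run.

## The three statistics

With `p1 = A/(A+B)` and `p0 = C/(C+D)`:

* **PRR** `= p1/p0`, with the log-scale Wald interval
  `exp(log PRR ± 1.96·s)`, `s² = 1/A − 1/(A+B) + 1/C − 1/(C+D)`.
* **ROR** `= (A/B)/(C/D) = AD/BC`, interval via
  `s² = 1/A + 1/B + 1/C + 1/D`. A zero among `B`, `C`, `D` triggers the
  Haldane–Anscombe correction (0.5 added to every cell), flagged in the
  output rather than applied silently.
* **IC** `= log2((A + 0.5)/(E + 0.5))` with the expected count
  `E = (A+B)(A+C)/N`. This is the observed-to-expected log-ratio of the
  Bayesian confidence propagation neural network (BCPNN) family, with a +0.5
  shrinkage in numerator and denominator that pulls small-count estimates
  toward zero. The plain `log2(A/E)` diverges badly at small `A`: for a
  three-report pair with `E ≈ 0.14` the plain form gives ≈ 4.45 where the
  shrinkage form gives 2.46. Published IC values at small counts are only
  consistent with the shrinkage form, which is why it is the package's
  definition rather than an option.

The IC's 95% credibility interval defaults to the closed-form approximation

```
low  = IC − 3.3·(A+0.5)^−1/2 − 2·(A+0.5)^−3/2
high = IC + 2.4·(A+0.5)^−1/2 − 0.5·(A+0.5)^−3/2
```

with a seeded Monte-Carlo alternative (`method = "mc"`): 2.5%/97.5% quantiles
of `log2 G`, `G ~ Gamma(A + 0.5, rate = E + 0.5)`, whose posterior mean is
exactly the IC point's argument. The two agree within a few hundredths of a
log2 unit once `A ≥ 50` (a property the test suite checks). Published
interval bounds in this literature do not always identify their method and
can sit between the two; the package therefore treats IC *points* as
reproducible to printed precision but interval bounds as method-dependent.

## The signal rule

A pair is a signal when **all** criteria hold simultaneously:

```
n ≥ 3   and   PRR ≥ 2   and   ROR ≥ 2   and   IC interval lower bound ≥ 0
```

PRR and ROR thresholds apply to the point estimates; only the IC uses its
interval, following the convention of the criteria this rule mirrors. All
four thresholds are overridable through `signal_thresholds()`. A pair with an
undefined component (e.g. `C = 0`, so PRR has no comparator) is never a
signal and carries a reason code instead of being dropped.

## Marginal reconstruction

Published signal tables print `A`, the drug total `A + B`, the database total
`N` and the PRR — but not `C`. Inverting the PRR formula,

```
C = (A / (A+B)) / PRR × (N − (A+B))
```

determines the full table, so ROR, its interval and the IC can be recomputed
and compared with the printed values at desk scale. `reconstruct_marginal()`
keeps `C` continuous by default: the inversion starts from a 2-decimal PRR
and is already approximate, and rounding `C` first would compound that error.
A `round_c = TRUE` variant exists for integer tables. Recomputing the PRR on
a reconstructed table returns the printed value to machine precision, which
the tests use as the round-trip check.

## Stratified analysis

`stratified_dispro()` recomputes the pair's 2×2 table **within** each age
band (`<18`, `18–44`, `45–64`, `65–74`, `≥75`) or sex: both the drug marginal
and the comparator are restricted to the stratum, so expected counts are
stratum-specific. This is the fully stratified design — a stratified
numerator over a global denominator would not reproduce stratum-specific
PRR/ROR/IC values. Reports with an unknown stratum value are excluded from
stratum rows but retained in the `"all"` row; consequently the stratum `A`s
sum to at most the overall `A`, with the gap equal to the unknown-stratum
pair count. `stratum_consistency_check()` verifies exactly this. Sparse
strata are reported rather than suppressed (no minimum beyond the global
`n ≥ 3` signal rule), and an empty stratum yields an explicit zero row
flagged `empty_stratum`.

## The hierarchy

The mock dictionary maps PT → HLT → HLGT → SOC with one `primary_flag = yes`
row per PT. MedDRA is multi-axial — a PT may sit under several SOCs — but
counts per PT must not be double-counted, so classification
(`is_neurological()`: primary SOC equals "Nervous system disorders") and
rollups always follow the primary path. An LLT column would be accepted but
unused: the analysis operates at PT level. The bundled
`inst/extdata/meddra_mock.tsv` is synthetic content in the real format,
covering the neurological PTs of the worked examples plus decoys; it is not
licensed MedDRA.

## The synthetic generator

`generate_reports()` emulates the *structure* of a large spontaneous
reporting database: per report, demographics are drawn from categorical
mixtures (with "unknown" as a first-class value, since real databases have
large unknown fractions); each drug is present independently with its
marginal probability; each PT is present independently with probability
`min(1, background × ∏ρ)` over the planted associations whose drug is on the
report. Age is drawn as an integer uniformly within its band (75–90 for the
open-ended band) and binned downstream, so stratification is exercised on
raw ages, not labels. Reports that draw zero drugs or zero reactions are
re-drawn: every real ICSR names at least one of each.

That re-draw conditions the dataset on non-emptiness, which inflates every
marginal by roughly `1/(1 − P(empty))`. Configurations used in tests
therefore include enough background drugs and events that `P(empty)` is
negligible where exact marginal recovery is asserted; rate *ratios* are
essentially unaffected because the inflation applies to both arms. The
generator deliberately does not model reporting dynamics over time,
duplicate reports, or drug–drug interactions — so passing tests say nothing
about duplicate-sensitivity or temporal trends on real data.

Default demographics follow the reporting profile of a widely reported oral
immunomodulator: predominantly female (77.5%), middle-aged, reported from
the Americas (92%), spontaneous (96%), consumer-notified (51%), with 18.6%
unknown age. These defaults are fixed study conditions, not tuning knobs.

## Problem sizes and numerical choices

* End-to-end calibration runs use 100,000 reports over 50 drugs × 100 PTs
  (null) and 41 pairs (planted); brute-force oracle comparisons use ≤ 500
  reports, where the double loop is exact and fast.
* Under the null (all ρ = 1) the joint rule flags well under 5% of evaluated
  pairs; the conjunction of four criteria is conservative by construction.
* Ties in treemap ordering break alphabetically after descending signal
  count, making exports deterministic.
* Exported tables round half-up to 2 decimals (1 decimal for percentages),
  matching publication style; machine-precision columns are written
  alongside, and all internal computation is full precision.
* `set.seed`-style state is never leaked: seeded routines (generator,
  Monte-Carlo IC) save and restore the caller's RNG state.

## Limitations

Disproportionality cannot adjust for confounding by indication, channeling,
or reporting waves, and the package does not attempt duplicate detection
across report identifiers. The IC interval approximation is asymmetric and
calibrated for the Gamma posterior above; other published BCPNN variants
(e.g. full MCMC over both margins) will differ in the second decimal. The
treemap figure is a best-effort slice-and-dice layout; the node export is
the tested artifact.
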