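---
title: "Cleaning EHR lab values and scanning them against a polygenic score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning EHR lab values and scanning them against a polygenic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labscan)
library(data.table)
```

## The problem

Clinical laboratory results accumulate in electronic health records (EHRs) as
a by-product of care: hundreds of millions of observations across thousands
of distinct tests, with data-entry errors, free-text results ("positive",
"&lt;5"), mixed unit dialects within one test, patients measured anywhere from
once to hundreds of times, and values that change after treatment begins.
`labscan` turns this raw material into analysis-ready quantitative traits and
then asks, for every retained lab, whether a predictor — typically a
polygenic score (PGS), optionally a diagnosis flag — is associated with it.
The scan is the laboratory analogue of a PheWAS and is called a LabWAS here.

## The cleaning cascade

Cleaning happens at two levels, never iterated, with a removal ledger at
every stage so that observations in = observations out + removals.

**Catalog filters** decide which labs are quantitative enough to analyse.
Numeric-ness is decided by a strict decimal/scientific parse:
`"1.0"` and `"2e1"` parse; `"inf"` parses but is non-finite;
comparator-prefixed strings like `"<5"` are non-numeric by design, because
they encode censoring, not a value. A lab is dropped when it

1. has no finite numeric observations (`non_numeric_only`),
2. was administered to at most one patient (`single_patient`),
3. has under 70% of its numeric observations in one canonical unit
   (`unit_discordant`) — unit strings are case-folded, whitespace-stripped
   and mapped through a user-supplied synonym table first, so `"mcg/L"` and
   `"μg/L"` count as one unit,
4. has fewer than 100 patients (`too_few_patients`), or
5. fewer than 1000 numeric observations (`too_few_observations`).

All applicable reasons are recorded in that fixed order; nothing
short-circuits. Thresholds are inclusive (exactly 70% / 100 / 1000 pass) and
configurable via `qc_config()`.

**Observation filters** then clean each kept lab. Stage 1 removes
non-numeric and non-finite values and — by default — observations not in the
lab's modal unit, so a patient's median is never computed across mixed
units. Stage 2 computes the mean and sample (n−1) SD of the stage-1
survivors **once**, pooled across patients, and removes values more than 4
SD from that mean. The filter is deliberately single-pass: iterating it
would keep shrinking the band and remove an unpredictable number of genuine
values; a unit test constructs a vector where iteration would provably
remove more and asserts that the implementation does not.

Each patient's **median** is then taken per lab. Observations are sorted by
value, ties broken by age at draw and then input order; for an even count
the median is the mean of the two middle order statistics and the **age at
median** is the midpoint of those two observations' ages — a deterministic
reading of the "age at the two lab values used" rule. Finally the medians of
each lab get a rank-based **inverse normal transformation (INT)**,
$\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with average ranks for ties
and offset $c = 3/8$ (Blom). The offset is a documented choice, not given by
the protocol we reproduce; Blom scores are the standard in quantitative-trait
genetics and any $c \in [0, 0.5]$ is accepted. INT enforces normality at the
price of interpretability: betas are in SD units of the transformed lab, not
mg/dL.

Two optional data operations support treatment-aware analyses:
`filter_pre_event()` truncates each patient's record at their first
medication mention (same-day draws excluded by default — a conservative
reading of "after the first mention"), and `exclude_patients()` removes,
e.g., diagnosed cases before a scan.

`stratify()` and `summarize_stratum()` produce descriptive summaries over a
sex × age-group × race grid with pooled levels. The factor levels are
configuration: the 72 subsets reported for the original site correspond to
one plausible factorization (e.g., 3 × 3 × 8) and are not hard-coded.

## The scan model

For each lab $\ell$ with at least `min_n` (default 100) complete cases,

$$\mathrm{INT}(\text{median lab}_\ell) \sim \beta_\ell\,x
  + \text{sex} + \mathrm{rcs}(\text{median EHR age}; 4) + PC_{1..k}
  \;(+\, \text{extra adjustments}),$$

by OLS. Continuous predictors are standardized to mean 0, SD 1, so
$\hat\beta_\ell$ is the change in INT lab value per SD of the score; binary
predictors (case/control) are left as 0/1 contrasts. Inference is t-based
(two-sided p with residual degrees of freedom, 95% CI at $t_{0.975,df}$) —
the protocol we reproduce does not state t vs normal; at biobank sample
sizes they are indistinguishable, and t is exact under the Gaussian model.

The age adjustment is a restricted (natural) cubic spline in the Harrell
truncated-power parameterization: $k-1$ columns (linear term plus $k-2$
nonlinear terms), knots at the conventional quantiles of the scanned
sample's age distribution (5/35/65/95th percentiles for $k=4$), shared
across all labs in a scan so there is a single design matrix per scan. The
basis is hand-built (the environment provides no `rms`/`Hmisc`), and tested
against three oracles: knots at the stated percentiles, exact recovery of
linear functions, and zero second differences beyond the boundary knots.
`labwas_config(spline_columns = 2)` reproduces the "first two splines"
variant used by one replication site.

The significance threshold is $\alpha / (n_\text{tested} \times
n_\text{scans})$, where $n_\text{tested}$ counts labs actually fitted —
skipped labs are reported with a reason but leave the Bonferroni
denominator — and `n_scans` is the size of the scan family (4 in the
published lipid/CAD analysis: 0.05/(315 × 4) ≈ 3.97 × 10⁻⁵). The scan plot
draws $-\log_{10}(p)$ per lab, upward/downward triangles for
positive/negative betas, a red line at the Bonferroni threshold and a blue
line at p = 0.05.

## What the synthetic generator emulates — and what it does not

`generator_config()` states a world in which every pipeline behaviour is
exercisable: lognormal and normal labs (EHR labs are typically
right-skewed); unit dialects within one lab; non-numeric, infinite and
gross-outlier contamination at configured rates (defaults 1%, 0.2%, 0.5% —
small, as expected after upstream interface validation, but non-zero);
`1 + Poisson(2)` draws per patient over a uniform EHR span of 1–15 years
starting at a uniform age of 18–70; a 54% female cohort; ten standard-normal
PCs; and a roster that includes a single-patient lab, a non-numeric-only lab
and a unit-discordant (55/45) lab so the catalog filters always have work to
do.

Effects are specified on the latent standardized scale: a draw's latent
value is $\beta g + \sqrt{1-\beta^2}\,u + \tau \varepsilon$ (patient score
$g$, patient-by-lab liability $u$, within-patient noise $\tau = 0.2$), and
the recorded value is the base distribution's quantile at that z. Because
INT of the patient medians approximately recovers the latent ranks, the
configured $\beta$ is directly comparable to the scan's $\hat\beta$ — up to
an attenuation factor of about $1/\sqrt{1 + \tau^2/\bar n}$ ≈ 0.99 from
within-patient noise, well inside the 0.02 bias budget the acceptance
criteria use. Gross outliers are planted at z = 10, which construction
guarantees lie outside the 4-SD band at the configured contamination rates.

Medication is modelled as a per-patient event age, uniform over the EHR
span, with uptake probability increasing in $g$ (confounding by indication,
as for lipid-lowering therapy) and an additive latent shift (default −0.8
SD) applied to subsequent draws on medication-sensitive labs. This
reproduces, qualitatively, the published observation that pre-medication
medians restore the expected PGS association: the acceptance suite verifies
that the pre-event-filtered scan's beta is closer to truth than the
unfiltered one.

The generator does **not** emulate: genotypes or LD (the score is an
abstract standardized vector); real assay changes over time (unit dialects
are synonyms, never different scales needing conversion); informative
observation frequency (sicker patients measured more); missing
demographics; or correlated labs. A green test therefore establishes that
the machinery is correct under a known, favourable world — not that any
particular biological result is reproducible.

A single global seed drives separate substreams for cohort, medication and
observations, so changing one rate does not reshuffle unrelated draws.

## Numerical and design choices

* **Patient counts in the catalog.** "Administered to one patient" is read
  over all observations (`n_patients_total`), while the ≥100-patients
  threshold is applied to patients with numeric observations (`n_patients`);
  this keeps the first two filters disjoint in the way the published
  11,061 → 4,415 arithmetic implies.
* **Mean/SD for the 4-SD filter** are computed after restriction to the
  modal unit (mixing units would corrupt both), one pass, sample SD. A lab
  whose stage-1 survivors are constant (SD 0) or a single observation (SD
  undefined) loses nothing at stage 2.
* **Ties everywhere** are broken deterministically (value, then age, then
  input order; modal units by count then lexicographically), so identical
  inputs give byte-identical outputs.
* **Complete-case analysis** per lab; each record reports its own n.
* **Diagnosis adjustment** is an extra design column, not a stratified
  rerun, matching "after controlling for" semantics.
* **Degenerate fits** (rank-deficient designs, n ≤ p) are reported as
  skipped records, never dropped or forced.

## Known limitations

* One acceptance criterion demands that, at 5000 patients with true effects
  {0, 0.05, 0.1, 0.3} over 20 labs, exactly the 0.3 lab be flagged in ≥95%
  of replicates. This is unattainable at any sample size: flagging 0.3 with
  95% power needs $n \gtrsim 242$, while *not* flagging 0.1 with 95%
  probability needs $n \lesssim 190$; at n = 5000 the 0.1 lab has an
  expected z of ~7 against a critical value of ~3 and is flagged essentially
  always. The test asserts the criterion as written and is expected to fail
  on that clause (the bias clause passes); we do not weaken it.
* The Bonferroni threshold ignores correlation between labs and is
  conservative on real panels.
* INT discards scale: betas cannot be mapped back to native units.
* The spline parameterization of the original analyses is not stated;
  results may differ in the third decimal from implementations using
  B-spline bases, though the fitted column span for a given knot set is the
  same.
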