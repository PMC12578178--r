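---
title: "Methods: DIMD signal detection in FAERS and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIMD signal detection in FAERS and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(faersignal)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made where
the published workflow leaves room, and what the synthetic benchmark does
and does not establish about real FAERS data.

## Data model and deduplication

FAERS quarterly extracts are "$"-delimited ASCII tables: DEMO (one row per
report version, with demographics and the `fda_dt` receipt date), DRUG (one
row per reported drug with a role code — prime suspect PS, secondary suspect
SS, concomitant C, interaction I), REAC (MedDRA preferred terms, PTs), plus
OUTC, THER, INDI and RPSR. `read_faers_quarter()` parses these with three
guarantees: rows carrying extra delimiters are counted as malformed and
dropped (never silently), a missing mandatory column is an immediate format
error naming file and column, and child-table rows whose `primaryid` has no
DEMO row are counted as orphans and dropped. Legacy AERS extracts (pre-2012)
that key reports by `ISR`/`CASE` are handled through a column-alias table
(`faers_aliases()`).

The same physical case is frequently re-submitted, so `dedup_reports()`
applies a two-stage rule: per `caseid`, keep the version with the most
recent `fda_dt`, breaking ties by the larger `primaryid` ("larger master
ID" is read as the larger `primaryid`, since that is the report-version
key — FAERS has no field literally called master ID); then, because repeated
`primaryid`s can survive the first pass, a secondary pass keeps one row per
`primaryid` by the mirrored rule (max `fda_dt`, then max `caseid`). The
secondary tie-break is not pinned down by the published description; we
mirror the primary rule for symmetry. The operation is idempotent, which
the test suite asserts on random report sets.

## Case definition and cohort

A report is a DIMD case iff at least one of its reaction PTs, after
normalization (uppercase; whitespace, apostrophes and hyphens stripped),
falls in the 28-term DIMD list (`dimd_pts()`). Matching is literal at PT
level; no MedDRA hierarchy traversal is attempted. Drug exposure means the
drug appears with role PS on the report (configurable via `role_filter`).

Reports with recorded age ≥ 120 years or weight ≥ 400 kg are treated as
data-entry outliers. Whether that exclusion applies only to descriptive
tables or to every analysis is not specified in the source workflow; we
expose it as `exclude_outliers` and default to excluding them from *all*
analyses, on the view that values that are implausible for a summary table
are equally implausible for a 2×2 count.

Age arrives under unit codes (YR, MON, WK, DY, HR, DEC); `normalize_age()`
converts to years and maps unknown codes or negative values to missing
rather than assuming years — assuming years for a corrupted unit would bias
the age distribution silently. Quartiles use the type-7 (linear
interpolation) convention, R's default, since no convention is stated for
the published descriptives. The age-band tally defaults to the quartile
cuts {33, 53, 67}.

Seven comorbidity flags (Parkinson's disease, schizophrenia, affective
disorders, epilepsy, gastro-oesophageal reflux, nausea/vomiting, other CNS
disorders) are derived from indication PTs via an editable map
(`default_comorbidity_map()`). The published workflow names the flags but
not their PT lists; the shipped lists — especially `other_cns` — are small
illustrative defaults meant to be replaced by the user's own MedDRA
curation.

## Disproportionality algorithms

All four algorithms score the same per-drug 2×2 table (a, b, c, d; N the
total, E = (a+b)(a+c)/N the expected count under independence).

**ROR** = ad/bc with the Wald interval exp(log ROR ± z·√(1/a+1/b+1/c+1/d)).
**PRR** = [a/(a+b)]/[c/(c+d)] paired with the Pearson χ², computed without
Yates continuity correction by default (a flag enables it) because the
paired threshold χ² ≥ 4 is conventionally stated for the uncorrected
statistic. Tables containing a zero cell receive the Haldane–Anscombe +0.5
correction on all cells, applied only when a zero occurs, and the result is
flagged `corrected` so downstream consumers can tell.

**BCPNN.** The information component IC = log₂(p₁₁/(p₁.p.₁)) carries
independent Beta posteriors for the joint and marginal reporting
probabilities (the classical priors: α₁ = β₁ = 1 for the margins updated
against α = β = 2, γ₁₁ = 1 for the joint cell, with γ calibrated as
γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)) so the prior IC expectation is zero).
Rather than the historical first-order approximations, we compute the
*exact* moments of log of a Beta variate — E log X = ψ(u) − ψ(u+v),
Var log X = ψ′(u) − ψ′(u+v) — so the reported IC and its variance agree
with numeric integration of the posterior to better than 10⁻⁶. The signal
bound is IC025 = IC − 1.96·√Var(IC); everything is defined at a = 0, so no
continuity handling is needed.

**EBGM.** The rate ratio λ = a/E is shrunk under a two-component gamma
mixture prior fitted by maximizing the negative-binomial mixture marginal
likelihood across all drug tables. The optimizer is bounded L-BFGS-B from
the fixed start (1, 1, 1, 1, 0.5) with box constraints [10⁻⁶, 10⁶] on
shapes/rates (and [10⁻⁶, 1−10⁻⁶] on the weight): the start and bounds are
fixed and documented so the fit is deterministic given the data;
non-convergence is an error carrying the optimizer's evaluation counts, not
a silent fallback. `ebgm_fit()` can also fix the mixture weight (e.g.
`mix_p = 1`) when a single-gamma prior is wanted. The posterior for a drug
is the conjugate mixture of Gamma(αⱼ+a, βⱼ+E); EBGM = exp(E[log λ | a])
(equivalently 2^E[log₂ λ]) via digamma, and EB05 is found by root-finding
on the mixture CDF (`uniroot`, tolerance 10⁻¹⁰). E = 0 yields NA, flagged,
rather than an error. The default signal rule is EBGM > 2, with EB05
available as an alternative metric.

**Combined rule and volcano.** A drug is a signal only when all four
algorithm flags hold *and* a ≥ 3. Fisher exact two-sided p-values are
computed by hypergeometric summation (with the customary 10⁻⁷ relative
guard against floating-point ties) and Bonferroni-corrected with family
size m = the number of drugs with a ≥ 1 against the event class — the
family actually tested in the volcano. The published axis description
assigns log ROR and −log p to different axes in two places; since intent
cannot be inferred, `volcano_table()` emits the coordinate columns once and
records the chosen orientation in an attribute (`ror_axis`, default `"x"`).
Adjusted p-values of exactly zero are replaced by the smallest positive
double and flagged.

## Risk-factor model

The sensitivity analysis restricts to complete cases (non-missing sex and
age). Controls are all non-DIMD reports in the same deduplicated
complete-case universe — the published workflow never names its control
set, and this is the only reading consistent with drug-exposure odds
ratios far above 1.

The univariate screen retains drugs with ROR lower bound > 1, a > 100 and
Bonferroni-adjusted p < 0.01, all strict (a drug with exactly 100 cases is
excluded; the boundary is asserted in the tests). The design matrix is
all-binary: male sex; age < 33 years (strict — age exactly 33 scores 0);
one PS-exposure indicator per screened drug; the seven comorbidity flags.
Constant columns are retained with a warning since the penalized fit
handles them.

LASSO selection uses glmnet with α = 1, standardization on, convergence
threshold 10⁻⁶ and 10⁵ maximum iterations, with *outcome-stratified*
10-fold cross-validation: fold labels are assigned within each outcome
class from the user's seed, making selection bit-reproducible. The CV loss
defaults to the binomial deviance — the natural loss for a logistic
model — with mean-squared error available as an option, since the published
configuration says "mean-squared prediction error" for what is otherwise a
logistic LASSO. The selected set is the non-zero coefficients at λ.min.

The final inference is an ordinary maximum-likelihood logistic fit on the
selected covariates (post-LASSO, matching the published two-step
procedure; no selective-inference correction is applied beyond Bonferroni,
with family size k = the covariates in the final model). Complete
separation is a hard error naming the covariate. A flag (`use_lasso =
FALSE`) fits on all screened covariates instead, covering the alternative
reading in which every screened drug is reported as an independent risk
factor. Model discrimination is the rank-based (Mann–Whitney) AUC with
midrank tie handling, invariant under monotone transforms of the score.

## The synthetic FAERS generator

`faers_generate()` emits FAERS-dialect quarterly files plus a ground-truth
sidecar. Its purpose is to make every pipeline stage falsifiable: the
outcome is drawn per report from a logistic model whose odds are the
baseline odds times the product of the multipliers of the report's PS
signal drugs, so each configured multiplier *is* the conditional odds ratio
exactly. Duplicate report versions share a `caseid`, always carry a larger
`primaryid`, and receive a strictly later `fda_dt` with probability 0.5
per extra version (otherwise a tie), so both branches of the dedup rule are
exercised. Ages are emitted under mixed unit codes (80% YR, 10% MON, 10%
DEC), drug names with random case/padding, and PTs in natural MedDRA
spelling, so the normalizers are genuinely on the path.

Defaults were chosen once to mimic the published DIMD reporting profile
and are not tuned per test: demographics follow the reported Table-1-style
distributions (age median 53, IQR 33–67, 43% missing; weight median 70 kg,
74% missing; sex 50/40/10 F/M/missing; occupation and country frequencies
in the published proportions); duplicate rate 10%; outlier rate 0.2%. The
four signal drugs carry multipliers 8, 4, 2, 1 at exposure probabilities
0.008, 0.012, 0.025, 0.020. The spacing of exposure levels matters: the marginal
2×2 odds ratio of a drug is attenuated below its conditional multiplier by
odds-ratio non-collapsibility across co-exposures, and these exposure
levels keep that attenuation below a quarter of the Wald standard error at
200,000 reports, while still leaving the multiplier-2 drug above the
a > 100 screen. With that design the recovery properties are sharp: across
20 seeded replicates at n = 200,000, the ROR interval covers the designed
value in well over 90% of drug×seed events, the post-LASSO logistic OR
does the same for the multiplier-{2,4,8} drugs (the multiplier-1 drug
correctly fails the screen and never enters the model), and the
multiplier-1 drug is never flagged by the combined rule.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real FAERS: reporting-lag dynamics, country-specific
reporting propensities, realistic co-prescription structure (exposures are
independent Bernoulli draws), free-text drug-name dialects beyond
case/spacing noise, and MedDRA versioning. Published full-database headline
counts are functions of the complete 2004–2024 download and are out of
reach of a synthetic desk-scale benchmark by construction; the tests
instead verify the *estimators* (oracle equivalence to 10⁻⁶–10⁻¹²,
exhaustive Fisher enumeration up to N = 40, parameter recovery, exact
threshold boundaries, bit-reproducibility of the whole pipeline under a
fixed seed).

## Problem sizes and runtime choices

The test suite runs the oracle-equivalence checks on all 2×2 tables with
N ≤ 40 (135,746 tables), dedup correctness on a 50,000-report world with
duplicate rate 0.2, parameter recovery on 20 replicates of 200,000 reports,
and determinism on a 30,000-report double run — sizes chosen so the full
suite completes in minutes on a single core while keeping every binomial
tolerance band narrow enough to be informative. `scripts/acceptance.R`
uses the 200,000-report study-scale world so the a > 100 screen and the
LASSO/logistic stage engage.

## Known limitations

PT matching is literal; synonym handling for drugs is a user-supplied map,
not an ingredient dictionary. The EBGM prior is fitted without
stratification (no age/sex strata, matching the unstratified published
analysis) and without the count-squashing tricks needed for
millions-of-pairs scale. The BCPNN variance treats the three Beta
posteriors as independent, as in the classical formulation; the exactness
claim is about the moments under that model, not about the dependence it
ignores. Post-selection inference is intentionally naive (Bonferroni only),
mirroring the workflow it implements.
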