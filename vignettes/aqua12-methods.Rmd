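---
title: "Scoring ADR report quality with AQUA-12: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ADR report quality with AQUA-12: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqua12)
```

## The problem

Hospital adverse drug reaction (ADR) review committees depend on the
completeness of the reports submitted to them: causality between a medication
and a reaction cannot be assessed, and risk advice cannot be given, from a
report that omits the reaction description, the candidate medications or the
exposure timeline. AQUA-12 is a pragmatic ordinal rubric for auditing that
completeness. A trained assessor reads one report and scores seven data
elements:

| element id | element | scores |
|---|---|---|
| `prev_adr_history` | Previous ADR history | 0, 1, 2 |
| `actual_reaction` | Description/diagnosis of the index reaction | 0, 1, 2 |
| `key_events` | Narrative of key events around the reaction | 0, 1, 2 |
| `suspected_medications` | List and details of suspected medications | 0, 1, 2 |
| `timeline` | Medication timeline relevant to the reaction type | 0, 1 |
| `management` | Management of the episode | 0, 1 |
| `outcome_sequelae` | Outcome and severity | 0, 1, 2 |

Zero means no attempt to record (a report saying "see medical records" is
scored 0 — reports must stand alone); the intermediate score marks partial
completion. The total score `S` is the plain sum, 0–12. Categories partition
the range: Excellent (12), Good (10–11), Moderate (8–9), Poor (≤ 7); a report
is *high quality* when `S >= 10`. These boundaries are integers and
inclusive; fractional scores do not exist.

The package deliberately contains no machine scoring of free text. The rubric
is applied by human assessors; the engine consumes their element scores,
validates them against the rubric, and computes everything downstream. The
rubric ships as a JSON definition (`default_rubric()`), so an institution can
substitute an adapted element set, but the packaged default is fixed to the
seven elements above.

## Inter-rater reliability

Reliability is evaluated on **total scores**, with assessors in the role of
items. For an `n x k` matrix of totals (reports × assessors),
`cronbach_alpha()` computes

$$\alpha \;=\; \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right),$$

with \(s_j^2\) the sample variance of assessor *j*'s totals and \(s_T^2\) the
sample variance of the per-report row sums. This is numerically identical to
the two-way, consistency, average-measures intraclass correlation, and to the
ANOVA identity \(\alpha = 1 - MS_{res}/MS_{between}\); the test suite asserts
that identity against an independent `lm()`-based decomposition. Only this
single estimator is offered — it is the quantity standard statistical
packages report when "Cronbach's alpha" is requested of a rater panel — and
per-element reliability, while callable by building a matrix of element
scores, is not part of the validated surface.

Two degenerate regimes are treated explicitly rather than silently:

* identical row sums (no between-report variance): reliability is
  *undefined* and `cronbach_alpha()` raises an error — never a silent 1.0 or
  `NaN`;
* zero residual mean square (assessors identical up to per-rater constants):
  \(\alpha = 1\) exactly, and the confidence interval is reported as
  undefined with a warning.

Note that consistency, not absolute agreement, is measured: an assessor who
is uniformly one point harsher than the others does not reduce \(\alpha\).

### Confidence interval

`reliability()` attaches Feldt's F interval. With
\(F = MS_{between}/MS_{res}\) on \(df_1 = n-1\) and \(df_2 = (n-1)(k-1)\)
degrees of freedom, \((1-\alpha)\,F\) follows an F distribution under the
two-way normal model, giving the two-sided bounds

$$1 - (1-\hat\alpha)\,F_{1-\gamma/2;\,df_1,df_2}
\quad\text{and}\quad
1 - (1-\hat\alpha)\,F_{\gamma/2;\,df_1,df_2}$$

at confidence level \(1-\gamma\) (default 0.95). Under that Gaussian model
the package measures empirical coverage of 94–96% at the nominal 95% level
(1,000 replicates, `n = 50`, `k = 2`; recomputed by both the test suite and
`scripts/acceptance.R`). Under the package's *ordinal* synthetic model the
same interval covers at roughly 93%: totals are discrete sums of bounded
elements and the rater noise is heteroskedastic, so the normal-theory
interval is slightly anti-conservative there. That mismatch is a property of
Feldt's interval on discrete bounded scores, not of the implementation, and
is the reason a nonparametric bootstrap over reports
(`reliability(..., ci = "bootstrap")`) is provided as a sensitivity check.

### Discrepancy flagging

During rubric development, reports whose assessor totals spread by **more
than** two points are flagged for panel discussion: `flag_discrepancies()`
flags a report when `max(total) - min(total) > threshold` (default 2 — a
spread of exactly two points is acceptable and not flagged). Reports with a
single assessor are skipped with a message, never flagged.

## Association tests

Univariable comparisons between binary groups (development vs evaluation
phase; high vs low quality) follow one fixed convention, because the
published audit style this package reproduces used exactly it:

* **2 × 2 tables** → two-sided Fisher exact test, point-probability
  ordering: the p-value is the sum of hypergeometric probabilities, over
  tables with the observed margins, not exceeding the observed table's
  probability (relative tie tolerance 1e−7). The doubling convention is not
  offered. The implementation delegates to `stats::fisher.test()`, whose
  two-sided rule is precisely this; the test suite verifies it against an
  independent exhaustive enumeration for *every* 2 × 2 table with grand
  total ≤ 40 (135,750 tables, maximum discrepancy below 1e−10).
* **larger tables** → plain Pearson chi-square, no Yates continuity
  correction, df = (r−1)(c−1), upper-tail asymptotic p. Expected counts
  below 5 produce a warning but never an automatic switch of method —
  switching would silently change which published numbers are reproducible.
  Fisher's exact test for r × c tables (Freeman–Halton) is intentionally
  absent: the reproduced analyses never used it.

`compare_groups()` dispatches between the two by table shape after dropping
characteristic levels unobserved in both groups. Row and column order follow
the declared category orders in `aqua_factor_levels()`, and the
"Not recorded" severity level is a legal analysis level retained by default.

On small sparse tables the asymptotic chi-square p differs from the exact
conditional (permutation) p by more than Monte-Carlo noise — for the packaged
70-report tables the gap is of order 0.001–0.01. The suite therefore checks
asymptotic/permutation agreement in the regime where the approximation is
valid (large, well-filled tables) and documents, rather than hides, the gap
on the small ones. One published figure is deliberately not reproduced: the
severity-by-phase comparison prints p = 0.48, while the plain Pearson test on
the printed counts gives 0.355 (and its exact-conditional counterpart
≈ 0.36). No combination of the conventions above yields 0.48; the package
keeps the computed value and flags the published one as a documented
discrepancy.

## Cohort summaries

`quality_distribution()` and `completeness_breakdown()` summarise one
designated assessment per report. Which assessor is designated is an explicit
choice (`primary_assessments()`, default: the first assessor id in the data)
because multi-assessor audit rounds do not say whose scores should feed the
descriptive tables; the choice is configurable and recorded in the output
provenance rather than hidden.

Percentages are computed against the stated denominator and rounded **half
away from zero** to one decimal (`round_half_up()`), matching the printed
style of audit tables (base R's `round()` rounds half to even and would
differ, e.g. at 0.05); unrounded values are always carried alongside in
machine-readable fields. Medication classes are counted **per mention**: a
report implicating two antimicrobials contributes two counts, so the block's
denominator is the number of mentions (112 across the 70-report reference
cohort), not the number of reports. A per-report "set" reading is impossible
for the reference cohort (24 antimicrobial mentions across 20
development-phase reports) and is not offered.

## The synthetic cohort generator

Real per-report, per-assessor scores for the instrument's validation rounds
were never published, so every statistical property of the machinery is
checked on synthetic cohorts with known truth. The model
(`simulation_config()`, `generate_true_reports()`,
`generate_rater_scores()`):

1. **Latent reports.** Each report draws one true score per element,
   independently across elements, from a per-element probability profile.
   The default profile reproduces the reference cohort's element
   incompleteness rates (17.1%, 27.1%, 35.7%, 37.1%, 8.6%, 8.6%, 8.6% below
   maximum), splitting the below-maximum mass 2:1 between the partial score
   and zero for two-point elements — partial completion is the commoner
   failure mode in practice.
2. **Rater noise.** Each of `k` assessors copies each true element score
   and, with probability \(\varepsilon\), shifts it by one point up or down
   with equal odds, clamped to the element's range (a shift proposed past a
   scale boundary is lost). The ±1 form keeps disagreement magnitudes on the
   scale of the "more than two points" flagging rule, unlike uniform
   rescoring which would produce implausible 0↔2 jumps.
3. **Metadata.** Reporter vocation, unit, reaction type, severity and phase
   are drawn from the reference cohort's relative frequencies; each report
   carries one or two medication-class mentions (mean 1.6, matching 112
   mentions over 70 reports).

Under this model the large-sample value of \(\alpha\) has a closed form.
Writing \(u_i\) for the conditional mean observed total of report *i* (the
true total plus the boundary-clamping bias, which is analytic per element)
and \(W\) for the mean within-report noise variance,
\(B = \operatorname{Var}(u_i)\) and

$$\alpha_{pop} = \frac{B}{B + W/k}.$$

`population_alpha()` evaluates this exactly and a 200,000-report simulation
agrees to three decimals. `calibrate_noise()` inverts it by root finding: for
the default profile and `k = 2`, \(\varepsilon \approx 0.105\) yields
\(\alpha_{pop} = 0.9\), the agreement level the instrument showed in its
evaluation rounds, and this is the default noise level. Parameter recovery at
that setting (`n = 50`, `k = 2`, 500 replicates) returns mean estimated
\(\alpha\) within ±0.01 of 0.9 — comfortably inside the ±0.03 design
tolerance.

What the generator does **not** emulate: inter-element correlation within a
report (elements are independent by default; a shared latent-quality factor
can be induced by concentrating profiles, but no correlation parameter is
fitted to real data), assessor-specific severity or drift, report-difficulty
effects on rater noise, and any association between metadata and quality.
Passing tests on synthetic cohorts therefore validate the estimators and
plumbing, not claims about real ADR report populations.

## The packaged fixture cohort

`cohort_fixture()` loads a fully synthetic 70-report cohort (20 development,
50 evaluation) whose *margins* reproduce every published count of the
reference audit exactly: the quality-category distribution per phase
(9/4/4/3 and 21/18/8/3), the per-element incompleteness counts per phase,
and each characteristic's phase and quality-group cross-tabulations. The
rows were constructed deterministically — a 0/1 incidence matrix per phase
with the published row/column sums, and per-characteristic three-way
(phase × quality × level) allocations solved from the published two-way
margins — so every association p-value computed from the fixture equals the
one computed from the printed tables. Individual rows are synthetic: the
real line listing was never published, and the fixture never pretends
otherwise. The published medication-class *totals* column is internally
inconsistent (its entries sum to 110 although the per-phase columns sum to
31 + 81 = 112 mentions); the fixture follows the per-phase columns.

## Numerical and design choices

* Validation errors name the offending element and value; absent elements
  are never imputed.
* Score matrices must be listwise-complete; reports missing an assessor are
  dropped with a logged count, never imputed.
* `reliability()` refuses confidence levels outside (0, 1); the Feldt
  interval's upper bound is capped by construction at 1 only through the
  estimator (\(\hat\alpha \le 1\)), and bounds below −1 are possible for
  pathological matrices, as with the estimator itself.
* JSON outputs carry full-precision numbers; half-up rounding is applied
  only in printed tables.
* Simulation problem sizes used by the packaged checks — 500 replicates for
  recovery, 1,000 for coverage, 200 per grid point for the noise-monotonicity
  property — were chosen so each Monte-Carlo standard error is several times
  smaller than the tolerance it guards, while the whole suite stays
  comfortably fast on one CPU.
* Seeds: all stochastic routines take explicit integer seeds; derived seeds
  stay within 32-bit range.

## Known limitations

* Feldt coverage is mildly anti-conservative (~93% at nominal 95%) on
  discrete bounded totals; use the bootstrap interval when that matters.
* The asymptotic chi-square p on small sparse tables differs from the exact
  conditional p by more than Monte-Carlo noise; the package reports the
  asymptotic value because that is what the reproduced audit used.
* The rubric engine validates and aggregates human scores; it cannot detect
  a mis-scored report.
* Reliability is validated for total scores only.
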