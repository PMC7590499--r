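---
title: "Validating a probabilistic verbal-autopsy coder: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a probabilistic verbal-autopsy coder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacheck)
```

## The problem

Verbal autopsy (VA) infers a cause of death (CoD) from a structured
interview when no medical certification exists. Probabilistic coders of the
InterVA family turn the interview into a fixed battery of binary indicators
and compute a posterior over a closed cause list. Validating such a coder
against a gold standard — here, the complete diagnostic autopsy (CDA) —
raises two distinct questions: does the coder get *individual* deaths right
(agreement, sensitivity per cause), and does it get the *population
composition* right (cause-specific mortality fractions, CSMFs)? The two can
diverge badly, and both depend on the cause composition of the test set,
which is why the harness stresses every metric across many artificial
compositions.

`vacheck` implements the full chain: coder, individual metrics, population
metrics, composition-resampling harness, and a synthetic-cohort generator
that stands in for individual death records that cannot be shared.

## The coder

For a death with indicator vector $s$ and probbase with prior $P_0(c)$ and
conditionals $P(s_i = \mathrm{yes} \mid c)$, the posterior over the $K'$
substantive causes is

$$P(c \mid s) \;\propto\; P_0(c) \prod_{i:\, s_i = \mathrm{yes}} P(s_i \mid c).$$

Assumptions worth stating explicitly:

* **Cause-conditional independence** of indicators — the standard InterVA
  assumption; the synthetic generator deliberately simulates under the same
  assumption, so engine tests measure implementation, not model
  misspecification.
* **Only "yes" answers carry evidence.** "No" and missing contribute
  nothing. This makes structurally unavailable indicators (questions absent
  from source documents) well defined: they simply never fire. It mirrors
  the cited model family and keeps the likelihood monotone in information.
* **Prevalence enters through the prior.** Malaria/HIV prevalence levels
  multiply tagged causes' priors (factors 1, 0.1, 0.01 for high/low/very
  low) before renormalization. Prevalence is information about cause
  frequency, not about symptom-given-cause behavior, so the conditionals
  are untouched.

Numerical choices: conditionals are clamped to $[10^{-6}, 1-10^{-6}]$ at
load so a sparse probbase cannot annihilate the posterior; accumulation is
in the log domain with log-sum-exp normalization (a 5,000-indicator record
is exercised in the tests); posterior ties are broken by dictionary order
for determinism.

**Reporting rule.** The original tool's internal cutoffs are not public.
The package reports the top cause only if its posterior reaches
`top_threshold` (default 0.4), then further causes while they reach
`relative_threshold` (default 0.5) of the top posterior, up to
`max_causes` (default 3); unreported mass is the *non-conclusive* residual.
The defaults were chosen once, for qualitative realism (most deaths one
cause, some two, few three, a small non-conclusive share) and are exposed
in `reporting_rule()`; they are not claimed to equal the original tool's
rule.

## Individual-level metrics

Per cause $j$, confusion counts come from the *top* cause only (second
causes are summarized separately by `agreement_summary()` and never enter
TP). Percentages are computed in full precision and displayed as integers
under **round half to even**; the printed tables this convention was
checked against contain 67.5→68, 62.5→62 and 87.5→88, which only banker's
rounding explains, and the display path uses exact integer arithmetic so
ties are decided exactly. Cohen's kappa is computed once, on the observed
cohort — in the source tables only the concordance column is marked as
draw-based — while the chance-corrected concordance

$$\mathrm{CCC}_j = \frac{\mathrm{sens}_j - 1/K}{1 - 1/K}$$

is medianized over composition draws. $K$ is the number of substantive
causes in the group's dictionary (not the number observed), and the overall
CCC is the *unweighted* mean over causes with at least one gold death,
following the metric family's definition; both choices are configurable in
spirit but deliberate defaults here. The non-conclusive category is a
first-class row in the per-cause tables and in the kappa cross-tabulation.

## Population-level metrics

The coder's CSMF credits each reported cause with its likelihood
("partial-likelihood weighting"); per-death residual mass accrues to the
non-conclusive fraction. By default only the first two reported causes are
used (`max_causes_used = 2`), matching the accounting of the source
tables; the third cause is available via configuration. CSMF accuracy is

$$\mathrm{CSMFA} = 1 - \frac{\sum_j |est_j - true_j|}{2\,(1 - \min_j true_j)},$$

and its chance correction rescales so random allocation scores 0. The
baseline is **empirical by default**: the median CSMFA of allocating $n$
deaths uniformly at random against uninformative Dirichlet truths over the
same $K$ causes. The analytic constant $1 - 1/e \approx 0.632$ is exposed
as `analytic_baseline()`, but it is the $K \to \infty$ limit: for small
cause lists the exact baseline is larger (at $K = 2$ the large-$n$ median
is $2/3$), so chance correction with the analytic constant would be
systematically optimistic at $K \le 7$. That mismatch is visible in the
acceptance checks and is the reason the empirical baseline, matched to the
group's $K$ and $n$, is the default.

## The Dirichlet harness

"Uninformative" is read as symmetric Dirichlet with $\alpha = 1$
(configurable). Per draw, a composition over the group's **substantive**
causes is sampled, the cohort is resampled to it (cause counts multinomial,
records within cause drawn with replacement), and each resampled record
keeps its coder output — the coder is deterministic per death, so outputs
travel with records. Non-conclusive is not a drawable gold category: the
validation varies the composition of actual causes, and a residual category
with structural truth share $1/K{+}1$ would distort every draw. Gold
non-conclusive deaths therefore never enter resampled cohorts, though they
remain first-class in the observed-data tables. Compositions that put
weight on causes unobserved in the cohort are renormalized over observed
causes (with a warning).

Within the draw loop the CSMF comparison is made **over the substantive
causes with the coder's vector renormalized** (residual excluded): the
drawn truth has zero mass on "undetermined", so keeping the residual
category would bound CSMFA away from 1 by the reporting rule's behavior —
with a mean first-cause likelihood of 0.90, even a perfectly ranking coder
would be capped near 0.88 — confounding allocation accuracy with reporting
confidence. The residual stays fully visible in the Table-4-style CSMF
report, where it belongs. Two further conventions: the truth in the
numerator is the *realized* resampled composition, so an identity coder
scores exactly 1 on every draw, while the denominator's $\min$ uses the
*drawn* continuous composition, which cannot be degenerate. Medians are
order-invariant and reported per group.

Seeding: one `set.seed()` at harness entry with sequential draws. Execution
is serial, so per-draw counter substreams would add machinery without
changing reproducibility; the same seed reproduces every median bit for
bit.

## The synthetic generator

`simulation_spec()` defaults encode the study conditions the package is
shaped around: five groups of 18/41/54/91/112 deaths; per-group true
compositions equal to the gold-standard CSMFs of the source series; 245
indicators of which 43 are missing in *every* record (the missingness is
structural — fields absent from clinical documents — not per-death
nonresponse; 24 of the 43 are flagged as secondary questions, behaviorally
inert); exactly one gold cause per death with likelihood 1; coder
likelihood means 0.90 (first cause) and 0.38 (second cause, present for
about 10% of deaths) with spread 0.05, consistent with the tight published
ranges. When a simulated report carries a second cause, the second
likelihood keeps its target mean and the first yields, so reports always
satisfy the sum-to-one invariant with non-increasing likelihoods.

The generator's probbase gives each cause a private indicator block at rate
$0.05 + 0.9s$ against a 0.05 background; $s = 0$ is the no-signal limit
(posterior equals prior) and $s = 1$ is pathognomonic. `simulate_va_outputs()`
bypasses the engine entirely, drawing top causes from a row-stochastic
confusion kernel — this is what lets the metric modules be tested against
known misclassification structure.

**What passing tests do and do not show.** The generator simulates under
the coder's own independence assumption, with honest indicators and
structural missingness only. Real VA data violate all three (comorbidity
correlations, informant error, informative missingness), so the test
results certify the *computational pipeline* — metrics, harness,
accounting — not the field performance of any coder. Group-level
concordance and CSMF-accuracy values of the original series depend on its
individual records, which are not public; the package's checks are
property-based instead (chance calibration, parameter recovery, formula
identities, worked-example reproduction of the printed per-cause tables).

`parameter_recovery_suite()` interprets "the pipeline at signal $s$"
through the kernel simulator with kernel $sI + (1-s)/K$: the Bayes engine
is deterministic, so at $s = 0$ it cannot emulate random guessing (a
uniform posterior falls below the top threshold and every death becomes
non-conclusive, pinning CCC at $-1/(K-1)$ rather than 0). The engine route
is covered by its own recovery check: a pathognomonic cohort must be coded
back to its gold causes for more than 95% of deaths.

## Problem sizes

The shipped tests run the harness at 500 deaths × 500 draws for the
chance-calibration and recovery checks (the sizes the acceptance criteria
name), 10,000 draws for the baseline sweep, and 20–60 draws in the
structural and determinism tests; the whole suite completes in about a
minute on one core. These sizes were chosen so that Monte-Carlo noise is an
order of magnitude below every asserted tolerance.

## Known limitations

* The engine is probbase-agnostic; the authentic InterVA-4 probbase and its
  letter-grade encoding are external artifacts, and InterVA-5 logic is out
  of scope.
* The shipped ICD-10 map is illustrative: the source study's full
  code-to-category table is unpublished, so only the documented subset is
  encoded and users supply their own map for real analyses.
* The infection-subset analysis requires subtype annotations; when coder
  outputs lack them (the engine emits broad categories only) the pipeline
  falls back to broad categories within the infectious subset.
* Whether the original analysis resampled deaths or reweighted metrics
  analytically per composition is not stated in the source; resampling is
  implemented, and analytic reweighting would be a possible variant.
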