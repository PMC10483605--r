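---
title: "Screening tumor mutations in plasma by variant frequency change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor mutations in plasma by variant frequency change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvfcscreen)
options(mvfcscreen.verbose = FALSE)
```

## The problem

Circulating tumor DNA (ctDNA) lets us monitor tumor burden and detect
minimal residual disease (MRD) from blood, but most ctDNA workflows first
need to know *which* plasma mutations are tumor-derived. That knowledge is
usually imported from tumor-tissue sequencing, which reintroduces invasive
sampling and is biased by tumor heterogeneity. Plasma, however, is a
mixture: cell-free DNA carries variants from the tumor, from clonal
hematopoiesis (CHIP), from germline leakage and from sequencing error, and
a one-timepoint plasma panel cannot tell these apart.

This package implements a screening strategy that uses *dynamics* instead
of tissue: when surgery removes the bulk of the tumor, the allele
frequency of genuinely tumor-derived plasma mutations must collapse with
it, while hematopoietic and other non-tumor variants are unaffected. The
quantity of interest is the **mutation variant frequency change**

$$\mathrm{MVFC} = \frac{\mathrm{VAF}_{\text{post-operative}}}
                       {\mathrm{VAF}_{\text{pre-operative}}},$$

computed per mutation between plasma drawn before and after resection.
Mutations with $\mathrm{MVFC} < 0.2$ are classified as tumor-derived
("MVFC-identified tumor mutations"); their persistence in post-operative
plasma above a detection floor defines ctDNA-based MRD, which can be
combined with the serum markers AFP and DCP commonly used in
hepatocellular carcinoma (HCC) follow-up.

## Calling model and thresholds

Input is UMI-consensus count data: per site and sample, the consensus
depth and the alt-supporting duplex (double-strand) and single-strand
consensus read counts. Upstream consensus building and stereotypical-error
suppression are out of scope; the pipeline starts from these counts.

A site is callable when all of the following hold
(`calling_config()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `min_depth` | 100 | consensus reads | below this, VAF estimates are too coarse for 0.5%-scale variants (inclusive $\ge$) |
| support rule | duplex $\ge 1$ **or** single-strand $\ge 3$ | reads | one duplex family is the standard high-confidence evidence unit of duplex sequencing; without duplex support, three independent single-strand families are required |
| `alpha` | 0.01 | probability | VAF must exceed $-\ln(\alpha)/\mathrm{depth}$ (strict $>$): at that frequency a real variant would yield zero alt reads with probability $\le \alpha$ under binomial sampling, so anything below it is indistinguishable from dropout |
| `pre_plasma_min_vaf` | 0.005 | fraction | pre-operative plasma floor (inclusive $\ge$), screening only variants quantifiable enough for a meaningful ratio |
| `tumor_tissue_min_vaf` | 0.10 | fraction | tumor tissue keeps clearly clonal mutations only (strict $>$) |

Mutations also detected in the patient's PBMCs — same support rule **and**
VAF above the PBMC depth-dependent threshold; both clauses must hold — are
removed as hematopoietic/germline contamination before screening.

Interpretation choices where the rules admit more than one reading, fixed
here and exposed in the configuration: "single-strand reads" are counted
summed over both strands (a per-strand reading would be stricter); the
depth cutoff and pre-plasma floor are inclusive while the formula, tissue
and MRD thresholds are strict, following the wording each rule is usually
stated with.

## Screening and the unevaluable category

`screen_patient()` computes the MVFC of every retained pre-operative call
against the *raw* post-operative counts at the same site. The post sample
is deliberately not re-called: a tumor mutation that responded to surgery
has near-zero post-operative VAF and could never re-pass the calling
rules, yet that near-zero value is exactly the signal. Three outcomes are
possible:

* post site covered at $\ge$ `min_depth`: MVFC is assigned, class
  `tumor` iff $\mathrm{MVFC} < 0.2$ (strict; exactly 0.2 is `nontumor`);
* post VAF 0: MVFC 0, class `tumor` — complete response at that site;
* post site absent or covered below `min_depth`: class `unevaluable`.
  Assigning MVFC 0 here would manufacture tumor calls out of missing
  data, so unevaluable mutations are excluded from MRD and enrichment
  computations.

The 0.2 boundary is a default, not a constant of nature: the MVFC
distribution is bimodal (a near-zero tumor mode and a mode at 1), and the
dividing point can shift with panel design and the clinical event used.
`mvfc_distribution()` exports the histogram so the split can be inspected
and re-thresholded manually; no automatic valley-finding is attempted.

## MRD calling

A patient is ctDNA-MRD positive when at least one tumor-class mutation is
present in post-operative plasma at VAF strictly above
`mrd_min_post_vaf` (0.1%). Only the VAF condition is applied at this step
— by design the post-operative evidence is not required to re-pass the
duplex/single-strand rule, mirroring how the decision rule is stated for
the method. AFP (> 20 ng/mL) and DCP (> 40 mAU/mL) give serum calls; the
headline combination is ctDNA OR AFP (DCP is evaluated as a single marker
but is not part of the combination). Serum cutoffs use strict `>` for
symmetry with the ctDNA rule.

## The synthetic cohort generator

Real cohorts for this design are access-restricted, so the package ships
a generator (`simulate_cohort()`) that emulates the data-generating
assumptions the method relies on, with ground-truth labels for testing:

* **Mutation load.** Per patient, Poisson numbers of tumor-derived
  (mean 11.65), non-tumor plasma (mean 79) and PBMC-shared (mean 10)
  mutations; the first two means reproduce a realistic per-patient plasma
  mutation load of roughly 90 and a tumor fraction of it near 13%.
* **VAFs.** Pre-operative plasma VAFs uniform on [0.005, 0.05] for both
  tumor and non-tumor origins — deliberately overlapping, so that static
  VAF carries no class information and only dynamics can separate them.
  Tumor-tissue VAFs of tumor mutations are uniform on [0.05, 0.60]; the
  tail below the 10% tissue cutoff is intentional, so tissue calling
  misses a small subclonal fraction as it does in practice.
* **Surgery.** Post-operative expected tumor-mutation VAF is the
  pre-operative value times `residual_ratio` (0.02) in residual-disease
  positive patients (30% of the cohort) and 0 in negative ones; non-tumor
  VAFs are unchanged. Every site receives a background error rate of
  1e-4.
* **Counts.** Depth is negative-binomial (plasma mean 1500, PBMC 850,
  tumor 1380, size 50); alt counts are binomial in depth and expected
  VAF, split duplex/single-strand with probability 0.5. Binomial (not
  beta-binomial) sampling is the simplest model consistent with VAF
  tracking tumor fraction; overdispersion is confined to depth.
* **PBMC-shared variants** get PBMC VAFs uniform on [0.01, 0.10], high
  enough that the PBMC-removal rule actually fires for the large
  majority, so the filter is exercised rather than decorative.
* **Outcome.** Recurrence times follow a Weibull proportional-hazards
  model, shape 0.9 and scale 2296 days — a mildly decreasing hazard with
  30% two-year recurrence in baseline patients, matching the
  early-recurrence-heavy pattern after HCC resection and ~45% cohort-wide
  two-year recurrence. The hazard is multiplied by 4
  (`hr_mrd`) for residual disease and by 2 (`hr_afp`) for AFP positivity;
  the AFP effect makes AFP an independent prognostic factor, as reported
  for post-operative HCC, and is what gives the ctDNA+AFP combination
  information beyond either single marker. Administrative censoring is
  uniform on [90, 1869] days (staggered enrollment with a multi-year
  accrual window). Clinical covariates (age, tumor number/size,
  differentiation, smoking, alcohol, BCLC stage) are generated as
  outcome-independent noise.
* **Serum markers.** Lognormal conditional on residual-disease truth:
  AFP meanlog $\log 30$/$\log 4$ (sd 1.0/0.85), giving sensitivity ~66%
  and specificity ~97% against truth at the 20 ng/mL cutoff — AFP is a
  specific but insensitive marker; DCP meanlog $\log 80$/$\log 15$
  (sd 1.0/0.8), sensitivity ~76%, specificity ~89% at 40 mAU/mL.

What the generator does **not** emulate: mutational signatures or any
sequence context, copy-number and fragmentomic signal, stereotypical
sequencing artifacts (assumed removed upstream), clonal evolution between
draws, inter-patient heterogeneity in `residual_ratio`, and correlations
between serum markers and covariates beyond the shared disease truth.
Tests passing on this cohort therefore show that the pipeline's logic and
statistics behave as designed under the method's own assumptions — not
that the thresholds are optimal for any particular real panel.

```{r example}
cohort <- simulate_cohort(simulation_config(seed = 7, n_patients = 5))
cohort
cfg <- calling_config()
pre <- cohort$pileup[cohort$pileup$sample_type == "pre_plasma", ]
calls <- subtract_pbmc(call_sample_mutations(pre, cfg),
                       cohort$pileup[cohort$pileup$sample_type == "pbmc", ],
                       cfg)
screened <- screen_patient(calls, cohort$pileup, cfg)
table(screened$mvfc_class)
call_mrd(screened, cohort$manifest, cfg)
```

## Evaluation statistics

* **Enrichment.** The 2x2 table of (detected in tumor tissue) x (MVFC
  class), pooled over patients, is tested with Pearson's chi-square
  (df 1) without continuity correction by default; the correction is a
  flag. Pooling mirrors how the enrichment claim is naturally stated —
  one test over all mutations.
* **Survival.** Kaplan-Meier curves and the two-group log-rank test
  (`survival::survfit`/`survdiff`), and Cox proportional-hazards
  regression with the Efron tie approximation (`survival::coxph`,
  convergence tightened to `eps = 1e-12`), univariate or multivariate.
  Tests cross-check both against independent hand-tabulated O/E/V
  computations and a grid-search maximization of an independently coded
  Efron partial likelihood.
* **Fixed-horizon ROC.** Cases are patients recurring on or before the
  horizon, controls those event-free beyond it; patients censored before
  the horizon have unknown status and are excluded. AUC uses the
  rank (Mann-Whitney) formulation with midranks, so a binary marker's AUC
  is exactly (sensitivity + specificity)/2.
* **Time-dependent ROC.** Cumulative-case/dynamic-control AUC(t) with
  inverse-probability-of-censoring weights from the Kaplan-Meier
  censoring estimator (cases weighted by $1/\hat G(T_i^-)$, controls by
  $1/\hat G(t)$). This is the conventional estimator for fixed-horizon
  prognostic claims; without censoring it reduces exactly to the
  fixed-horizon AUC, which is tested. "Six months / one year / two
  years" are 183/365/730 days; p-values are two-sided with
  $\alpha = 0.05$.

A note on marker combination: because the ctDNA call is already highly
sensitive to the simulated residual disease, the OR-combination with AFP
buys only a small expected AUC gain at the six-month horizon, and in any
*single* simulated cohort the paired AUC differences between combined and
single markers are of the same order as their Monte-Carlo noise. The
package's replicate-level checks (log-rank power across 100 cohorts)
average over this noise; single-cohort AUC comparisons should be read
with that caveat.

## Numerical and degenerate-input choices

Ratios are computed in double precision with no rounding (tables are
written with 17 significant digits and round-trip bit-exactly). Division
by a zero pre-operative VAF cannot arise for screened mutations (the
pre-plasma floor is positive) and raises an error elsewhere. Empty
cohorts, header-only files and zero-event groups are either legal
degenerate inputs (empty outputs) or explicit errors, never silent NaNs;
the pipeline reports per-stage counts to standard error and aborts with
the stage name on failure. All randomness flows from the single seed in
`simulation_config`; identical configurations produce byte-identical
pipeline outputs, which the test suite asserts with file checksums.

Problem sizes used by the test suite were chosen to keep the full run
under a minute while leaving the stochastic checks well-powered: 50
patients for recovery/enrichment, 100 replicate cohorts of 65 patients
for the log-rank power check, one 200-patient cohort for marker AUCs, and
10,000 replicates for binomial-mean checks.

## Limitations

The screen requires a clinical event with a known, large effect on tumor
burden; a marginal debulking compresses the MVFC separation and the 0.2
boundary loses meaning. Mutations unevaluable post-operatively are
unrescuable without deeper or repeated draws. The MRD rule trusts single
qualifying mutations, so residual CHIP misclassified as tumor-class
(rare but possible) can flip a patient call. Finally, defaults here are
calibrated to ~1500x UMI-consensus panels; shallower assays need jointly
re-derived depth, VAF and MVFC thresholds.
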