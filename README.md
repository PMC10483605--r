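# mvfcscreen

Screening tumor-derived mutations in plasma **without tumor-tissue
sequencing**, and calling minimal residual disease (MRD) from
post-operative cell-free DNA.

Most ctDNA monitoring needs a tissue-derived mutation list to know which
plasma variants are tumor-derived; plasma alone is a mixture of tumor,
clonal-hematopoiesis (CHIP), germline-leak and artifactual variants.
This package implements a dynamics-based alternative for surgical
cohorts (developed for hepatocellular carcinoma, applicable to any panel):
if surgery removes the tumor bulk, the variant allele frequency (VAF) of
genuinely tumor-derived plasma mutations must collapse with it. The per-
mutation statistic is the **mutation variant frequency change**

```
MVFC = VAF_post-operative / VAF_pre-operative
```

and mutations with `MVFC < 0.2` are classified as tumor-derived. The
pipeline is:

1. **Call** pre-operative plasma mutations from UMI-consensus counts:
   depth ≥ 100, support by ≥ 1 duplex (double-strand) consensus read or
   ≥ 3 single-strand reads, VAF > −ln(0.01)/depth, pre-plasma VAF ≥ 0.5%
   (tumor tissue, where available, uses VAF > 10%).
2. **Subtract** variants detected in matched PBMCs (same support rule and
   VAF threshold there) to remove hematopoietic/germline contamination.
3. **Screen** each remaining mutation by MVFC against the raw
   post-operative counts; mutations without adequate post-operative
   coverage are `unevaluable`.
4. **Call MRD**: a patient is ctDNA-MRD positive if any tumor-class
   mutation persists post-operatively at VAF > 0.1%; serum AFP
   (> 20 ng/mL) and DCP (> 40 mAU/mL) give serum calls, and the combined
   marker is ctDNA OR AFP.
5. **Evaluate**: tissue-enrichment chi-square, Kaplan–Meier/log-rank,
   univariate/multivariate Cox (Efron ties), fixed-horizon ROC for early
   recurrence (183 days), and time-dependent AUC(t) with IPCW.

A seed-deterministic synthetic cohort generator (`simulate_cohort()`)
emulates the assumed data-generating process — tumor-fraction collapse
after surgery, persistent non-tumor mutations, PBMC-shared variants,
binomial sequencing noise at ~1500× consensus depth, and MRD-linked
Weibull recurrence times — with ground-truth labels, so every stage is
testable end to end. See `vignette("mvfc-screening")` for the model,
parameter rationale, and limitations.

## Worked example

```r
library(mvfcscreen)
cohort <- simulate_cohort(simulation_config(seed = 7, n_patients = 65))
cfg <- calling_config()

pre   <- cohort$pileup[cohort$pileup$sample_type == "pre_plasma", ]
pbmc  <- cohort$pileup[cohort$pileup$sample_type == "pbmc", ]
calls <- subtract_pbmc(call_sample_mutations(pre, cfg), pbmc, cfg)
screened <- screen_patient(calls, cohort$pileup, cfg)
table(screened$mvfc_class)
#> nontumor    tumor
#>     5035      789
```

789 of 5824 screened plasma mutations show the post-surgical VAF collapse
(`MVFC < 0.2`). Crossing them with tumor-tissue calls shows the class is
almost exactly the tissue-confirmed set:

```r
tissue <- call_sample_mutations(
  cohort$pileup[cohort$pileup$sample_type == "tumor", ], cfg)
tab <- enrichment_table(screened, tissue)
tab
#>               tumor nontumor
#> in_tissue       705        1
#> not_in_tissue    84     5034
chi_square_enrichment(tab)
#> statistic = 5110, df = 1, p = 0
```

MRD calls and their prognostic value:

```r
mrd <- call_mrd(screened, cohort$manifest, cfg)
d <- merge(cohort$manifest, mrd, by = "patient_id")
km_logrank(d$rfs_days, d$relapse_event, d$ctdna_positive)
#> statistic = 13.76, df = 1, p = 0.0002082

time_dependent_roc(d$combined_positive, d$rfs_days, d$relapse_event,
                   c(183, 365, 730))
#>   time       auc n_cases n_controls
#> 1  183 0.7461054      13         51
#> 2  365 0.6796536      17         44
#> 3  730 0.6858351      21         29
```

Patients carrying persistent tumor-class mutations after surgery relapse
significantly earlier (log-rank p ≈ 2e-4), and the combined ctDNA+AFP
marker discriminates six-month early recurrence with AUC ≈ 0.75 on this
cohort. The same flow runs end to end from one YAML config via
`run_pipeline(config, out_dir)` or the CLI
(`inst/cli/mvfc_pipeline.R` with subcommands `simulate`, `call`,
`screen`, `mrd`, `evaluate`, `run-all`).

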