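# vascreen

Marker-guided screening of vascular (endothelial) genes in bulk tumor
transcriptomes, differential-correlation association with an MRI
contrast-enhancement phenotype, and survival stratification — with a seeded
synthetic cell-type-mixture cohort for end-to-end validation.

## Who this is for

Bulk RNA-seq averages over every cell type in a biopsy, so genes expressed in
the tumor vasculature are diluted and hard to see directly. If the endothelial
fraction varies across a cohort, endothelial-specific genes co-vary with
canonical endothelial markers — and that co-variation is enough to screen for
them without deconvolution. `vascreen` is for computational biologists working
with cohorts (e.g., TCGA glioblastoma) that pair expression with MRI
segmentation volumes and survival, who want this screen plus its radiogenomic
and prognostic follow-ups as tested, reusable, scriptable pieces.

## The statistics at the core

* **EC-enrichment screen.** For every gene *g* and marker panel
  *M* = {CDH5, CLDN5, VWF}, compute Spearman ρ(g, m) across samples and
  `mean_corr(g) = mean over m in M of ρ(g, m)`; genes with `mean_corr > 0.3`
  are EC-enriched; rank 1 = highest mean correlation. p-values use the t
  approximation `t = ρ·sqrt((n−2)/(1−ρ²))`; FDR is Benjamini–Hochberg.
* **Differential correlation.** With EV (enhancing), NV (central
  non-enhancing) and CV = EV + NV segmentation volumes, the EV/CV ratio
  defines the contrast-enhancement phenotype. The top-20 and bottom-20
  samples by EV/CV form CE-high/CE-low groups; per EC-enriched gene,
  `Δ = mean_corr within CE-high − mean_corr within CE-low`; `Δ > 0.1` ⇒
  CE-high-associated, `Δ < −0.4` ⇒ CE-low-associated.
* **Survival.** Median EV/CV split; Kaplan–Meier product-limit curves;
  log-rank test `χ² = (ΣO − ΣE)²/ΣV`; Cox proportional hazards (Efron ties,
  via the `survival` package) adjusting for age; age subgroups (< 60 / ≥ 60);
  pooled-variance t test of EV/CV, mesenchymal vs other subtypes.

See `vignettes/vascular-screening-methods.Rmd` for conventions, degenerate
cases, and what the synthetic generator does and does not emulate.

## Worked example

```r
library(vascreen)

ds  <- generate_dataset(mixture_config(seed = 42))   # 2000 genes x 128 samples
scr <- enrichment_screen(marker_correlation_profile(ds$expression), threshold = 0.3)
scr
#> enrichment_result: 2000 scored genes, 155 enriched (mean corr > 0.3), 0 dropped
#>   gene_id mean_corr          fdr rank enriched
#> 1   CLDN5 0.8519349 0.000000e+00    1     TRUE
#> 2    CDH5 0.8449727 0.000000e+00    2     TRUE
#> 3     VWF 0.8436565 0.000000e+00    3     TRUE
#> 4 ECG0033 0.8176845 9.141948e-88    4     TRUE
#> ...
```

The three markers rank 1–3 (self-correlation is included in their own mean),
and the screen recovers the 150 planted constitutive endothelial genes at
recall and precision 1.0 on this seed. Then the imaging phenotype and the
differential score:

```r
feats  <- compute_segmentation_features(ds$segmentation)   # CV = EV + NV, ratio = EV/CV
groups <- dichotomize_extremes(feats, k = 20)              # 20 CE-high, 20 CE-low
tab    <- differential_correlation_score(ds$expression, marker_panel(), scr, groups)
head(tab[order(-tab$delta), c("gene_id", "corr_high", "corr_low", "delta", "ce_class")], 3)
#>     gene_id corr_high    corr_low     delta           ce_class
#> 155 CEH0024 0.8125313 -0.02155388 0.8340852 CE-high-associated
#> 113 ECG0150 0.8170426  0.45513784 0.3619048 CE-high-associated
#> 131 ECG0054 0.8310777  0.47969925 0.3513784 CE-high-associated
```

The top hit is a planted conditional gene (`CEH0024`): strongly
marker-correlated in CE-high tumors, flat in CE-low tumors. Survival, with
the simulated hazard ratio of 1.8 for above-median EV/CV:

```r
split <- median_split(feats)
hi <- merge(split[split$group == "CE-high", ], ds$clinical)
lo <- merge(split[split$group == "CE-low", ], ds$clinical)
logrank_test(hi$os_time, hi$os_event, lo$os_time, lo$os_event)
#> log-rank: chi2 = 15.6240, p = 7.727e-05 (n = 64 vs 64)

cox_fit(ds$clinical$os_time, ds$clinical$os_event,
        data.frame(ce_high = as.numeric(split$group == "CE-high"),
                   age = ds$clinical$age))
#> cox_fit: n = 128, events = 99
#>     term         coef         se        hr     ci_lo    ci_hi            p
#>  ce_high  0.789936768 0.20702930 2.2032571 1.4683903 3.305893 0.0001358637
#>      age -0.004460574 0.01162996 0.9955494 0.9731132 1.018503 0.7013182254
```

The CE-high group has significantly worse survival (hazard ratio 2.20, 95% CI
1.47–3.31; the true simulated value 1.8 is inside the interval) and age — a
pure noise covariate here — is null, as it should be.

## Command line

```sh
Rscript inst/cli/vascreen.R simulate --seed 42 --out-dir sim/
Rscript inst/cli/vascreen.R run --config run.json --out-dir out/
```

(after installation the script lives at
`system.file("cli", "vascreen.R", package = "vascreen")`). Subcommands:
`simulate`, `enrich`, `associate`, `survive`, `run`; each takes `--config`
(flat JSON mirroring `pipeline_config()`), `--seed`, `--out-dir`,
`--verbose`. Outputs are single-header TSVs (`enrichment.tsv`,
`histogram.tsv`, `diff_scores.tsv`, `km_<group>.tsv`) plus
`survival_report.json` and a `manifest.json`; reruns with the same inputs are
byte-identical. Exit codes: 0 ok, 2 data error, 3 configuration error.

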