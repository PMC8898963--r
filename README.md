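# m6apattern

Tumor cohorts differ in how heavily their transcriptomes are marked by
N6-methyladenosine (m6A), and the regulator proteins that write, erase and
read this modification are linked to immune infiltration, stemness and
prognosis. `m6apattern` implements the full analysis used to study such
modification patterns in bulk expression cohorts, for computational
biologists who want the machinery as tested, reusable functions rather
than a one-off script pile:

* **resampling consensus clustering** of samples on an m6A-regulator panel,
  with CDF/delta-area selection of the number of clusters;
* **ssGSEA** (integrated running-sum statistic) for tumor-microenvironment
  signature quantification, with the 0-floor normalization and
  cluster-comparison tests;
* **dual-method differential expression** (variance-shrunk t + Wilcoxon,
  both BH-adjusted) with DEGs called by the two-caller intersection, and
  cross-cohort signature intersection;
* the **m6Ascore**: univariate-Cox prognostic filtering of the signature,
  correlation PCA, and the standardized per-sample PC1 + PC2 projection sum

      m6Ascore_s = [ Σ_g (PC1_g + PC2_g) − X̄ ] / SD,

  oriented so higher score means higher hazard, with median high/low
  stratification;
* **survival analysis** (Kaplan–Meier with Greenwood errors, log-rank,
  Efron/Breslow Cox fits, forest tables, uni→multivariate carry-over);
* a simplified **weighted co-expression module** stage (soft threshold,
  topological overlap, eigengenes, module merging at 0.75, gene
  significance / module membership, hub genes);
* a **synthetic-cohort generator** with known ground truth (two latent
  modification patterns, immune/stemness gene programs, pattern-dependent
  exponential survival) used for calibration and recovery testing;
* a **pipeline orchestrator** (`run_pipeline()`) chaining all stages from a
  single config, writing every intermediate table plus a replayable JSON
  manifest.

## Worked example

```r
library(m6apattern)

# a synthetic cohort: 300 samples, 21 regulators, two 40-gene programs,
# pattern shift delta = 3, survival log-hazard link beta = 0.7
ch <- generate_cohort(n_samples = 300, n_genes = 300, n_regulators = 21,
                      delta = 3, program_size = 40, noise_sd = 1,
                      beta_surv = 0.7, seed = 1)
sv <- generate_survival(ch$truth, baseline_hazard = 0.1, censor_rate = 0.3,
                        seed = 2)
al <- align_samples(ch$expr, sv)

# consensus clustering on the regulator panel, k = 2..5
cons <- consensus_sweep(al$expr, ch$truth$regulator_genes, ks = 2:5,
                        n_resamples = 200, seed = 3)
(tab <- cdf_and_delta(cons))
#>   k       auc delta_area
#> 1 2 0.5041639 0.50416388
#> 2 3 0.5116230 0.01479496
#> 3 4 0.5189489 0.01431909
#> 4 5 0.5273753 0.01623726
select_k(tab)
#> [1] 2

# DEGs between the clusters, prognostic filter, score model
de   <- de_test(al$expr, cons[[1]]$assignment)
degs <- call_degs(de, alpha = 0.05, lfc = 1)      # 101 genes here
prog <- prognostic_filter(degs, al$expr, al$surv) # 100 survive Cox p < 0.05
model <- sign_orient(fit_score_model(al$expr, as.character(prog)), al$surv)
scores <- apply_score(model, al$expr)

# high vs low m6Ascore: survival separation
g <- group_assignment(scores$sample_id, scores$group)
logrank(al$surv, g)
#> $chi2 [1] 14.79784   $df [1] 1   $p [1] 0.0001196723
cox_fit(transform(al$surv, m6ascore = scores$score), "m6ascore")$table
#>       term      beta       HR         se        z            p   ci_low  ci_high
#> 1 m6ascore 0.2431801 1.275298 0.07055362 3.446742 0.0005673897 1.110594 1.464429
```

The delta-area table says adding a third cluster gains under 2% of
consensus-CDF area, so two modification patterns suffice; the clusters
recover the planted pattern exactly (adjusted Rand index 1.0 on this
seed). The score built from the cluster contrast separates survival: the
high-score group dies faster (log-rank p ≈ 1.2e-4, hazard ratio ≈ 1.28 per
score SD).

The numbered drivers under `analysis/` run the same workflow end to end on
two simulated cohorts (simulate → consensus → ssGSEA → DEG signature →
m6Ascore/survival → co-expression modules), writing tables and figures
under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_consensus_patterns.R
# ... through analysis/06_coexpr_modules.R
```

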