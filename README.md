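# immunorecov

Tools for analysing immune recovery in HIV-infected patients who start
antiretroviral therapy (ART) severely lymphopenic (< 200 CD4+ T cells/µL).
In this population a substantial fraction never regain normal CD4 counts
despite full viral suppression — the *poor immunological responders* (PIR),
as opposed to *adequate immunological responders* (AIR). Identifying PIR
early matters clinically: they carry higher morbidity and mortality and are
the natural candidates for closer follow-up or thymus-boosting therapies.

The package implements, as a reusable and tested pipeline, the statistical
workflow of a longitudinal cohort study of this question:

1. **Trajectory clustering** (`cluster_cohort()`): patients are split into
   two groups from their CD4 trajectories over months 0–36 by the 3-step
   longitudinal clustering procedure — 24 summary measures per trajectory,
   PCA factor selection (eigenvalue > 1, one representative measure per
   factor), seeded k-means — with clusters labelled AIR/PIR a posteriori by
   whether members crossed 500 cells/µL.
2. **Recovery kinetics** (`fit_recovery_nlme()`): nonlinear mixed-effects
   fits of the asymptotic recovery model

   *X*(*t*) = *A* + *B* [1 − exp(−*t*/τ)]

   for CD4 counts (fixed effects: shared *A*, group-wise *B* and τ; random
   effects on *A*, *B*) and the CD4/CD8 ratio (shared τ; random *A*, *B*,
   τ). *A* is the level at ART start, *A* + *B* the long-run plateau and τ
   the recovery timescale in months. When the random-effect set allows it
   the fit maximizes the exact marginal likelihood by profiling τ over an
   inner linear mixed-effects step.
3. **Comparison statistics** (`route_test()`, `independent_t()`,
   `mann_whitney()`, `fisher_exact_2x2()`, `cramers_v()`, …): Shapiro-Wilk
   test routing, pooled-variance t with Cohen's *d*, Mann-Whitney *U* with
   signed *r* = *Z*/√*N*, Fisher exact tests with cross-product odds ratios,
   Bonferroni thresholds, the P25/P75 ± 3·IQR extreme-outlier sensitivity
   protocol, and derived thymic-function features (RTE counts, TREC
   normalisations, sj/β TREC ratio, thymic score).
4. **Outcome prediction** (`univariable_screen()`, `backward_stepwise()`,
   `roc_auc()`, `evaluate_published_model()`, …): logistic models of PIR/AIR
   outcome from baseline–6-month variables — liberal univariable screen
   (p < 0.20), backward stepwise elimination, likelihood-ratio and
   Hosmer-Lemeshow checks, ROC/AUC, and the four published three-predictor
   coefficient models P(PIR) = 1/(1 + e^(a + b·x₁ + c·x₂ + d·x₃)).

Because the study's patient-level data are not publicly deposited, the
package ships a seeded synthetic-cohort generator (`generate_cohort()`)
reproducing the study design: the 14-visit schedule {0, 2, …, 60} months,
group sizes 14 (AIR-like) and 19 (PIR-like), CD4 and CD4/CD8 trajectories
drawn from the published group kinetics with patient-level random effects,
baseline covariates matching the published group summaries, and visit-level
missingness. The full pipeline (`run_pipeline()`) runs end-to-end on such
cohorts, deterministically for a fixed seed.

## Worked example

```r
library(immunorecov)

co <- generate_cohort(cohort_config(), seed = 1)
co
#> Synthetic ART cohort: 33 patients (AIR n=14, PIR n=19), 1770 visit records
#>   schedule (months): 0 2 6 12 16 20 24 28 32 36 42 48 54 60
#>   analytes: cd4_cd8_ratio, cd4_count, cd8_count, dj_trec_per1e5, rte_pct, sj_trec_per1e5

labels <- cluster_cohort(co, seed = 1)
attr(labels, "cluster_summary")
#>   cluster  n n_crossed_500 label
#> 1       1 21             9   AIR
#> 2       2 12             2   PIR

truth <- data.frame(patient_id = co$covariates$patient_id,
                    label = co$covariates$true_group)
fit <- fit_recovery_nlme(co, labels = truth, analyte = "cd4_count")
fit
#> Exponential recovery fit (cd4_count, profile-ml; 33 patients)
#>   AIR: X(t) = 115.6 + 495.5 [1 - exp(-t/19.95)]  plateau 611.1
#>   PIR: X(t) = 115.6 + 285.1 [1 - exp(-t/24.96)]  plateau 400.7
#>   residual SD 55.55; logLik -2447; converged: TRUE
```

The fitted plateaus (`asymptote(fit)` → AIR 611.1, PIR 400.7 cells/µL) are
the model's long-run mean CD4 counts per group; on this synthetic cohort
they recover the generating plateaus (629.1 and 414.6) to within sampling
error of a 33-patient study. With default noise the unsupervised clusters
only partially recover the latent groups (here 21/12 against the true
14/19) — the two generated trajectory families overlap substantially at the
study's dispersion; the comparison above therefore uses the known synthetic
labels.

Printed-value checks, independent of any simulation:

```r
d <- cohens_d_pooled(38.1, 8.6, 14, 45.3, 10.8, 19)  # published age summaries
round(d, 2); magnitude_label("cohens_d", d)
#> 0.72  "medium"

evaluate_published_model("model3",
  data.frame(age_years = 45, log10_vl_baseline = 5.0, cd4_count_6mo = 200))
#>      p_pir         call
#> 1 0.904909 probably PIR
```

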