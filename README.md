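# psamix

Stratification of psoriatic-arthritis (PsA) cohorts into latent clinical
phenotypes, for biostatisticians and rheumatology researchers analysing
trial or registry baseline data.

PsA presents with highly variable combinations of joint, entheseal,
dactylitic and skin involvement. `psamix` identifies homogeneous patient
subgroups from baseline demographics and clinical characteristics alone,
then summarises treatment response within each subgroup. At its core is a
finite mixture model for mixed-type data,

    h(y | φ) = Σₖ πₖ fₖ(y | θₖ),   k = 1..K,

with component densities fₖ taken as conditionally independent within a
component — diagonal Gaussian for continuous features, multinomial for
categorical ones — fitted by EM with multi-style random restarts. The
number of phenotypes K is chosen by a BIC elbow rule over a grid (default
2–10, lower BIC better), and the stability of the resulting partition is
assessed with Monti consensus subsampling: C(i,j) = Σₜ Mₜ(i,j) / Σₜ Iₜ(i,j),
the fraction of co-clustering among co-sampled patient pairs across T
resampled refits.

Around the model the package provides the full analysis pipeline:

* **Cohort ingestion** against a declared feature schema, with the
  pre-modelling screens (drop features >20% missing, drop the later of any
  feature pair with |r| ≥ 0.95, drop incomplete patients) and the age/race
  recodings.
* **Phenotype profiling**: table-one style per-cluster statistics
  (optionally conditional on positivity indicators) and cluster-ordered
  heatmap layouts.
* **Responder endpoints**: MDA (5-of-7), DAPSA low disease activity
  (≤ 14), TJC/SJC ≥50% improvement, ACR50, and MCIDs for HAQ-DI (≥0.35
  decrease), pain (≥10 mm decrease) and FACIT-F (≥4 increase), aggregated
  by phenotype × week as observed (Wilson 95% CI) or under non-responder
  imputation with multiple imputation (NRI-MI, Rubin's rules).
* **A synthetic cohort generator** reproducing the five-phenotype latent
  structure of a biologic-naive PsA trial population (mixing proportions
  0.403/0.208/0.140/0.138/0.111 and per-phenotype feature distributions),
  with optional planted missingness and collinear duplicates, plus a
  longitudinal visit simulator with reason-coded missingness — so the
  entire pipeline is testable without patient-level trial data.

## Worked example

Generate a trial-sized cohort with planted data problems, screen it, select
K, and profile the phenotypes:

```r
library(psamix)

gb <- generate_baseline(1196, default_generator_config(missingness = TRUE),
                        seed = 1)
ex <- apply_feature_exclusions(gb$cohort)
ex$report
#> Exclusion report: 4 feature(s) dropped, 0 patient(s) dropped
#>   - facit_f | missing_gt_threshold
#>   - tjc_dup | collinear_with:tjc
#>   - sjc_dup | collinear_with:sjc
#>   - pain_dup | collinear_with:pain

dp <- drop_incomplete_patients(ex$cohort)
n_patients(dp$cohort) / 1196
#> retained 1114 of 1196 patients (93.1%)

enc <- encode_features(dp$cohort)
ks <- select_k(enc, grid = 2:10, n_restarts = 3, seed = 1)
ks
#> BIC grid search (tau = 0.1)
#>   K     BIC
#>   2 54661.9
#>   3 54117.3
#>   4 53885.9
#>   5 53783.2
#>   6 53955.1
#>   7 54123.7
#>   8 54279.2
#>   9 54459.1
#>  10 54633.0
#> selected K = 5
```

The BIC falls steeply to K = 5 and rises beyond it: five phenotypes. Hard
assignments and per-phenotype profiles:

```r
labels <- assign_clusters(ks$fit)
cluster_profile(dp$cohort, labels)
#> Phenotype profile: 5 clusters
#>   cluster 1: n = 229 (20.6%)
#>   cluster 2: n = 136 (12.2%)
#>   cluster 3: n = 148 (13.3%)
#>   cluster 4: n = 478 (42.9%)
#>   cluster 5: n = 123 (11.0%)
#> continuous features, mean (SD):
#>   tjc   21.0 (6.5)  26.5 (7.7)  45.9 (9.9)  10.0 (3.5)  24.2 (9.0)
#>   sjc   10.1 (3.7)  15.1 (5.4)  22.5 (10.7)  7.5 (2.3)  16.3 (6.6)
#>   pain  56.8 (20.6) 60.1 (21.9) 69.0 (20.7) 53.2 (23.6) 54.0 (26.8)
```

Cluster 4 is the large moderate-activity group (42.9% of patients, mean TJC
10.0), cluster 3 the small very-high-activity group (TJC 45.9) — the
recovered sizes and joint-count profiles track the generator's configured
phenotypes. Stability by consensus subsampling:

```r
cons <- consensus_matrix(enc, K = 5, T = 30, a = 0.8, seed = 2)
stability_summary(cons, labels)
#> Cluster stability (mean consensus):
#>   cluster 1: within = 0.943
#>   cluster 2: within = 0.959
#>   cluster 3: within = 0.989
#>   cluster 4: within = 0.988
#>   cluster 5: within = 0.980
#>   between clusters: 0.007
```

Within-cluster consensus near 1 and between-cluster consensus near 0: the
partition is stable under resampling. Responder analysis continues with
`generate_visits()` (or a real visit CSV), `endpoint_flags()`,
`responder_rates()` and `nri_mi_rates()`; see the vignette
(`vignettes/psa-phenotyping.Rmd`) for the models, assumptions and tuning
parameters.

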