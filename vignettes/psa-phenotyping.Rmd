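---
title: "Latent clinical phenotypes in psoriatic arthritis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent clinical phenotypes in psoriatic arthritis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Psoriatic arthritis (PsA) is clinically heterogeneous: joint, entheseal,
dactylitic and skin involvement combine in patterns that differ widely
between patients, and those patterns plausibly moderate treatment response.
`psamix` stratifies a PsA cohort into latent clinical *phenotypes* from
baseline data alone — no outcome is used in the clustering — and then asks
how responder endpoints evolve within each phenotype.

## The mixture model

The baseline feature vector $y$ of a patient is modelled as a draw from a
finite mixture with $K$ components,

$$h(y \mid \phi) = \sum_{k=1}^{K} \pi_k\, f_k(y \mid \theta_k),$$

where $\pi_k$ is the prior probability of phenotype $k$ and $f_k$ its
component density. No covariates enter the model: the mixture is fit to the
joint baseline distribution itself.

The component density family is the latent-class convention for mixed-type
data: **conditional independence within a component**, with a diagonal
Gaussian for each continuous feature and an independent
multinomial/Bernoulli for each categorical or binary feature. This choice
makes the likelihood tractable, the BIC parameter count well defined
($p = (K-1) + K\,[2\,p_{\mathrm{cont}} + \sum_j (L_j - 1)]$), and matches
how the resulting phenotypes are described clinically — by per-phenotype
feature frequencies and means. Its cost is that within-phenotype
correlation (e.g. between tender and swollen counts) is attributed to the
latent class only.

Fitting is by EM. The E step computes posterior responsibilities
$r_{ik} \propto \pi_k f_k(y_i \mid \theta_k)$ with log-sum-exp throughout;
the M step updates weights, means, variances (floored at $10^{-4}$ times
the pooled feature variance) and smoothed category probabilities (Laplace
$\alpha = 0.5$; $\alpha = 0$ recovers the exact closed form at $K = 1$).
A component whose total responsibility collapses below $10^{-6} n$ is
re-seeded at the observation with the weakest best membership.

### Initialisation and restarts

The log-likelihood surface of a mixed-type mixture is multimodal, and the
modes are separated along *different feature types*: a k-means
initialisation on continuous features alone systematically misses
partitions that differ mainly in categorical profile (in this domain,
hand-dominant versus feet-dominant joint involvement). Each call to
`fit_em()` therefore cycles four initialisation styles across its restarts:

* k-means on the standardised continuous features plus one-hot categorical
  indicators ("mixed");
* k-means on the one-hot indicators alone ("cat");
* k-means on the mixed design with random exponential column weights, so
  each such restart emphasises a different random feature subset
  ("subspace");
* a uniform random hard partition.

Hard labels are blended with Dirichlet noise (85/15) before the first M
step. Ten restarts are the default; the best final log-likelihood wins.
Convergence is declared at a relative log-likelihood change below
$10^{-6}$ (at most 500 iterations). We deliberately do *not* run EM to a
much tighter tolerance: on this family the likelihood is extremely flat in
the mixing weights, and very long runs can drift toward spiky
small-variance components that a variance floor only partially contains.

### Choosing the number of phenotypes

`select_k()` fits every $K$ on a grid (default 2–10) and applies an elbow
rule to the BIC sequence: the selected $K$ is the smallest grid value whose
next BIC decrease falls below $\tau = 0.10$ times the first decrease on the
grid, with an interior global BIC minimiser taking precedence when it is
smaller. If the BIC never decreases the grid minimum is returned with a
`no_elbow` flag. All decreases and ratios are exposed so the choice can be
audited or overridden — the rule operationalises a judgement call
("the decrease of BIC is minimal beyond $K$"), it does not replace it.

## Consensus stability

Stability of a $K$-cluster solution is assessed with Monti consensus
subsampling: $T = 200$ iterations, each drawing 80% of patients without
replacement, refitting the mixture (3 restarts per iteration for
tractability; seeds derived from the master seed), and accumulating

$$C(i,j) = \frac{\sum_t M_t(i,j)}{\sum_t I_t(i,j)},$$

the fraction of co-clustering among co-sampled pairs. Pairs never
co-sampled are *undefined* (`NaN`), never zero, and are excluded from the
within/between-cluster summary means. Sampling without replacement is the
classical choice; with-replacement duplicates would break the
pair-indicator logic (a `replace` flag exposes the alternative, with
duplicates collapsed).

## Responder endpoints

Per patient-visit the package computes: DAPSA ($TJC_{68} + SJC_{66} +
\mathrm{CRP}\,[\mathrm{mg/dL}] + \mathrm{pain}\,[\mathrm{cm}] +
\mathrm{patient\ global}\,[\mathrm{cm}]$) with low disease activity at
$\le 14$; minimal disease activity as the standard 5-of-7 rule
($TJC \le 1$, $SJC \le 1$, $BSA \le 3\%$, pain $\le 15$ mm, patient global
$\le 20$ mm, HAQ-DI $\le 0.5$, tender entheseal points $\le 1$); ACR50;
$\ge 50\%$ joint-count improvements; and MCIDs (HAQ-DI decrease
$\ge 0.35$, pain decrease $\ge 10$ mm, FACIT-F increase $\ge 4$). All
cut-offs are inclusive. A zero baseline count is a responder for a
percent-improvement endpoint only if the visit value is also zero. MCID
denominators are gated on baseline eligibility (HAQ-DI $\ge 0.35$, pain
$\ge 10$ mm). CRP is stored in mg/L and converted at computation.

Rates are aggregated per cluster × week two ways. *As observed* (AO) uses
the non-missing denominator with a Wilson 95% interval (chosen for
small-cell robustness). *NRI-MI* counts missingness for reasons other than
pandemic/geopolitical interruption as non-response, imputes
interruption-related missingness $m = 20$ times from the cluster-week AO
rate, and pools by Rubin's rules (total variance = within +
$(1 + 1/m)\times$ between) with a normal-approximation interval. With no
missingness the NRI-MI rate equals the AO rate exactly; the imputation
model is the simplest one consistent with conditioning on observed data,
and is a documented stand-in for an unpublished analysis plan.

## The synthetic cohort generator

No patient-level data accompany the analysis this package operationalises,
so the generator is a first-class module: it encodes the *study
conditions* under which every downstream stage is exercised.

Five phenotypes with mixing proportions (0.403, 0.208, 0.140, 0.138,
0.111). Continuous features (TJC68, SJC66, pain VAS) use the published
per-phenotype means and SDs; counts are drawn from floor-truncated normals
(inverse-CDF, so no boundary point mass) and rounded to integers; pain is
left Gaussian. Categorical features carry the published per-phenotype level
frequencies: sex, age band, BMI band, dactylitis presence, enthesitis band,
body-surface-area band, CRP band, disease-duration band and psoriatic
spondylitis. Seven per-location involvement indicators (tender/swollen
hands and feet, swollen large joints, dactylitis hands/feet) complete the
schema: the source analysis used per-location joint information, and
without it the hand-dominant and feet-dominant phenotypes are statistically
indistinguishable — the five-component structure is then not recoverable by
BIC at the trial sample size. Their contrasts were fixed once, from the
phenotype descriptions, such that `select_k` recovers $K = 5$ with a clean
interior BIC minimum at $n = 1119$.

Two generator details matter for interpretation. First, features are
conditionally independent within a phenotype — the generator deliberately
matches the family the model fits, so parameter recovery is well-posed;
passing recovery tests therefore demonstrates correctness of the machinery,
*not* robustness to the within-cluster correlation real cohorts certainly
have. Second, truncation: an early design clamped draws to physiologic
ranges, which puts point masses on the boundaries and measurably biases the
Gaussian-mixture MLE; the final design truncates only where the spec of the
cohort demands it (count floors at zero, where the affected mass is
negligible).

With `missingness = TRUE` the generator plants the screening structure the
ingestion module removes: one low-information feature that is 25% missing,
three exact duplicate (perfectly collinear) columns, and sporadic
missingness at 0.00415 per core feature so that ≈6.4% of patients are
incomplete on the final feature set — mirroring a 1196 → 1119 retention.

The longitudinal module simulates visits at weeks 12, 24, 52, 100 and 196.
Each phenotype has a mean improvement fraction per clinical domain rising
log-linearly in week from its week-12 to its week-196 value; patient-visit
draws are Beta with concentration 5. The week-196 means (0.74, 0.80, 0.83,
0.81, 0.82) were calibrated once so that per-phenotype week-196 MDA rates
bracket roughly 43–61%, with the mildest-baseline phenotype highest — the
qualitative ordering the clinical setting implies. Visit missingness
carries a reason (`covid_geo`, `other`, absorbing `dropout`) at 3% per
visit each by default.

## Ingestion rules

Screening precedes modelling, in this order: features with a missing
fraction above 0.20 (computed over all loaded rows) are dropped; then among
numeric-coded feature pairs with $|r| \ge 0.95$ on complete cases the
later feature in schema order is dropped (deterministic and conservative —
the published analysis cites a collinearity screen without printing its
criterion); then patients missing any remaining feature are removed, so EM
never sees missing values. Age is banded $\le 45$, 45–65, $\ge 65$ with 45
assigned to the first band and 65 to the second, making the bands a
partition; race collapses to White, Black/African American, Asian,
multiple/others.

## Problem sizes and numerical choices

The test-suite experiments run at the sizes the analysis itself uses:
K-selection at $n = 1119$ over the 2–10 grid (3 restarts per $K$ across ten
replicate seeds), parameter recovery at $n = 5000$ (10 restarts), consensus
sanity at $T = 50$ on two-blob data, and law-of-large-numbers generator
checks at $n = 10^5$. Tolerances follow the estimators' sampling error:
weights to ±0.03, component means to ±1 tender joint (about 2.7 standard
errors at the realised component size, so occasional dataset-level
excursions are expected and are visible in the BIC diagnostics rather than
silently absorbed).

Ties in hard assignment break toward the lower component index; patient
ordering for heatmaps is by cluster, then descending own-cluster
responsibility; feature ordering follows the clinical group order
tender-joint, swollen-joint, psoriasis, dactylitis, enthesitis, other,
demographic.

## Limitations

* Component labels are arbitrary; clinical names for phenotypes are
  attached by the analyst, not inferred.
* The conditional-independence family understates within-phenotype
  correlation; on real data the BIC grid may prefer more components than a
  clinically parsimonious reading would.
* The NRI-MI imputation model and the MDA skin criterion (BSA rather than
  PASI) are documented stand-ins where the source analysis plan is not
  public.
* Safety endpoints, placebo comparisons and radiographic outcomes are out
  of scope.

## A minimal end-to-end run

```{r, eval = FALSE}
library(psamix)

gb  <- generate_baseline(1119, default_generator_config(missingness = TRUE),
                         seed = 1)
ex  <- apply_feature_exclusions(gb$cohort)
dp  <- drop_incomplete_patients(ex$cohort)
enc <- encode_features(dp$cohort)

ks  <- select_k(enc, grid = 2:10, seed = 1)
fit <- ks$fit
labels <- assign_clusters(fit)

cons <- consensus_matrix(enc, K = ks$selected_K, T = 200, a = 0.8, seed = 2)
stability_summary(cons, labels)

prof <- cluster_profile(dp$cohort, labels)

vis <- generate_visits(dp$cohort, gb$truth[match(dp$cohort$data$patient_id,
                                                 gb$truth$patient_id), ],
                       seed = 3)
fl  <- endpoint_flags(vis)
responder_rates(fl, labels)
nri_mi_rates(fl, labels, m = 20, seed = 4)
```
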