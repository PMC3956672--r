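---
title: "Methods: scoring, cut-point stability and survival modeling in ihcsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, cut-point stability and survival modeling in ihcsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcsurv)
```

# The problem

Tumor-marker prognostic studies in early breast cancer typically score
protein expression semiquantitatively on tissue microarrays, dichotomize
each marker at a data-derived cut-off, and relate the resulting binary
variables to disease-free survival (DFS) and overall survival (OS).
Two methodological hazards dominate this design: *minimum-p cut-off
selection bias* (scanning many candidate cut-offs inflates false
positives) and *cut-off instability* (a cut-off tuned on one sample need
not transfer). `ihcsurv` implements the full chain — scoring, subtype
classification, stability-validated cut-point selection,
combined-biomarker survival analysis and multiple correspondence
analysis (MCA) — with a synthetic-cohort generator so that every stage
can be tested against known generating truth.

# Scoring and classification

The immunoreactive score is IRS = SI × PP with staining intensity SI ∈
{0,1,2,3} and percent-positive band PP ∈ {0,1,2,3}; its reachable values
are {0,1,2,3,4,6,9}. The band boundaries are: 0 ↔ exactly 0%, 1 ↔
strictly between 0 and 10%, 2 ↔ [10, 50), 3 ↔ [50, 100]. The published
band notation ("0 = 0%, 1 = 0–9%") overlaps at zero; we resolve it so
that 0% always maps to band 0, which is the only reading under which the
bands partition [0, 100]. Percentages are accepted as reals even though
pathologists usually record integers.

The H-score is 1·weak% + 2·moderate% + 3·strong% ∈ [0, 300]; the three
band percentages may sum to less than 100 (unstained cells) but never
more.

Positivity rules: ER/PgR positive at ≥1% nuclear staining; Ki67 high at
≥14%; EGFR positive at ≥1% membrane staining; CK5 positive on any
staining; HER2 positive if IHC 3+, FISH ratio >2.2 or gene copies >6 —
and *missing*, not negative, when all three fields are absent. All
thresholds live in `ihc_thresholds` and can be overridden per run.

Subtypes: hormone-receptor (HR) positivity is ER-positive and/or
PgR-positive. HR+/HER2+ → luminal-HER2 (Ki67 is deliberately not
consulted, following the class definitions); HR+/HER2− → luminal A
(Ki67 < 14%) or luminal B (≥14%); HR−/HER2+ → HER2-enriched; HR−/HER2−
→ triple-negative regardless of EGFR/CK5 (the basal-like sub-distinction
is recorded via the statuses but not used as a class). Patients whose
statuses cannot decide a class are explicitly *unclassifiable* and
counted in the attrition report, never silently dropped. HR-negativity
requires both ER and PgR observed negative; a single missing receptor
with the other negative leaves the patient unclassifiable rather than
guessing.

# Dichotomization and cut-point stability

"High" expression is *at or above* the cut-off. Quantile conventions are
chosen for coarse ordinal scores: medians use the even-n averaging
convention, while quartile and decile *candidates* use lower
interpolation (quantile type 1), so candidate cut-offs are attainable
score values — an interpolated cut-off of, say, 2.37 is meaningless for
an IRS under the ≥ rule.

For over-dispersed scores (the H-score), `decile_scan()` dichotomizes at
each of the nine deciles and records the two-group log-rank p per
endpoint. The scan is descriptive: the minimum p over nine correlated
looks is not a nominal 0.05 test, and the package does not auto-select
the argmin. (A property test confirms the anticonservatism: under the
null the minimum p falls below 0.05 far more often than 5%.) No
Altman-style minimum-p correction is applied, matching the procedure the
package reproduces; the scan output flags the caveat instead.

The internal cross-validation splits the cohort into training and
validation halves 100 times, stratified so that nodal status, surgery
type, immunophenotype subtype and taxane treatment are equally assigned:
within every cell of the strata cross-classification the two sets differ
by at most one patient (cells of size one are assigned at random). Each
replication computes the training median (or requested quartile),
dichotomizes both halves at it, and fits a univariate Cox model per
half. The report carries per-replication hazard ratios with 95% CIs,
mean and median training-minus-validation HR differences — on both the
HR and log-HR scales, since the published summaries do not specify the
scale — the percentage of validation CIs crossing HR = 1, and the final
cut-off: the median of the 100 training medians. Per-replication models
are univariate by default (the simplest reading of the source
procedure); covariate adjustment is available. Non-convergent fits are
recorded as missing and counted, never imputed. One master seed
deterministically derives per-replication seeds, so a report is
reproducible bit for bit.

`validate_candidate()` exposes the acceptance evidence with a
documented, configurable default rule: a candidate is *independently
prognostic* if fewer than 80% of validation CIs cross 1; otherwise it is
still a *candidate prognostic marker* if at least 75% of the HR point
estimates fall on one side of 1 (the "IQR limit below 1" pattern);
otherwise it is *not independently prognostic*. The exact rule behind
the original study's rejections is unstated, which is why the thresholds
are parameters rather than constants.

# Survival engine

Kaplan–Meier estimation, the unweighted log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package behind
thin module functions; the test suite verifies them against independent
brute-force oracles (explicit risk-table enumeration for KM/Greenwood
and log-rank; a one-dimensional maximization of a hand-written Efron
partial likelihood for Cox) on every fixture of 20 patients or fewer.
Efron tie handling is the default — the least biased common choice with
tied months — with Breslow available for cross-checking against other
software. The "4-year rate" is the product-limit estimate at exactly
48.0 months. Univariate significance defaults to 5%, multivariate
retention to 15%, both configurable.

The multivariate procedure is backward elimination: start from the
combined biomarker variable plus the clinical candidates (surgery,
nodes, size, histology, radiotherapy), repeatedly drop the least
significant candidate until all remaining ones have Wald p < 0.15; the
combined variable is always retained. The selection mechanism behind the
published adjusted models is not named in the source; backward
elimination is the choice most consistent with differently-retained
covariate subsets per endpoint, and it is flagged as a package decision.
The two combined pathway variables (IGF1Rα/IGF2R and IGF1Rα/EGFR) are
refused in one model: they are nearly collinear by construction, and the
original analysis also reports two separate models for that reason.
Interaction tests add a product term to the main-effects model and
report its Wald p.

# Combined clusters

Cluster membership is evaluated within a subtype filter (luminal A+B by
default): a member satisfies both marker conditions (e.g. IGF1Rα IRS at
or above its cut-off *and* IGF2R IRS below its cut-off); every other
patient inside the filter is the comparator ("the rest"); patients
outside the filter or missing a constituent marker are unassessable and
excluded from all denominators, including 4-year rates. The sensitivity
analysis widens the filter by luminal-HER2 and tests the
cluster-by-HER2-group interaction. The four control combinations
(low/low, high/high, high/EGFR-positive, low/EGFR-negative) run through
the identical machinery; together with the primary clusters they tile
all four quadrants of each marker-pair dichotomy, which the tests assert
by enumeration.

# Multiple correspondence analysis

`mca_fit()` performs correspondence analysis of the complete-case
indicator matrix: chi-square metric, SVD, principal-normalization
coordinates. With complete data the total inertia is exactly J/Q − 1 (J
total categories, Q variables), which the tests assert to 1e−12; the
eigenvalues are verified against an independent eigendecomposition of
the centered Burt matrix to 1e−10. Raw inertia percentages are reported
by default because the headline percentages in this literature are raw;
the Benzécri correction is available behind a flag for sensitivity.
Markers enter dichotomized, matching the binary variables used
everywhere else. Rows with missing values are dropped and counted. A
marker whose cut-off is degenerate (e.g. a mostly-absent marker whose
median is the minimum score, so "≥ median" holds for everyone) is
dropped from the MCA table with a warning rather than crashing the
decomposition. `inverse_association_check()` summarizes whether two
markers' elevated categories point the same way or opposite ways as a
signed cosine over chosen dimensions, with small magnitudes flagged
inconclusive.

# The synthetic cohort: what it emulates

The generator's defaults are the stated conditions of the cohort the
package was built around: n = 1021 node-positive patients; subtype mix
252/394/137/109/129 (24.7/38.6/13.4/10.7/12.6%); covariate frequencies
from the published characteristics table (53.6% post-menopausal, 60.6%
with ≥4 positive nodes, 68.6% mastectomy, 69.2% tumors >2 cm, 50.4%
grade III); administrative censoring at the maximum follow-up of 166.7
months. Values the source does not state were fixed once: the taxane
frequency (0.75 — one parent trial gave taxanes to all patients, the
other to half) and the MCAR missingness rate per IGF marker (0.05,
consistent with the per-marker attrition visible in the REMARK flow
diagram).

Marker scores arise from a latent Gaussian copula: correlated standard
normals are transformed to uniforms and thresholded at the cumulative
per-subtype marginals, so marginal category frequencies are matched
exactly by construction while a single correlation matrix controls the
association structure. The source documents only marginal frequencies
and qualitative associations, so the default correlation encodes the
qualitative pattern: positive coupling within the IGF1R axis
(α/β/IGFBP2), a negative association of IGF2R with each of them (the
receptor's "buffer" role), and a weak negative IGF1Rα–EGFR coupling.
The IRS is decomposed into an (SI, PP) pair uniformly among its factor
pairs. Default per-subtype marginals reproduce the published pattern:
IGF1Rα at or above the overall median of 2 in over 30% of each luminal
subtype but only 16.5%/18.1% of HER2-enriched/triple-negative; IGF1Rβ
absent in 66.8%; IGF2R present in ~55% and enriched in HR-negative
disease; EGFR positive in 62.2%/35.5%/<10% of triple-negative/
HER2-enriched/luminal tumors.

Event times: a relapse time and a death time are drawn independently
given the covariates, each from its own proportional hazard
(exponential by default, Weibull optional); DFS ends at whichever comes
first and OS at death, so DFS ≤ OS always. An earlier design coupled a
post-relapse survival time to the relapse time; it was abandoned because
the resulting marginal OS hazard is time-varying (accelerated-failure
rather than proportional), which biases marginal Cox estimates away from
the generating coefficient — the direct-death construction keeps *both*
endpoints exactly proportional-hazards, which the parameter-recovery
properties require. The generating linear predictor (defaults: ≥4 nodes
log(1/0.54), mastectomy log(1/0.59), tumor >2 cm log(1/0.73), true
IGF1Rα-high/IGF2R-low luminal A+B cluster log(0.55) — the published
adjusted OS effect) multiplies both hazards.

Baseline rates were calibrated once against the published outcome
summary under the default covariate mix and then frozen: relapse
0.0013/month and death 0.0009/month reproduce the 4-year DFS of 76.1%
(simulated 76.8%), the 4-year OS of 89.5% (simulated 89.6%) and the
relapse fraction of 36.2% (simulated 38.6%). Censoring is
administrative at 166.7 months plus uniform dropout with probability
0.79, which reproduces the median follow-up of 105.4 months (simulated
105.1); the high dropout share stands in for the staggered accrual of
the parent trials, which the censoring model deliberately does not
simulate. Two limitations are accepted rather than hidden: the
cumulative death fraction is under-matched (~20% vs 26.4%) because a
constant death hazard cannot also match the 4-year OS under this
censoring — real mortality accelerates after relapse, which is exactly
the structure the proportional-hazards requirement excludes; and
subtype is generated independently of the clinical covariates, so the
covariate-by-subtype associations of the source's Table are not
reproduced. A green test therefore establishes correctness of the
*procedures* under a proportional-hazards world with copula-ordinal
markers — not distributional fidelity of any real cohort.

# Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes one integer seed;
  per-replication seeds are derived deterministically. Identical seed
  and configuration give byte-identical cohort files and pipeline
  summaries.
* Subtype proportion vectors are renormalized when they sum to within
  0.01 of 1 (rounded percentages), and rejected otherwise; the latent
  correlation must be symmetric, unit-diagonal and positive
  semidefinite (eigenvalue tolerance −1e−8).
* Constant scores: quartile candidates collapse and are flagged
  degenerate; every decile-scan p is missing; a degenerate dichotomy in
  a Cox fit is a refused "no contrast" error, recorded as missing inside
  the cross-validation loop.
* A decile cut that empties one group records a missing p rather than
  failing the scan; an empty arm in a cluster analysis yields a partial
  result with an explicit `insufficient` flag (fewer than 10 events also
  triggers it).
* Cox refusals: constant covariates and models with fewer events than
  covariates are refused outright; non-convergence (non-finite or
  runaway coefficients) is reported via `converged = FALSE`. Inside
  backward elimination, an inestimable candidate (empty factor level
  after complete-case filtering) is eliminated first.
* MCA requires at least two observed categories per variable; a
  declared-but-never-observed category is dropped with a warning.

# Known limitations

The pipeline does not model non-proportional hazards, informative
censoring, competing risks or time-varying covariates; proportionality
is assumed, not diagnosed. The simulator does not produce image-level
staining, inter-observer disagreement, or covariate-subtype dependence.
The study sizes of specific published analyses (e.g. the exact member
counts of the combined clusters) are not reproducible without the
original patient-level data; all quantitative checks in the test suite
are therefore analytic identities, in-text arithmetic, oracle
equivalences or parameter-recovery simulations against the generator's
own truth.
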