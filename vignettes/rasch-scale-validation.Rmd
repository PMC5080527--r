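---
title: "Validating dichotomous symptom scales with the Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dichotomous symptom scales with the Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschval)
```

## The measurement model

`raschval` treats a set of k binary symptom indicators as a candidate
measurement instrument for a single latent trait. The dichotomous Rasch
model places persons and items on one interval (logit) scale:

$$\Pr(X_{vi} = 1 \mid \theta_v, \beta_i) =
  \frac{\exp(\theta_v - \beta_i)}{1 + \exp(\theta_v - \beta_i)},$$

with person ability $\theta_v$ and item difficulty $\beta_i$. Two features
make this the natural audit model for symptom checklists. First, the raw
score $r_v = \sum_i x_{vi}$ is sufficient for $\theta_v$, so "count the
symptoms" is a valid scoring rule exactly when the model fits. Second, all
items share one discrimination, so misfit of individual items is
interpretable as a violation (noise, redundancy, multidimensionality) rather
than absorbed into extra parameters.

### Conditional maximum likelihood

`rasch_cml()` estimates difficulties by maximising the likelihood of the
responses conditional on the raw scores. The person parameters cancel,
leaving

$$\log L_c(\beta) = -\sum_i \beta_i s_i - \sum_r n_r \log \gamma_r(\epsilon),$$

where $s_i$ is item i's score among non-extreme persons, $n_r$ the number of
persons with raw score r, and $\gamma_r$ the elementary symmetric function
of order r of the easiness terms $\epsilon_i = e^{-\beta_i}$
(`elementary_symmetric()`). We chose CML over joint maximum likelihood
because it is consistent for fixed test length as the sample grows, which
matches how survey analyses present difficulties as sample-size-stable.
Persons with raw score 0 or k contribute nothing to the conditional
likelihood and are excluded from estimation; items endorsed by none or all
non-extreme persons are reported as inestimable by name.

Numerical choices: the ESF recursion runs in log space (stable for tests up
to ~50 items); Newton–Raphson uses the analytic conditional information
matrix (conditional covariances of item scores given raw score, also from
ESFs), step-halving, a tolerance of 1e−8 on the gradient norm and a cap of
100 iterations. Identification is by $\sum_i \beta_i = 0$, the convention
that spreads easy items below zero and rare symptoms above it. Standard
errors come from the Moore–Penrose inverse of the information matrix, whose
null direction is the common shift absorbed by the constraint.

### Person measures

`ability_wle()` implements Warm's weighted likelihood estimator. The
weighted score equation $r - \sum_i P_i(\theta) + J/(2I) = 0$ is solved once
per observed raw score (sufficiency makes per-person work redundant), with
$I = \sum_i P_iQ_i$ the test information and $J = \sum_i P_iQ_i(1 - 2P_i)$.
We chose WLE over the MLE because the reliability computations need finite
measures and standard errors for zero and perfect scorers; the standard
error is $1/\sqrt{I(\hat\theta)}$.

## The five diagnostics

All thresholds below are `validation_config()` defaults, not constants.

**Dimensionality** (`parallel_analysis()`). Observed eigenvalues come from
the Pearson (phi) correlation matrix of the binary columns. The null
reference is built by independently permuting each column of the observed
data: unlike Normal(0,1) reference data, permutation preserves the item
margins that inflate eigenvalues of dichotomous correlation matrices while
destroying all inter-item structure. A component is retained while its
observed eigenvalue exceeds the 95th percentile of the corresponding null
eigenvalues, stopping at the first failure; adjusted eigenvalues are
reported as observed − (null mean − 1). Phi correlations are the default
because they are always defined for 0/1 data; a tetrachoric alternative
would estimate latent correlations but fails on empty cells.

**Item fit** (`item_infit()`). The infit numerator is the squared-residual
sum $\sum_v (x_{vi} - \hat P_{vi})^2$ at the WLE abilities and CML
difficulties, over non-extreme persons. The textbook denominator
$\sum_v \hat P_{vi}\hat Q_{vi}$ is biased for short tests: because
$\hat\theta_v$ is a function of person v's own responses, the expected
squared residual per cell is smaller than $\hat P\hat Q$ by roughly a factor
$(1 - W_{vi}/I_v)$, centring the statistic near $1 - 1/k$ (≈ 0.91 for
k = 11) instead of 1 — which would make a 0.91–1.09 acceptance band reject
well-fitting items wholesale. We therefore use the exact null expectation of
the numerator given each person's raw score,

$$\sum_v \left[\pi_{r_v i}(1 - \pi_{r_v i}) + (\pi_{r_v i} - \hat P_{vi})^2\right],$$

where $\pi_{ri} = \epsilon_i \gamma^{(i)}_{r-1}/\gamma_r$ is the conditional
endorsement probability given raw score r under the fitted model. This
denominator costs nothing extra (the ESF machinery is already present) and
centres the mean square at 1 for any test length — a property we verify by
simulation in the test suite. The standardised form uses the
Wilson–Hilferty cube-root transformation with the exact conditional variance
of the numerator. The default band 0.91–1.09 flags noisy,
under-discriminating items above and deterministic, redundant items below.

**Local independence** (`residual_correlations()`). Yen's Q3: Pearson
correlations between columns of standardised residuals, tested per pair with
the score-type statistic $\chi^2 = n\,r^2$ on 1 df and Holm-adjusted over
all $k(k-1)/2$ pairs as one family. A pair is flagged only by the
conjunction of magnitude (r > 0.2) and significance (Holm p ≤ 0.05), so
that large samples do not flag trivial correlations nor small samples large
but unstable ones.

**Invariance** (`dif_test()`). Uniform DIF by the Mantel–Haenszel test with
continuity correction, stratifying on the total raw score over all items (a
purification option that uses the rest score is available but off by
default, the simplest defensible reading when no purification protocol is
given). The common odds ratio uses the MH estimator with the
Robins–Breslow–Greenland variance of its log. Non-uniform (crossing) DIF
uses the Breslow–Day homogeneity test with Tarone's correction on
(informative strata − 1) df; strata with a zero margin are dropped as
uninformative. An item is flagged when either test is significant at the
configured level, with no multiplicity adjustment across items —
conservative in the direction of finding problems. Scale-level differential
test functioning is the weighted method-of-moments between-item variance of
the MH log odds ratios,

$$\hat\tau^2 = \frac{\sum w_i^2(\lambda_i - \bar\lambda)^2 - \sum w_i}
  {\sum w_i^2}, \qquad w_i = 1/v_i,$$

deliberately not truncated at zero (small negative values mean less
dispersion than sampling error predicts), banded small/medium/large at
0.07/0.14 with boundaries assigned to the lower band.

**Reliability** (`scale_reliability()`). Cronbach's α with n−1 variances,
and the Person Separation Index
$(\mathrm{var}(\hat\theta) - \overline{se^2})/\mathrm{var}(\hat\theta)$
computed over all persons — WLE makes extreme scorers usable, and a config
flag excludes them for sensitivity analysis since software conventions
differ on this point. PSI is reported unclipped (it can be negative) with
pass flags at the conventional α > 0.8 and PSI > 0.7.

## The elimination pipeline

`rasch_validate()` splits the persons into disjoint calibration and
validation samples of `n_per_sample` each (default 500, a size at which the
infit band 0.91–1.09 is roughly ±2 standard errors of the statistic — a
fact that shapes the design below), runs parallel analysis on the full set
in both samples, then iteratively eliminates items one at a time with
re-estimation after every removal.

Two design decisions were genuinely open and deserve their rationale:

*Dependence is resolved before misfit.* Response dependence (e.g., two
near-duplicate items) deflates the infit of both pair members far below any
reasonable band and, if the pair is large enough, distorts every other
item's fit statistic, because the model-based residual variances assume
local independence. A stage order that screens infit first therefore
misattributes dependence as misfit — or worse, protects the pair and
eliminates sound items around it. At each step the pipeline flags Q3 pairs
first: if one exists, the member with the larger mean absolute residual
correlation against all other items is removed (tie-break: worse absolute
log infit) and the elimination is logged as `local_dependence`; only when no
pair is flagged is the worst out-of-band infit item removed as `misfit`.
Items with infit *above* the band cannot be produced by response copying, so
genuine noise items are never mislabelled by this priority.

*Eliminations require confirmation in the validation sample.* With an
acceptance band of ±2 SE, each refit gives each item a few-percent chance of
a false flag, and sequential refits compound this to a substantial
familywise false-elimination rate. The pipeline therefore eliminates an item
only when the finding replicates: for misfit, the calibration mean square
must be outside the band *and* the validation sample must show a significant
standardised infit deviation in the same direction (one-sided, at
`alpha_level`); for dependence, the same pair must show r above threshold
with unadjusted p ≤ `alpha_level` in the validation sample (no familywise
control when replicating one pre-identified pair). Replication is
deliberately a significance test rather than a second band check: a band
check in both samples deadlocks when two marginal misfits split their
evidence across samples, while directional significance keeps power against
real pathologies and drops the null false-elimination rate to a fraction of
a percent per item. The validation sample confirms; it never initiates an
elimination. Setting `confirm_with_validation = FALSE` restores single-
sample behaviour.

After elimination: parallel analysis of the retained set, DIF per requested
covariate on the retained items — flagged items are *reported, never
auto-removed*, because group-dependent behaviour of a clinically meaningful
symptom is a finding about the item, not automatic grounds for exclusion —
reliability of the initial set, retained set, and any user-named subsets,
and a role-swapped re-run of the elimination procedure whose per-item
agreement with the calibration decisions is tabulated. If elimination would
leave fewer than three items the pipeline aborts with the partial log
attached (condition class `raschval_abort`). The result carries Wright-map
data (person-measure histogram plus item locations on the shared logit
axis); the text rendering and the PNG are generated from the same stored
arrays.

## The synthetic generator

`simulate_responses()` emulates a population symptom survey: by default 11
binary indicators with difficulties spanning −0.77 to +2.33 logits (most to
least commonly endorsed) and a unimodal standard-normal latent trait,
sampled 500–1200 persons at a time. Each violation the pipeline tests for
can be planted with a controlled magnitude:

* *misfit*: per-item discrimination slopes other than 1 (a two-parameter
  generating mechanism; the package never estimates slopes);
* *uniform DIF*: a difficulty shift ±δ/2 split symmetrically between the
  groups so the pooled difficulty — and hence the rest of the analysis — is
  unchanged;
* *non-uniform DIF*: a group-specific slope ratio, the mechanism the
  Breslow–Day test targets (odds-ratio heterogeneity across strata);
* *local dependence*: item j's response overwritten by item i's with
  probability ρ, which directly controls the residual correlation and is
  trivial to verify by brute force;
* *multidimensionality*: a subset of items additionally loading on an
  independent second trait.

A fixed seed makes output byte-identical. What the generator does *not*
emulate: survey design effects (stratification, clustering, weights),
item nonresponse (the data model rejects missing cells; loading from CSV
applies listwise deletion and reports the count), polytomous or longitudinal
responses, and trait distributions other than the normal. Passing tests on
synthetic data therefore demonstrate that each statistic detects the
violation it targets at survey-realistic sizes — not that any particular
real survey satisfies the model.

## Problem sizes and what the tests show

The test suite exercises each stage at the sizes the workflow is designed
for: samples of 500 per arm and 11 items, with 20 replicate seeds for
detection-rate checks, 100 for the Breslow–Day power estimate, 1000 for
Mantel–Haenszel type-I calibration, and 500 permutations per parallel
analysis (5000 remains the analysis default). Small fixed 5×3 matrices pin
the CML estimator against direct numerical maximisation of the enumerated
conditional likelihood; closed-form cases pin the ESFs, τ² and α. One known
borderline: the Tarone-corrected Breslow–Day test has power of only about
one half against a within-item slope ratio of 2.5 at n = 500, so detection
of non-uniform DIF of that magnitude should be read as possible, not
expected — a limitation of the test at this sample size, not of the
implementation (we verified the statistic numerically against an independent
implementation).

## Limitations

CML difficulties are exactly invariant to the person distribution, but all
plug-in diagnostics (infit, Q3, PSI) depend on the WLE abilities and hence
mildly on the trait distribution; the infit denominator removes the
dominant such bias but not higher-order effects. The Q3 χ² = n r² form is a
score-type approximation whose exact null distribution depends on the
residual covariance structure. DIF stratification drops zero-margin strata
rather than pooling them; with very sparse data this can leave an item
untestable, which is reported as such and treated as non-significant with a
warning. The pipeline's elimination order is principled but greedy; it does
not search over item subsets.
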