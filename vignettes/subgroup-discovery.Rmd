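---
title: "Staged subgroup discovery in two-arm oncology trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged subgroup discovery in two-arm oncology trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscreen)
```

## The model

`oncoscreen` analyses a two-arm randomised trial in which every patient
carries a treatment indicator $t \in \{0, 1\}$, outcomes $Y$ (overall
survival and progression-free survival as censored time-to-event;
objective response as binary), a vector of binary somatic-alteration
indicators $x_1, \dots, x_m$, and categorical subtype labels
$s_1, \dots, s_q$ per subtyping scheme.  All regression models are either
Cox proportional-hazards fits (partial likelihood, Efron tie handling) or
maximum-likelihood logistic fits, written through their linear predictors:

* arm-specific screening, fitted separately per arm and stratum:
  $f(\mathbf{x}) = \alpha_{0j} + \alpha_{1j} x_j + \sum_l C_l$;
* cross-arm interaction:
  $f(\mathbf{x}, t) = \beta_{0j} + \beta_{1j} x_j + \beta_{2j} x_j t + \sum_l C_l$;
* subgroup treatment effect (conditional average treatment effect):
  $f(\mathbf{x}, t) = \gamma_0 + \gamma_1 t + \sum_l C_l$.

$\beta_{1j}$ is the prognostic and $\beta_{2j}$ the predictive component
of biomarker $j$; $\gamma_1$ is the log hazard (or odds) ratio of the
experimental arm inside one subgroup.  The intercepts $\alpha_{0j}$,
$\beta_{0j}$, $\gamma_0$ are estimated in logistic models only — the Cox
partial likelihood absorbs them into the baseline hazard, the standard
identifiability convention.  All p-values are two-sided Wald tests; 95%
intervals are $\exp(\hat\theta \pm z_{0.975}\,\mathrm{SE})$.

Two modelling choices deserve emphasis:

* **No treatment main effect in the interaction model.**  The interaction
  stage deliberately carries only $x_j$ and $x_j t$.  Under this
  parameterisation $\beta_{2j}$ compares treated mutants against the
  pooled remainder, which maximises power for the biomarker-specific
  question at the price of absorbing any biomarker-independent treatment
  effect into $\beta_{2j}$.  A configuration switch
  (`include_treatment_main = TRUE`) adds $\beta_t t$ for sensitivity
  analyses.
* **Reciprocal reporting.**  With `effect_reporting = "reciprocal"`
  (default) any reported ratio above 1 is flipped to its reciprocal with
  a direction flag (`benefit-in-wildtype`, `benefit-in-control`, …), so
  ratios below 1 always read as a benefit.  Stored coefficients remain on
  the raw scale; only the reporting columns flip.

## Thresholds and eligibility

| parameter | default | meaning |
|---|---|---|
| `fdr_mol` | 0.05 | BH threshold for subtype enrichment/depletion calls |
| `fdr_alpha` | 0.1 | BH threshold for arm-specific screening |
| `fdr_beta` | 0.2 | BH threshold for predictive interaction components |
| `n_min` | 10 | minimum patients per compared group before any fit |
| `n_permutations` | 1000 | treatment-label permutations (multiplicity) |
| `n_bootstrap` | 500 | bootstrap resamples (bias correction) |
| `fdr_beta_cv` | 0.3 | relaxed interaction FDR inside cross-validation |
| `mutex_alpha` | 0.05 | growth threshold of the module search |

Eligibility filters are applied before fitting and audited row by row:
screening requires at least `n_min` mutants *and* wild-types in the
analysed stratum-arm; interaction and subgroup stages require `n_min` of
each status *in each arm*; a module union is only tested where it
redistributes at least `n_min` patients relative to every single member
in that stratum (otherwise it duplicates a member's test).  Degenerate
outcomes (no events; one response class) and non-converged or separated
fits are excluded before BH adjustment, shrinking the family
accordingly, and recorded in the audit table.

**BH families.**  Correction families are (scheme, direction) for the
landscape, (endpoint, arm, scheme) for screening and (endpoint, scheme)
for interactions.  The unstratified analysis is its own family
(`scheme = "none"`) rather than sharing one with the subtype levels; the
alternative grouping is defensible, but separating them keeps a
stratum's family size independent of how many other schemes are
configured.

## Mutual exclusivity without a network prior

Functionally related driver alterations tend not to co-occur in the same
tumour, and grouping them recovers power for individually rare events.
The published network-guided approaches need curated interaction
databases; `oncoscreen` instead runs a network-free greedy search: from
every seed feature with at least `n_min` altered patients, the candidate
whose admission minimises the module score is added while the score stays
below `mutex_alpha`.  A member's exclusivity p-value is the one-sided
hypergeometric lower tail of its co-occurrence count with the union of
the other members; the module score is the worst member p-value, and a
candidate is only admissible while every member's observed co-occurrence
stays at or below its independence expectation (the test never rewards
co-occurrence).  Score ties prefer larger union coverage, then
lexicographic names, making output deterministic; duplicate member sets
are removed.  One consequence worth knowing: *perfect* exclusivity
between two rare features (say 10 and 12 patients of 100) is not
statistically surprising — its tail probability is about 0.27 — so such
pairs are correctly *not* reported.  Externally derived groupings can
always be supplied as `custom_modules` and join the feature set
unchanged.

## Resampling for honest subgroup inference

The search strategy — screening gate, interaction gate, and picking the
better of the mutant/wild-type populations — is itself a selection
procedure, so the naive p-value and effect of a found subgroup are both
optimistic.  Two resampling layers address this:

* **Permutation multiplicity adjustment.**  Treatment labels are permuted
  uniformly over the whole cohort (preserving marginal arm sizes;
  alterations and subtypes untouched, so the landscape never has to be
  recomputed), the complete search is replayed on each null dataset, and
  the smallest selected-subgroup p-value $p^{(u)}$ is recorded — 1 when
  the null search selects nothing, which keeps the estimator defined and
  conservative.  The adjusted p-value is the plain fraction
  $\tfrac1U \sum_u \mathbf{1}\{p^{(u)} \le p_{\gamma_1}\}$; an add-one
  variant $(1 + \Sigma)/(1 + U)$ is available by configuration.
* **Bootstrap bias correction.**  For each of $B$ resamples of patients
  with replacement, the mutant/wild-type selection is replayed for every
  originally found (feature, stratum) pair, giving the resample-selected
  population $A^{(b)}$; the per-resample corrected value is
  $\gamma_1(A) + \gamma_1(A^{(b)}) - \gamma_1^{(b)}(A^{(b)})$.  All
  arithmetic stays on the log scale (ratios are exponentiated only at
  reporting, since averaging ratios is biased); the point estimate is the
  mean and the 95% interval the 0.025/0.975 empirical quantiles of the
  per-resample values themselves (not re-centred on the corrected mean —
  the alternative re-centred interval was considered and rejected as less
  direct).  Resamples with a degenerate candidate population are skipped
  with a reduced denominator; above 20% skips the subgroup is flagged
  unstable.

**What the correction can and cannot do.**  The replayed selection is the
mutant-versus-wild-type choice per found pair.  The correction therefore
removes (an estimate of) that selection's optimism, but a single
bootstrap estimates optimism around the *observed* configuration, which
is itself inflated — the well-known under-correction of one-level
bootstraps.  In the package's null simulations the mean absolute selected
log-effect shrinks by roughly 15–20%, not by half: for a best-of-two
selection even an oracle that removed the selection bias entirely would
only reach a ratio of
$E|Z| / E\max(|Z_1|,|Z_2|) \approx 0.798/1.128 \approx 0.71$, because the
surviving estimate keeps its own sampling noise.  The corrected estimate
should be read as "naive minus estimated optimism", not as an oracle.
Cross-pair selection (when many candidate pairs compete) is adjusted by
the permutation p-value, not by the bootstrap.

Both layers draw from seeds derived from one master seed, so identical
seed and configuration reproduce every number bit for bit.  For forced
("best"-mode) searches the permutation loop uses a precomputed-subset
fast path that is verified in the test suite to equal the generic replay
exactly.

## The synthetic-trial generator

`simulate_trial()` draws: subtype labels (categorical per scheme);
binary features, independent except inside hard mutual-exclusivity
groups (one categorical draw per group, so co-occurrence is exactly
zero) and optionally enriched per subtype level via odds multipliers;
Bernoulli treatment; exponential survival with hazard
$\lambda_0 \exp(\eta + \eta_{\text{trt}} t)$, where $\eta$ collects
prognostic feature and covariate effects and $\eta_{\text{trt}}$ the
planted subgroup-specific predictive effects; independent exponential
censoring (observed time the minimum); progression-free survival from
the same machinery at a higher baseline rate; and a binary response with
$\operatorname{logit} P = a - b\,(\eta + \eta_{\text{trt}} t)$, so
response is genuinely correlated with the survival process.

Constant hazards mean proportional hazards holds exactly, so the Cox
estimands equal the design's log-hazard parameters — which is what makes
parameter-recovery and coverage tests meaningful.  What the generator
does *not* emulate: non-proportional hazards, informative censoring,
correlated co-occurrence short of hard exclusivity, measurement error in
the alteration calls, and real-world covariate confounding.  Passing
tests therefore certify the machinery under its stated model, not
robustness to those violations.

`fire3_like_design()` packages a 400-patient, 30-feature design with a
KRAS/NRAS/BRAF exclusivity group, sidedness and CMS1–4 schemes,
MSI-in-CMS1/right-side enrichment, moderate prognostic effects and two
planted predictive effects — an unstratified RAS-wild-type benefit
(log HR $-0.35$) and a strong amplified-CMS2 subgroup benefit
(HR $0.21$) — magnitudes chosen to echo what such analyses report.
Median survival (~25 months OS, ~10 months PFS at the baseline rates
$1/36$ and $2.5/36$ per month) and ~30% censoring are typical of
metastatic colorectal cancer first-line trials.

## Problem sizes used by the test suite

The packaged studies are sized to run on one CPU in minutes, chosen once:
type-I-error control uses 200 null trials (n = 300, 20 features, two
schemes, OS, U = 200); power/recovery uses 50 replicates of a planted
interaction (log HR $\log 0.4$, 30% prevalence inside a 40% subtype,
n = 600, 12 features at 5–40%, ~15% censoring); permutation-null
calibration uses 200 replicates × U = 200 with six designated candidate
features; the winner's-curse study uses 200 null trials with one
designated 30%-prevalence feature and B = 200; coverage uses 500 fits at
n = 300.  The acceptance script runs the full pipeline at U = B = 200.

## Cross-validation stability

`stability_cv()` repeats k-fold cross-validation (default 5×5, folds
stratified by arm; a fold that leaves an arm degenerate is redrawn and
logged), reruns screening and interactions on every training set with
the relaxed `fdr_beta_cv`, and tallies how often each
(endpoint, feature, scheme, level) ranks among the `top_k` smallest
interaction p-values.  Ranking is by interaction p-value — the ranking
statistic is a genuine free choice; p-value ranking was picked because it
is the quantity the selection gate itself thresholds.  The resampling
stage is skipped inside the loop: the target is selection stability, not
effect estimation.

## Known limitations

* The exclusivity search is greedy; it recovers cleanly separated
  modules (and matches exhaustive subset scoring in tests) but has no
  optimality guarantee for overlapping structures, and no
  signalling-network prior.
* Cox models assume proportional hazards; no diagnostics are run.
  Covariates enter unpenalised and must be complete.
* The bootstrap bias correction under-corrects by construction (see
  above); treat corrected estimates as conservative-naive, and rely on
  the permutation p-value for error control.
* Subgroups are single-feature × single-level only; no multi-marker
  rules.
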