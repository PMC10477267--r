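# oncoscreen

Subtype-aware biomarker screening and subgroup discovery for two-arm
randomised oncology trials.

## The problem

Randomised trials in molecularly profiled cancers routinely ask which
somatic alterations make one treatment preferable to the other — overall
and inside tumour subtypes such as primary tumour sidedness or consensus
molecular subtypes (CMS).  Answering that question naively invites three
well-known failure modes: low power for rare alterations, a large hidden
multiple-testing burden from the subgroup search itself, and the winner's
curse that inflates the effect estimate of whichever subgroup the data
happened to crown.  `oncoscreen` is a staged discovery engine for exactly
this setting, written for trial statisticians and translational-oncology
analysts who have a clinical table, a binary patient-by-gene alteration
matrix, and subtype labels.

## The method

For a trial with treatment indicator `t ∈ {0, 1}`, outcome `Y` (overall
survival, progression-free survival as time-to-event; objective response
as binary), candidate binary biomarkers `x_j` and subtype levels `s_k`,
the pipeline runs five stages:

1. **Molecular landscape.**  One-sided hypergeometric tests for
   enrichment/depletion of each alteration in each subtype level
   (Benjamini–Hochberg within each scheme × direction family,
   `FDR_mol = 0.05`), and a network-free greedy search for mutually
   exclusive alteration modules whose unions join the feature set,
   alongside user-defined groupings such as RAS = KRAS ∪ NRAS.
2. **Arm-specific screening.**  Per treatment arm, per endpoint, per
   stratum (all patients plus every subtype level), the prognostic model
   `f(x) = α0j + α1j x_j + Σ C_l` is fitted by Cox partial likelihood or
   logistic regression; `exp(α1j)` is the mutant-versus-wild-type hazard
   or odds ratio.  BH within each (endpoint, arm, scheme) family at
   `FDR_α = 0.1`.  Tests require at least `n = 10` mutants and 10
   wild-types in the analysed stratum-arm.
3. **Predictive interactions.**  Across arms,
   `f(x, t) = β0j + β1j x_j + β2j x_j t + Σ C_l` separates the prognostic
   (`β1`) from the predictive (`β2`) component; BH within
   (endpoint, scheme) at `FDR_β = 0.2`.  A biomarker is putatively
   predictive when its interaction FDR passes and its screening call was
   significant in at least one arm.
4. **Subgroup selection.**  For each predictive biomarker the conditional
   average treatment effect `f = γ0 + γ1 t + Σ C_l` is estimated in the
   mutant and the wild-type population; the one with the larger |γ1| is
   the reported subgroup.
5. **Honest inference.**  Treatment labels are permuted `U` times and the
   *entire* search is replayed per permutation; the adjusted p-value of a
   found subgroup is the fraction of null best-subgroup p-values at or
   below its own.  A nonparametric bootstrap (`B` resamples) replays the
   mutant/wild-type selection and averages
   `γ1(A) + γ1(A⁽ᵇ⁾) − γ1⁽ᵇ⁾(A⁽ᵇ⁾)` to de-bias the selected effect, with
   a 95% interval from the 0.025/0.975 quantiles of those values.

A seeded synthetic-trial generator (`simulate_trial()`), a repeated
cross-validation stability analysis (`stability_cv()`), broom-style
`tidy()`/`glance()` methods and `autoplot()` figures complete the
package.

## Worked example

```r
library(oncoscreen)

trial  <- simulate_trial(fire3_like_design(), seed = 1)
report <- run_pipeline(
  trial,
  config  = utils::modifyList(unclass(trial_config(trial)),
                              list(endpoints = "OS",
                                   n_permutations = 200L,
                                   n_bootstrap = 200L)),
  seed = 7
)
report
```

```
<onco_report>
  400 patients, 37 features (7 modules)
  enrichment calls: 2 | screening hits: 10 | predictive: 3
  OS | ARFRP1_AMP mutant | cms=CMS2: effect 0.47 (corrected 0.62 [0.16, 2.61]), p_adj 0.31
  OS | MSI mutant | none=ALL: effect 0.39 (corrected 0.42 [0.21, 0.98]), p_adj 0.115
  OS | MSI mutant | side=left: effect 0.76 (corrected 0.82 [0.14, 3.98]), p_adj 0.31
```

The packaged design plants an experimental-arm benefit for
ARFRP1-amplified CMS2 tumours; the pipeline recovers that subgroup with a
naive within-subgroup hazard ratio of 0.47.  The bootstrap pulls the
estimate back towards the null (0.62 — the naive value is the best of the
mutant/wild-type pair and therefore optimistic), and the search-aware
permutation adjustment shows that, in a 400-patient trial with 37
candidate features, a subgroup this extreme arises by chance in roughly a
third of null replays (`p_adj 0.31`) — exactly the honesty the staged
design is for.  The two other lines are the companion calls at this seed
(the simulated MSI alteration is prognostic, not predictive; its
subgroup does not survive adjustment either).

`run_pipeline(..., out_dir = "results/")` writes every stage as TSV
(`enrichment.tsv`, `modules.tsv`, `arm_biomarkers.tsv`,
`interactions.tsv`, `subgroups_adjusted.tsv`, `km_curves.tsv`,
`audit.tsv`), a JSON summary and a MANIFEST; identical seeds give
byte-identical files.  The same pipeline is scriptable from a shell via
`exec/oncoscreen` (`run`, `simulate`, `landscape`, `stability`
subcommands).

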