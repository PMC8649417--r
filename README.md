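# grmmeans

Monte Carlo evaluation of group mean comparison strategies for
patient-reported outcome (PRO) measures under the graded response model
(GRM), including differential item functioning (DIF) and missing-at-random
responses.

PRO instruments score patients on a latent construct θ. When two patient
groups (a *reference* group fixing the metric at N(0,1) and a *focal* group
with mean μ_F and variance σ²_F) are compared, the analyst chooses among:

* **sum scores** + two-sided Welch *t*-test + pooled-SD effect size
  (listwise deletion of persons with missing responses);
* the **IRT-model** approach: multigroup GRM fit by marginal maximum
  likelihood with all items constrained equal across groups and (μ_F, σ²_F)
  free, testing μ_F = 0 with a 1-df likelihood ratio test
  χ² = −2(ln L_restricted − ln L_general);
* **IRT-EAP** scores: posterior means E[θ | u] under pre-calibrated item
  parameters and a N(0,1) prior, then Welch test + pooled effect size.

Under the GRM, item *j* with `V` ordered categories has cumulative category
response functions

    P(u_ij ≥ v) = logistic(a_j (θ_i − b_jv)),   v = 1, …, V−1,

with discrimination `a_j` and ordered thresholds `b_j1 < … < b_j,V−1`
(pure logistic metric; `a_to_loading()` documents the D = 1.7 conversion to
factor loadings). The package provides the full simulation laboratory:
item banks, condition-specific item draws, directional DIF (40% of items
disadvantaging the focal group), MAR missingness (30% of subjects on 20% of
items), an SQUAREM-accelerated EM estimator for the multigroup GRM, an
all-others-as-anchors likelihood-ratio DIF prescreening pipeline, a seeded
study runner over the 2^7 × 2 condition grid, Type-I-error / power /
effect-size-MAE summary tables, and shallow regression-tree summaries
(max depth 4, complexity 0).

See `vignettes/methods.Rmd` for the model, the generator's assumptions,
and the numerical choices.

## Worked example

One replication of a demanding cell — 400 per group, 20 highly
discriminating five-category items with homogeneous thresholds, DIF
present, true focal mean 0.5:

```r
library(grmmeans)
grid <- build_condition_grid()
cell <- grid[grid$n_per_group == 400 & grid$n_items == 20 &
             grid$discrimination == "high" & grid$n_categories == 5 &
             grid$thresholds_mode == "homogeneous" & grid$dif == "present" &
             grid$missing == "absent" & grid$true_focal_mean == 0.5, ]
set.seed(derive_seed(42, 0, 0)); banks <- build_bank_set()
rec <- run_replication(as_condition_spec(cell),
                       seed = derive_seed(42, cell$condition_id, 1),
                       banks = banks)
print(rec$prescreen)
for (r in rec$results) print(r)
cat(sprintf("DTF effect size of this replication: %.3f\n", rec$dtf))
```

```
DIF prescreening: anchors {1,3,19,20}; clean items {1,2,3,5,11,13,14,16,18,19,20}; DIF items {4,6,7,8,9,10,12,15,17}
sum_score (non-prescreened): p = 7.775e-05, reject, effect size = 0.281
sum_score (prescreened): p = 1.18e-11, reject, effect size = 0.487
irt_eap (non-prescreened): p = 1.015e-05, reject, effect size = 0.314
irt_eap (prescreened): p = 2.181e-12, reject, effect size = 0.505
irt_model (non-prescreened): p = 3.851e-06, reject, effect size = 0.337
irt_model (prescreened): p = 2.884e-12, reject, effect size = 0.518
DTF effect size of this replication: -0.208
```

The 8 DIF items disadvantage the focal group by about a fifth of a test
SD (DTF −0.208), so without prescreening all three approaches
underestimate the true effect of 0.5 (estimates 0.28–0.34); after
prescreening all three recover it (0.49–0.52).

A small study over four DIF-free cells, summarized and displayed as a
tree:

```r
sub <- grid[grid$n_items == 5 & grid$n_categories == 2 &
            grid$thresholds_mode == "diverse" & grid$dif == "absent" &
            grid$missing == "absent" & grid$true_focal_mean == 0.5, ]
study <- run_study(sub, n_reps = 30, master_seed = 42)
s <- summarize_study(study)
fit_tree(s$power, "rate")
```

```
root: mean=0.840, n=24
  n_per_group in {100}: mean=0.681, n=12
  n_per_group not in {100}: mean=1.000, n=12
```

With 400 per group, power is 1.00 in every arm of these cells; at 100 per
group it averages 0.68 and the tree's first split picks the sample size as
the dominant feature. The same machinery is available from the command
line (`inst/cli/grmmeans`) with `simulate`, `summarize`, and `tree`
subcommands.

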