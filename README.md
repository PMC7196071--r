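# actbenefit

Tools for predicting which stage II–III colorectal-cancer patients
benefit from 5-fluorouracil-based adjuvant chemotherapy (ACT) after
curative surgery, from bulk tumour gene-expression profiles.

Prognostic signatures abound; *predictive* ones — markers of whether
treatment changes the outcome — are rarer and statistically harder.
This package implements a complete treatment-benefit workflow:

* **labels** — a patient is *ACT-benefit* when treatment and three-year
  relapse status are concordant with chemotherapy helping (relapse-free
  past 36 months with ACT, or relapsed before 36 months without it) and
  *ACT-futile* in the opposite cells; patients censored before the
  landmark are excluded;
* **screen** — per-gene two-sided Wilcoxon rank-sum tests between the
  benefit and futile groups (exact by enumeration for small groups);
* **model** — genetic-algorithm wrapper selection over candidate genes
  around an RBF support vector machine whose fitness is 5-fold
  cross-validated AUC (population 20, crossover 10%, mutation 30%),
  with TNM stage forced into every model, own Platt calibration, and
  exact JSON model round-trips;
* **cutoff** — sliding-window STEPP: the ACT effect (36-month RFS
  difference, Cox HR) re-estimated across overlapping score-ordered
  subpopulations, with the cutoff at the smallest window median above
  which every window has HR < 1;
* **validation** — Kaplan–Meier/log-rank, Cox models (Efron ties),
  treatment × group interaction tests, uncorrected Pearson chi-square
  baseline tables, and a propensity-score sensitivity analysis with
  greedy 1:1.5 nearest-neighbour matching;
* **synthetic cohorts** — a generator planting treatment-modifying
  genes in exponential relapse models with stage-confounded treatment
  assignment, so the whole pipeline is testable without downloads;
* a rank-based gene-pair (REO) classifier as a comparator.

In the standard notation: relapse hazard is modelled as
`h(t) = h0 · exp(β·x + ACT·(α + γ·1[s > q_τ]))` where `s` is the gene
biomarker score; the pipeline estimates the benefit region `s > q_τ`
from labels, and validation tests `γ` through the Cox product term.

## Worked example

A synthetic 600-patient cohort with three planted treatment-modifying
genes, run through the full pipeline:

```r
library(actbenefit)

cfg <- synthetic_config(n_patients = 600, n_genes = 50)
sim <- generate_cohort(cfg, seed = 42)

lab <- label_cohort(sim)
table(lab$labels)
#> benefit  futile
#>     272     289        (39 patients censored before 36 months excluded)

screen <- wilcoxon_screen(lab$expression, lab$labels, alpha = 0.05)
cand <- screen$gene[screen$candidate]          # 4 candidate genes

feats <- build_feature_matrix(lab$expression, lab$clinical, cand,
                              include_stage = FALSE)
stage <- cbind(tnm_stage_iii = as.numeric(lab$clinical$tnm_stage == "III"))
y <- lab$labels == "benefit"
tuned <- tune_hyperparams(cbind(feats, stage), y, seed = 1)
sel <- ga_select(feats, y, tuned$cost, tuned$gamma,
                 config = ga_config(iterations = 200, seed = 2),
                 forced_features = stage)
sel$best_fitness
#> [1] 0.622                                    # CV AUC of the selected model

model <- train_final_model(lab$expression, lab$clinical, lab$labels,
                           cand[sel$best], tuned$cost, tuned$gamma,
                           seed = 3, fitness = sel$best_fitness)
scores <- predict_scores(model, sim$expression, sim$clinical)

pr <- stepp_profile(scores, sim$clinical$act,
                    sim$clinical$rfs_months, sim$clinical$relapse_event)
round(as.data.frame(pr)[, c("median_score", "rfs_diff", "hr")], 3)
#>   median_score rfs_diff    hr
#> 1        0.343   -0.175 1.507      # low scores: ACT harmful
#> ...
#> 7        0.621    0.270 0.617      # high scores: ACT protective

cutoff <- select_cutoff(pr)          # 0.529
groups <- stratify_patients(scores, cutoff)

interaction_pvalue(sim$clinical$rfs_months, sim$clinical$relapse_event,
                   sim$clinical$act, groups,
                   adjusters = data.frame(stage = stage[1:600, ]))
#> [1] 0.000684
```

Per-group Cox fits of the ACT effect show the stratification doing its
job — ACT is associated with *worse* RFS where the model predicts
futility and better RFS where it predicts benefit:

```
predicted-futile:  ACT HR 1.470 (1.173-1.840), p = 0.0008
predicted-benefit: ACT HR 0.617 (0.436-0.875), p = 0.0067
```

`run_pipeline()` wraps all of the above (plus artifact files and a
manifest) behind a single seeded configuration; reruns are
byte-identical. See the vignette in `vignettes/act-benefit-modeling.Rmd`
for the model, its assumptions, and the package's design choices.

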