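# wsitrust

Trustworthy tile-based whole-slide image (WSI) classification for R:
distance-aware uncertainty, conformal abstention, ambiguity-guided tile
elimination, and out-of-distribution (OOD) rejection, exercised end-to-end
on a seeded synthetic cohort generator.

## Who this is for

Computational pathology groups prototyping *deployment safeguards* around a
tile-based subtype classifier: binary labels (e.g. LUAD vs LUSC) are known
only per slide, every tile inherits that weak label, and a deployed model
must quantify its uncertainty, abstain with guarantees, and refuse inputs
from other tissue types. All components work on any per-tile embedding +
manifest representation; none require images.

## What is inside

| Layer | Functions | Idea |
|---|---|---|
| Classifier | `sngp()`, `abmil()`, `dropout_net()` / `mc_dropout_predict()` | Spectral-normalized residual MLP (or attention-MIL bag model) with a random-Fourier-feature Gaussian-process head: logits `mu = phi' beta`, ridge variance `sigma^2 = tau phi' (Phi'Phi + tau I)^{-1} phi`, one forward pass per tile |
| Conformal | `conformal()`, `crc()`, `conformal_evaluate()` | Split CP with `s(x,y) = 1 - f(x)_y` and threshold `q_hat = ` the `ceil((R+1)(1-alpha))`-th smallest calibration score; conformal risk control by bisection with a finite-sample-corrected target, robust to undetected OOD |
| EAT | `ambiguity_score()`, `select_k()`, `ambiguity_index()`, `eliminate()` | Ambiguity `1 - |p0 - p1|`; eliminate tiles by latent cluster (no weak-label dominance), score threshold, or at random (baseline) |
| OOD | `probability_ood_score()`, `uncertainty_ood_score()`, `ood_scorer()`, `evaluate_detection()`, `dsc_filter()`, `guarded_inference()` | Patient-level OOD scores (mean max-probability deficit, or mean of the `delta = 200` lowest tile uncertainties), FPR/TPR/precision thresholds, detector + CRC pipeline |
| Metrics | `aggregate_hierarchy()`, `classification_metrics()`, `fairness_gaps()`, `attention_efficiency()` | Tile→slide→patient two-stage means, accuracy/AUROC, max−min subgroup gaps, attention-vs-relevance overlap |
| Data | `cohort_config()`, `generate_cohort()`, `generate_ood_cohort()`, `relevance_mask()` | Seeded three-cluster synthetic cohorts with weak labels, hierarchy, demographics, and displaced OOD cohorts |
| Studies | `cp_validity_study()`, `guarded_coverage_study()`, `eat_paired_study()`, `eat_retention_study()`, `reproduce_protocol()` | The package's simulation experiments, sized for one CPU |

A thin CLI wraps simulation and the evaluation protocol:
`Rscript inst/cli/wsitrust.R simulate --seed 7 --out cohort/`.

## Worked example

```r
library(wsitrust)

cfg    <- cohort_config(seed = 42)          # 100 patients, 2/3 ambiguous tiles
cohort <- generate_cohort(cfg)
model  <- sngp(cohort, config = sngp_config(D = 256, epochs = 20, seed = 42))

test <- generate_cohort(cohort_config(seed = 43))
pred <- predict(model, test)                # probabilities + per-tile uncertainty
pat  <- aggregate_hierarchy(pred$probs, test$manifest)$patient
classification_metrics(as.matrix(pat[, c("p0", "p1")]), pat$label)

cal <- pat[1:50, ]; te <- pat[51:100, ]
cp  <- conformal(nonconformity(as.matrix(cal[, c("p0", "p1")]), cal$label),
                 alpha = 0.05)
ev  <- conformal_evaluate(predict(cp, as.matrix(te[, c("p0", "p1")])), te$label)

ood   <- generate_ood_cohort(cfg, n_patients = 30)
s_in  <- unit_ood_scores(pred, test$manifest$patient_id)
s_out <- unit_ood_scores(predict(model, ood), ood$manifest$patient_id)
evaluate_detection(s_in, s_out)$auroc
```

Output from this run:

```
SNGP classifier: 8-d input, hidden [32, 32], RFF dim 256, tau 1, c 1
  trained on 2514 tiles; best validation accuracy 0.675
patient accuracy 1.000, AUROC 1.000
Split conformal predictor: alpha 0.05, R 50, q_hat 0.4800
coverage 1.000, mean set size 1.00, DA error 0
OOD AUROC 1.000
```

Reading it: tile-level validation accuracy saturates near 0.67 because two
thirds of the tiles are ambiguous by construction (their weak labels are
coin flips — no classifier can beat that ceiling), yet averaging tiles to
patients recovers perfect patient-level discrimination; the conformal layer
then certifies 95% coverage (here all 50 test patients get correct
singleton sets, so the determinate-answer error is 0), and the
uncertainty-based OOD score separates a displaced cohort perfectly.

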