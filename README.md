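# zonescreen

Screening-test analysis of virtual driving-test (VDT) telemetry. New
license applicants drive a simulated route; the multichannel recording
(~10 Hz frames: position, speed, brake, throttle, steering, lane offset,
signals, posted limit) is used to predict failure on the subsequent state
on-road examination (ORE), where an infraction score ≥ 26 fails and scores
20–35 form a "gray zone" of near-misses. The package is aimed at
researchers evaluating behavioral time-series screeners: it provides both a
standard engineered-variables representation and a soft-clustering
representation built from event-zone behavior, plus the screening metric
suite used to compare them.

## The method

Routes contain predefined **event zones** (crosswalks, school zones,
construction/playground zones, banked curves, stop- and light-controlled
intersections, rear-end events) bounded by entry/exit waypoints along the
route centerline. For each zone, the slice of every drive recorded between
the waypoints — its **subinterval** `χ_i`, carrying the lane-offset,
throttle, brake, and steering channels — is extracted, and all pairs are
compared with **dynamic time warping** (per-frame Euclidean cost across
channels, path-length-normalized), giving a dissimilarity matrix `D`.
**k-medoids** (k = 8, best of 20 restarts, ≤ 100 rounds, inertia
`Σ_i d(χ_i, c_{a(i)})²`) elects medoids `c_1..c_k` — *prototypical
behaviors* for that zone. Rather than a hard label, each drive is
represented by its dissimilarities `d(χ_i, c_j)` to every medoid of every
zone (soft clustering): k × 166 = 1328 features on the full bank, with k
blank entries for zones a drive never encountered.

A cross-validated logistic decision rule (threshold τ swept 0..1 by 0.01)
or an RBF-SVM over a dyadic (cost, gamma) grid predicts pass/fail, and a
2×2 screening table (FF/FP/PF/PP) is summarized by accuracy, fail rate,
false-alarm rate, ratio of false alarms `FP/(FF+FP)`, TPR/FPR with ROC/AUC,
and the **risk ratio** `RR = [FF/(FF+FP)] / [PF/(PF+PP)]` with a Katz
log-normal 95% CI.

Because the study cohort (n = 4308, 25.4% ORE failure) was never deposited,
the package includes a synthetic simulator: 10 environments, 166 zones,
~8-minute drives, three planted behavior archetypes per zone type, a latent
skill θ selecting archetypes (risky ones more likely as θ falls), and an
outcome model `score = round(max(0, a(1−θ) + bW + ε))` coupling the ORE
score to both skill and realized infractions `W`.

## Worked example

Reconstruct the published screening table for the clustering + logistic
classifier from its printed rounded metrics, and recompute every derived
statistic:

```r
library(zonescreen)
cm <- reconstruct_confusion(4308, 1096,
        c(tpr = 10.0, fpr = 1.3, ratio_false_alarms = 27.2))
cm
#>           fail ORE  pass ORE
#> fail VDT       110        41
#> pass VDT       986      3171
screening_metrics(cm)
#> accuracy 76.2%  fail rate 3.5%  false alarm rate 1.0%
#> ratio of false alarms 27.2%  TPR 10.0%  FPR 1.3%
#> risk ratio 3.071 (95% CI 2.747-3.434)
```

A drive predicted to fail is 3.07 times as likely to actually fail the ORE
as one predicted to pass, and 27.2% of predicted failures are false alarms.

Run a small synthetic pipeline end to end (simulate → extract → cluster →
featurize → evaluate):

```r
cfg <- run_config(seed = 7, n_drivers = 40, n_env = 2, total_zones = 8,
                  route_length = 800, k = 3, restarts = 3, folds = 4,
                  cluster_scope = "all", out = "run1")
rep <- run_pipeline(cfg)
ncol(rep$features)   # 24 = k (3) x zones (8)
rep$result           # threshold sweep with ROC/AUC
```

A command-line wrapper over the same functions lives at
`inst/cli/zonescreen` (subcommands `simulate`, `extract`, `cluster`,
`featurize-variables`, `evaluate`, `run`).

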