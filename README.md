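# circaphase

Circadian phase prediction from ambulatory wearable recordings.

## The problem

Knowing an individual's circadian phase — the clock time of their melatonin
rhythm's peak — matters for scheduling light therapy, assessing shift-work
misalignment, and predicting performance risk. The gold-standard markers
(salivary melatonin under a laboratory constant routine; urinary
6-sulphatoxymelatonin, aMT6s, from sequential urine collections) are costly
and slow. `circaphase` implements a machine-learning alternative for
chronobiologists and sleep researchers: a lagged-input multilayer
perceptron that predicts the reference melatonin/aMT6s rhythm from
wrist-worn blue-light irradiance and skin-temperature recordings, plus the
full preprocessing, reference-fitting, validation and evaluation chain
around it, and a synthetic-cohort generator with known ground-truth phase.

## The model

* **Reference rhythms.** Melatonin profiles are fitted with a bimodal
  skewed baseline cosine function (BSBCF)
  `f(t) = b + H/(2(1-c)) [g(t) - c + |g(t) - c|]`,
  `g(t) = cos(t - φ + v cos(t - φ)) + m cos(2t - 2φ - π)`;
  aMT6s excretion rates (concentration × volume / duration, at block
  midpoints) with a 24-h cosine `f(t) = b + a cos(2π (t - φ)/1440)`.
  Phase is the center of gravity (CoG) of one 24-h cycle of the fitted
  curve: `CoG = Σ t (f(t) - b) / Σ (f(t) - b)` over its above-baseline
  portion.
* **Inputs.** 30-minute binned channels; light lags 0–24 h (49 columns),
  temperature lags 0–5 h (11 columns per variable): 60 inputs / 311
  weights with one wrist sensor, 115 inputs / 586 weights with the
  6-variable montage. One hidden layer of 5 tanh units, logistic output.
* **Training.** Full-batch resilient backpropagation (iRprop−), 100
  seeded random restarts keeping the lowest training MSE, leave-one-out
  cross-validation by participant, predictions scored only on out-of-lab
  data. Comparators: mid-sleep proxy, a uniform guess over the 1.3–7.1 h
  normal acrophase range, and resampling of the group's measured phases.

## Worked example

Six synthetic fixed-schedule participants with phase-coupled light
exposure; leave-one-out network predictions of each held-out participant's
aMT6s acrophase:

```r
library(circaphase)
cfg    <- run_config(restarts = 10, epochs = 200, rng_seed = 1)
sim    <- sim_config(n_participants = 6, days = 4, seed = 1, coupling = 1)
cohort <- gen_cohort(sim)
cd     <- cohort_designs(cohort, cfg)          # preprocess + reference + lags
preds  <- loocv(cd$designs, cfg, seed = 1)     # 6 folds, 10 restarts each
scored <- score_predictions(preds, cd$references)

data.frame(id = names(scored$errors),
           measured_h  = round(scored$measured / 60, 2),
           predicted_h = round(scored$predicted / 60, 2),
           error_min   = round(scored$errors, 1))
#>     id measured_h predicted_h error_min
#> 1 FS01       5.41        4.68      43.8
#> 2 FS02       3.71        4.19     -28.7
#> 3 FS03       4.54        4.46       4.6
#> 4 FS04       2.48        2.20      16.8
#> 5 FS05       2.09        2.51     -25.7
#> 6 FS06       1.63        1.96     -19.5

round(scored$summary[, c("n", "mean", "mae", "rmse", "pct_within_60")], 2)
#>   n  mean   mae rmse pct_within_60
#> 1 6 -1.47 23.18 26.1           100
```

`measured_h` is each participant's aMT6s acrophase (clock hours) from the
cosine fit to their urine blocks; `predicted_h` is the CoG of the curve
fitted to the network's predicted rhythm; `error_min` is the signed
circular difference (measured − predicted). Here the network recovers
phase with a mean absolute error of 23 minutes and every participant
within ±1 h — the cohort was generated with full phase–light coupling, the
regime in which the method is identifiable. Decoupling phase from the
rest–activity cycle (`coupling = 0`, the night-shift regime) makes
diurnal-trained predictions fail; see the methods vignette.

A command-line interface wraps the same pipeline:

```sh
exec/circaphase simulate  --out cohort_dir --n 16 --seed 1
exec/circaphase evaluate  --in cohort_dir --out results --seed 1 --restarts 10
```

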