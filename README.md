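# raforecast

Forecasting next-visit rheumatoid arthritis (RA) disease activity from
longitudinal electronic health record (EHR) data.

## The problem

RA care is steered by the Clinical Disease Activity Index (CDAI), a composite
score on 0–72 recorded at clinic visits and binned into remission (≤ 2.8), low
(2.8–10], moderate (10–22] and high (> 22) activity, or aggregated into a
binary state: **controlled** (CDAI ≤ 10) vs **uncontrolled** (CDAI > 10). A
model that forecasts whether a patient will be uncontrolled at their *next*
visit — from nothing but the diagnosis, medication, laboratory and CDAI event
tables a clinic already has — could inform how aggressively to treat today.
This package implements such a forecasting pipeline end to end, for
rheumatology researchers and clinical-ML practitioners:

- **Cohort definition** from relational event tables: ≥ 2 RA ICD-9 codes
  (714.0/714.1/714.2) ≥ 30 days apart, ≥ 1 DMARD prescription, ≥ 2 CDAI
  scores, ≥ 1 inflammation lab (ESR or CRP). Each patient's most recent CDAI
  visit is the prediction target (index visit).
- **Fixed-interval featurization**: each patient's history is cut into four
  120-day windows counting back from the index date; within a window only the
  most recent value of each variable is kept, missing cells take a sentinel
  (zero), and only the first occurrence of each medication counts. With 29
  DMARD indicators, 8 corticosteroid indicators, CDAI, ESR and CRP per window
  plus 5 static variables (age, sex, race, RF, anti-CCP), the design matrix
  has 4 × 40 + 5 = **165 variables**.
- **The forecaster**: a small, highly regularized recurrent network — a dense
  transform applied identically to every window (statics broadcast onto each
  window), stacked gated recurrent units, and a sigmoid output giving
  P(uncontrolled at the index visit). Trained with Adam on binary
  cross-entropy, equal class weights, early stopping on validation AUROC.
  A fully dense surrogate (the multilayer-perceptron comparator) trains on the
  flattened 165-vector.
- **Bespoke baselines**: an *outcome-posterior* classifier that predicts
  controlled with the training prevalence (e.g. 60% of the time), and a
  *change-posterior* classifier that carries each patient's prior outcome
  forward, flipped with the cohort's visit-to-visit switch rate.
- **Evaluation and explanation**: AUROC with DeLong confidence intervals
  (variance from per-positive/per-negative placement values), grouped
  permutation importance scores (PIS, in percentage points of AUROC, with
  percentile CIs and a "time" entry that permutes window order),
  confident-and-wrong counts (confidence band 0.2/0.8, correctness threshold
  0.5), per-category subgroup accuracy, learning curves, and a t-SNE confusion
  plot of the learned patient representations.
- **Cross-hospital transfer**: train at a large source site, then (1) train a
  native model on the small target site, (2) apply the source model directly,
  (3) fine-tune it on the target training set (output layer first, then all
  weights, at a tenth of the learning rate).
- **A calibrated synthetic EHR generator**, because real RA extracts are
  protected health data. Profiles emulate a university hospital (median
  100-day visit gaps, median 6 CDAI scores, 60% controlled visits, 25%
  visit-to-visit switch rate, broad DMARD use) and a safety-net hospital
  (180-day gaps, 4 scores, narrower treatment, different demographics). The
  generator solves its CDAI map in closed form so those marginals are hit, and
  persists its latent ground truth so signal-recovery tests are possible.

## A worked example

```r
library(raforecast)

cfg <- experiment_config(
  source_profile = hospital_profile("university", n_patients = 1200),
  target_profile = hospital_profile("safety_net", n_patients = 330),
  evaluation = list(pis = TRUE, pis_repeats = 50, pis_windows = "combined"),
  seed = 1)
report <- run_experiment(cfg)
print(report)
```

```
<ra_experiment>
source test set:
  recurrent          AUROC 0.804 (0.739-0.868)
  dense              AUROC 0.746 (0.676-0.817)
  outcome_posterior  AUROC 0.487 (0.418-0.557)
  change_posterior   AUROC 0.674 (0.608-0.741)
target test set:
  native             AUROC 0.664 (0.515-0.813)
  direct             AUROC 0.781 (0.649-0.913)
  finetuned          AUROC 0.787 (0.657-0.917)
  outcome_posterior  AUROC 0.481 (0.341-0.620)
  change_posterior   AUROC 0.744 (0.622-0.866)
confident-and-wrong: 19 of 210 (9.0%)
```

Reading the output: on the source site the recurrent forecaster is far above
both posterior baselines. The outcome posterior sits at the chance AUROC of
0.5, as it must — its predictions ignore the truth entirely; the change
posterior is modestly informative here because the synthetic outcome process
has exactly symmetric 25%-switch transitions, making the prior outcome a
usable score. On the small target site, the model transferred from the large
source site beats the model trained natively on the target's own
125-patient-scale training set,
and fine-tuning adds little beyond direct transfer. The PIS table in
`report$pis` ranks the CDAI history as by far the most important variable
group (combined PIS ~15 percentage points of AUROC in this run), followed by
the inflammation labs.

Exact numbers vary with the seed; the block above is the output of the
configuration shown (seed 1) on the synthetic study.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/raforecast.R generate --preset university --n 500 --out ehr_csv --seed 7
Rscript inst/cli/raforecast.R run --config experiment.yaml --out results
```

See `vignettes/methods.Rmd` for the model, the generator's design and its
limitations.
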