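# voicerisk

Simulated depression-risk screening from Parkinson's voice biomarkers, as a
reproducible R pipeline. Depression frequently accompanies Parkinson's
disease and degrades vocal quality: a breathy voice lowers the
harmonics-to-noise ratio (HNR, dB) and unstable vocal-fold control raises
jitter (cycle-to-cycle variation of the fundamental frequency, stored as a
raw fraction in the UCI column `MDVP:Jitter(%)`). In the absence of
clinical annotations, a heuristic screening label can be simulated from
these two biomarkers and used as proxy ground truth. `voicerisk` packages
that pipeline end to end for anyone studying voice-based digital
phenotyping or needing a fully audited, dependency-light reference
implementation of attention-augmented tabular classification.

The labelling rule is

```
y = 0 (low risk)   iff  HNR > 20  and  Jitter < 0.005   (both strict)
y = 1 (high risk)  otherwise
```

equivalently `y = 1 − H(HNR − 20)·H(0.005 − Jitter)` with the Heaviside
convention `H(0) = 0`, so threshold-equality cases are high risk. The
classifier is a self-attention-enhanced MLP (SA-MLP): dense 64 (ReLU) →
multi-head self-attention (4 heads, key dim 16, one token per sample) →
residual + layer norm → dense 32 (ReLU) → dropout → sigmoid, trained with
mini-batch Adam (lr 0.001, batch 16, ≤ 50 epochs), early stopping
(patience 10) on binary cross-entropy, all gradients hand-derived and
verified by finite differences. A plain-DNN and a k-NN baseline, a
rule-faithful synthetic generator of the 22-column UCI schema, stratified
splitting, z-score normalization, screening metrics and a parameter audit
round out the package. Everything is driven by one integer seed and
replays exactly.

## Worked example

```r
library(voicerisk)

cfg <- experiment_config(
  synth = synth_params(n = 1000, seed = 11, target_balance = 0.5),
  seed = 11, baselines = c("dnn", "knn")
)
rep <- run_experiment(cfg)
print(rep)
```

```
[data] 1000 rows, 500 high risk (seed substream 19156603)
[split] train 800 / test 200 (seed substream 24169330)
[train] stopped epoch 14, best epoch 4 (seed substream 23710028)
screening experiment
  data: synthetic
  sa_mlp metrics (rounded):
    accuracy=0.90 precision=0.90 recall=0.89 f1=0.89 specificity=0.90
  dnn metrics (rounded):
    accuracy=0.88 precision=0.86 recall=0.89 f1=0.88 specificity=0.86
  knn metrics (rounded):
    accuracy=0.76 precision=0.79 recall=0.70 f1=0.74 specificity=0.81
```

The SA-MLP learns the rule from data in which only 2 of 22 features carry
signal: held-out accuracy ~0.90 against a 0.5 chance level, ahead of the
attention-free DNN and far ahead of k-NN. Misclassifications concentrate in
a narrow band around the jitter threshold where the generator puts maximal
density (see the methods vignette). `plot_feature_space(ds)` shows the
labelled HNR–jitter plane with the threshold lines; `autoplot(fit)` shows
the loss history of a fit.

The parameter audit prints each layer's trainable-parameter count next to
the published reference summary it follows, flagging rather than resolving
that reference's internal inconsistencies:

```r
param_audit()
#>  2 Dense            64   1472  (reference 1472, match)
#>  3 Query Dense      64   4160  (reference 4160, match)
#>  ...
#>  6 Multi-Head Attention  4160  (reference 16512, FLAGGED)
#> model total (this implementation): 20353 trainable parameters
#> reference per-layer sum: 32705; reference reported grand total: 29697
```

A thin CLI wraps the same functions
(`Rscript inst/cli/voicerisk.R simulate|label|train|evaluate|param-audit|run`,
see `inst/extdata/experiment-example.yaml`). To run on a locally supplied
copy of the real UCI table instead of synthetic data, point
`experiment_config(input = "parkinsons.data", synth = NULL)` at the file:
the reader drops the `status` diagnosis flag (labels here are simulated,
not the PD diagnosis) and the rest of the pipeline is identical.

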