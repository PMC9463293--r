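# stiffsense

Tissue-stiffness classification from ultrasonic aspirator signal feedback.

During resection of soft brain tumors, an ultrasonic aspirator fragments
tissue with an oscillating tip. The generator driving the tip is
load-dependent, so its electrical state — nine feature channels sampled at
1000 Hz — carries information about the mechanical stiffness of the tissue
currently under the tip. `stiffsense` implements the full machine-learning
pipeline for the resulting binary problem (*very soft*, meningioma-like,
vs *soft*, healthy-brain-like) for researchers working on sensor-based
intraoperative tissue differentiation:

* a **synthetic recording generator** (idle–contact–idle phase structure,
  class-dependent channel baselines, contact drift, an injectable 1.2 Hz
  irrigation-like disturbance, broadband noise) so the whole pipeline is
  testable without proprietary lab recordings;
* two **noise-removal filters** — a third-order Butterworth low-pass
  (cutoff 0.75 Hz) and a second-order notch at 1.2 Hz (quality factor
  0.4) — realized as cascaded biquad sections and applied zero-phase;
* three **classifiers** under one probabilistic-prediction contract:
  a 100-tree Gini random forest baseline; an autoencoder-regularized
  fully connected network (encoder 9→32→9, mirrored decoder, classifier
  head 9→4→2) trained end to end with the combined loss
  `loss = CE(logits, y) + 0.3 · MSE(x̂, x)`;
  and a 1D residual CNN over sliding windows of 64 samples (stem 9→16
  channels + three stride-2 residual blocks 16→32→32→64, kernel 7, batch
  norm and dropout 0.3 after every convolution, global average pooling;
  seven convolutional layers in total, predictions attached to the last
  sample of each window);
* **recording-disjoint fivefold cross-validation** with a grouped
  87.5/12.5 train/validation split for the networks, and an experiment
  grid over classifiers × {raw, low-pass, band-stop} reporting macro F1,
  accuracy, PPV, TPR and AUROC as mean (sd) over folds.

Both networks are implemented in-package with explicit backpropagation
(convolutions compiled via Rcpp/RcppArmadillo) and are verified against
finite-difference gradients in the test suite.

## Worked example

Generate a smoke-scale dataset (2 tissue models per class, every recording
contaminated by the 1.2 Hz disturbance at amplitude 1.5), inspect the
low-pass filter, and compare raw vs low-pass preprocessing for the forest
and the network over recording-disjoint fivefold cross-validation:

```r
library(stiffsense)

cfg <- generator_config(n_models_per_class = 2, periodic_noise_fraction = 1,
                        periodic_noise_amplitude = 1.5, seed = 11)
ds <- generate_dataset(cfg)
ds
#> Tissue dataset: 20 recordings (soft=10, very_soft=10); 20000 per-sample rows

lp <- design_lowpass(0.75, 3, 1000)
round(filter_response(lp, c(0, 0.75, 1.2, 7.5)), 4)
#> [1] 1.0000 0.7071 0.2372 0.0010

tc <- train_config(max_epochs = 20, batch_size = 1024,
                   early_stopping_patience = 20)
grid <- run_experiment_grid(ds, classifiers = c("rf", "nn"),
                            filters = c("raw", "lowpass"), seed = 3,
                            train_cfg = tc)
grid
#> Experiment grid: rf/nn x raw/lowpass, 5 folds
#>   nn       lowpass   F1 0.863 (0.026)
#>   rf       lowpass   F1 0.797 (0.108)
#>   nn       raw       F1 0.518 (0.026)
#>   rf       raw       F1 0.605 (0.011)
```

The filter response shows unit DC gain, the −3 dB point at the cutoff,
and the 1.2 Hz disturbance attenuated to 0.24 (0.056 after zero-phase
application). On contaminated input the common-mode disturbance sits along
the class-informative direction, so per-sample classification of raw data
is near chance; low-pass preprocessing restores it — the network's mean F1
rises from 0.52 to 0.86, reproducing the direction of the reference
finding that low-pass filtering is the superior preprocessing step.

`summarize_grid(grid)` returns the full metric table;
`run_full_study(study_config(smoke = TRUE), "out/")` (or
`Rscript scripts/run_study.R --out out/ --smoke --seed 1`) runs the whole
study end to end and writes results, filter responses, training histories
and a provenance log.

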