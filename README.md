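# voxgan

Three-round adversarial transfer learning for volumetric image
classification, in pure R/C++.

Subject-level 3D CNNs for neuroimaging (e.g. classifying Alzheimer's
disease from gray-matter density maps) overfit badly because labeled
scans are scarce while the networks are large.  `voxgan` implements a
learning strategy that spends unlabeled data first:

1. **Round 1** — a 3D DCGAN (generator G + residual discriminator D) is
   trained adversarially on *all* volumes, labels ignored, until D's
   held-out real-vs-synthetic accuracy hovers around 50 % (approximate
   Nash equilibrium).  G maps a latent vector `z ∈ R¹⁰⁰`, `z ~ N(0, I)`,
   through a fully-connected reshape and four upsampling blocks to a
   volume in [0,1]; D stacks a convolution stem, four residual blocks
   (two stride-2 bottlenecks) and a dropout-regularised output block.
   Binary cross-entropy; Adam with learning rates 2·10⁻³ (G) / 2·10⁻⁴ (D);
   batch 16.
2. **Round 2** — D's output block is replaced by a three-layer
   classification head; stem + residual blocks 1–2 are frozen and the
   rest fine-tuned on the primary task with class-weighted binary
   cross-entropy (weights ∝ total/count per class, Adam 10⁻³).
3. **Round 3** — the round-2 convolutional weights transfer to secondary
   tasks under a fresh head, freezing only stem + residual block 1.

Performance is reported as accuracy = (TP+TN)/(TP+TN+FP+FN),
sensitivity = TP/(TP+FN), precision = TP/(TP+FP), and the trapezoidal
AUC; 3D Grad-CAM maps (rectified gradient-weighted channel sums,
averaged over cases predicted with p > 0.7) localise the regions the
classifier relies on.

Everything runs on a single CPU at "desk scale": a built-in phantom
generator emulates smooth, bounded-intensity brain-like volumes with
class-dependent intensity reduction in implanted "atrophy" loci, so the
whole pipeline — including freeze-depth, training-strategy and
sample-size ablation harnesses — is exercisable and testable without
any data download.  The 3D convolution/pooling/batch-norm engine and a
minimal NIfTI-1 reader/writer are implemented in the package (no deep
learning framework is required, or available, in this stack).

## A worked example

```r
library(voxgan)

cohort <- generate_cohort(phantom_spec(grid_size = 16, n_per_class = 30,
                                       effect_size = 0.6, seed = 1))
parts  <- split_subjects(cohort$labels$subject_id, c(7, 1, 2), seed = 1,
                         labels = cohort$labels$label)
spec   <- network_spec_desk(16)

gan <- fit_dcgan(build_generator(spec), build_discriminator(spec),
                 cohort$volumes[parts$partition != "validation"],
                 cohort$volumes[parts$partition == "validation"],
                 gan_control(epochs = 30, seed = 1))
gan
#> 3D DCGAN fit: 30 epochs, batch 16
#>   final losses: G 2.9706, D 0.2808
#>   held-out D accuracy, last-20-epoch mean: 0.954

cls <- to_classifier(gan$discriminator)
apply_freeze(cls, "through_rb2")
fit <- fine_tune(cls, cohort$volumes[parts$partition == "train"],
                 cohort$volumes[parts$partition == "validation"],
                 fine_tune_control(epochs = 15, seed = 1))
test <- cohort$volumes[parts$partition == "test"]
compute_metrics(predict(fit, test),
                vapply(test, function(v) v$label, integer(1)))
#> n = 12   TP 6  FP 0  TN 6  FN 0
#>   accuracy 100.0%   sensitivity 100.0%   precision 100.0%   AUC 100.0%
```

The first block prints the fitted GAN (a short 30-epoch, 16³ run — the
discriminator is still ahead of the generator at this budget; longer
32³ runs drift toward the 50 % equilibrium).  The metrics block is the
round-2 classifier's held-out confusion: on an easy phantom task
(intensity reduction δ = 0.6) the transferred classifier separates the
classes perfectly.

Ablation harnesses mirror the package's experimental claims:
`frozen_ablation()` (classification accuracy versus freeze depth),
`strategy_comparison()` (three-round training versus the same
architectures from scratch), `sample_size_sweep()` (accuracy as the
labeled training set shrinks), and `average_heatmap()` /
`export_heatmap()` for cohort saliency maps.  A thin command-line
wrapper lives at `inst/cli/voxgan.R` (subcommands `phantom`,
`preprocess`, `train-gan`, `run-pipeline`, `eval-metrics`, `saliency`),
driven by YAML configs with a single global seed.

## The acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the terminal
windowed discriminator accuracy of the desk-scale DCGAN: it generates a
phantom cohort of 100 volumes at 32³ (δ = 0.5), trains the 3D DCGAN for
200 epochs at batch 16 with the stated losses and optimizers, takes the
moving average of held-out discriminator accuracy over the final 20
epochs, averages over 3 seeds, and writes the result (in percent) as
JSON.
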