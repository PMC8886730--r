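# medusa

Multi-scale encoder-decoder self-attention for medical image
classification, in R.

Chest radiograph analysis has to cope with disease signatures that are
subtle (faint ground-glass opacities), highly variable within a disease,
and easily confounded by acquisition artifacts. Conventional
self-attention add-ons for CNN classifiers — squeeze-excite channel
gates, pooling-based spatial attention — are small isolated blocks with
no attentional context shared across scales. This package implements the
*single body, multi-scale heads* alternative: one high-capacity
U-Net-style encoder-decoder `G(x)` reads the input image and emits a
global attention map `A_G` at input resolution, and lightweight
scale-specific heads distribute that one map to every stage of a
convolutional backbone:

    A'_j = B_j(σ(A_G))         bilinear resize to the stage's spatial dims
    Ā_j  = C_j(A'_j)           one convolution to the stage's channels
    F̄_j  = Ā_j ⊗ F_j + F_j     residual multiplicative gating

with `σ` the elementwise logistic, `⊗` elementwise multiplication, and
`F_j` the backbone's stage-`j` feature map. Training uses the published
recipe: the encoder-decoder is pretrained on lung-field segmentation
(transfer learning), then the attention block and main network are
trained *alternately*, one frozen while the other learns. Sensitivity,
positive predictive value and accuracy reporting, ablation modes
(attention disabled; segmented input `s(x)`; additive `x + s(x)`), and
attention heat-map visualizations round out the pipeline.

Everything is testable offline: the package bundles a deterministic
synthetic radiograph phantom generator (elliptical lung fields, paired
binary masks, class-discriminative lung opacities, class-independent
off-lung distractor artifacts, and distortion modes). The numeric core is
self-contained — a small reverse-mode autodiff tape with C++ (Rcpp)
convolution/pooling/bilinear kernels — so no deep-learning framework is
required.

## Worked example

Generate a phantom dataset, pretrain the attention body on lung masks,
train the full classifier with alternating freezing, and evaluate:

```r
library(medusa)

spec <- phantom_spec(image_size = 64)
dir <- file.path(tempdir(), "phantoms")
manifest <- generate_dataset(200, 0.5, spec, seed = 0, out_dir = dir)

cfg <- run_config(image_size = 64, encdec_depth = 3, encdec_base_channels = 8,
                  backbone_channels = c(8, 16, 32), batch_size = 32,
                  learning_rate = 5e-4, epochs = 24)
ecfg <- encdec_config(depth = 3, base_channels = 8)

pre_samples <- lapply(1:64, function(i) generate_sample(spec, 1000 + i))
pre <- pretrain_encoder_decoder(pre_samples, ecfg, epochs = 10, seed = 0)
held <- lapply(1:32, function(i) generate_sample(spec, 2000 + i))
segmentation_dice(pre$params, ecfg, held)
#> [1] 0.9513598

model <- init_from_pretrained(build_model(cfg, "small_cnn", seed = 0), pre)
tr <- manifest[manifest$split == "train", ]
va <- manifest[manifest$split == "val", ]
train <- medusa:::load_manifest_samples(tr, dir, 64, with_masks = TRUE)
for (k in seq_along(train)) train[[k]]$label <- tr$label[k]
val <- medusa:::load_manifest_samples(va, dir, 64, with_masks = TRUE)
for (k in seq_along(val)) val[[k]]$label <- va$label[k]

fit <- train_alternating(model, train, val,
                         alternating_schedule(1, "main", 24), seed = 0)
evaluate(fit$best_model, manifest, dir = dir, split = "val")
#> metrics_report [model / dataset, mode full, n = 29]
#>   sensitivity 100.00%  ppv 85.71%  accuracy 93.10%
```

The held-out Dice of ~0.95 says the pretrained encoder-decoder has
learned the lung fields; the validation metrics say the attention-gated
classifier solves most of the phantom task (the same model with
`set_ablation(., "attention_disabled")` scores far lower — location
information enters only through the attention map); and `attention_panel(fit$best_model,
val[[1]]$image, "panel/")` writes the global heat-map overlay (red =
high attention, concentrated on the lungs) plus one normalized
attention-enforced activation map per backbone stage.

Metrics can also be re-derived from any published 2×2 table:

```r
cm <- cm_from_counts(tp = 195, fp = 2, tn = 198, fn = 5)
c(sensitivity(cm, decimals = 2), ppv(cm, decimals = 1), accuracy(cm, decimals = 1))
#> [1] 97.5 99.0 98.3
```

A command-line wrapper (`inst/cli/medusa`) exposes the same pipeline as
`generate`, `pretrain`, `train`, `evaluate` (with `--ablation`) and
`visualize` subcommands; every run writes a JSON run manifest.

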