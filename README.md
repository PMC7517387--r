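# vesselseg

Per-pixel segmentation of retinal blood vessels in fundus photographs, in
pure R. Vessels occupy only ~10–13% of a fundus frame, span widths of 1–8
pixels, and sit at low contrast against the background; `vesselseg`
implements an encoder–decoder convolutional network designed for exactly
that regime, together with every stage around it — preprocessing,
augmentation, training, evaluation — and a synthetic phantom generator so
the entire pipeline runs and is tested without clinical data.

The core model is a **multi-scale feature-fusion U-Net**:

* an encoder of inception-style multi-scale blocks (parallel 1×1, 3×3 and
  stacked-3×3 branches concatenated ¼ : ½ : ¼), channel width doubling at
  each 2×2 max-pool;
* a decoder with **dual skip connections**: the usual encoder feature-map
  concatenation, plus the max-pooling *indices* carried from encoder to
  decoder so upsampled values are placed back at their recorded argmax
  positions (index unpooling);
* a sigmoid head giving a vessel probability per pixel.

Training minimizes a cost-sensitive objective

```
J = α · Dice(p, y) + (1 − α) · CE_w(p, y) + λ/2 · Σ W²
```

where the weighted cross-entropy `CE_w` charges a vessel pixel predicted
as background (p ≤ 0.5) a penalty weight of 1 + 6 — the class-imbalance
countermeasure that keeps the rare vessel class from being ceded to the
background. A classic U-Net builder, CLAHE preprocessing (tile-clipped
histogram equalization with bilinear blending), paired rotate / mirror /
shift / crop augmentation, and Sen/Spe/Acc/ROC-AUC metrics complete the
toolbox. The CNN engine itself (convolutions as shifted GEMMs, batch
norm, index pooling, SGD) is part of the package, built on
RcppArmadillo — no external deep-learning framework is required.

## Worked example

Generate phantoms, train a small network, and evaluate it:

```r
library(vesselseg)

train <- lapply(1:32, function(s)
  generate_phantom(phantom_spec(size = 128, seed = s)))
val <- lapply(101:108, function(s)
  generate_phantom(phantom_spec(size = 128, seed = s)))

cfg <- train_config(lr_init = 0.5, lr_decay_factor = 0.1,
                    lr_decay_every = 20, batch_size = 8, epochs = 30,
                    momentum = 0.9, seed = 1,
                    network = network_spec(depth = 2, base_channels = 16))
model <- train_segmenter(train, cfg, val_pairs = val, verbose = TRUE)
#> epoch   1  lr 0.5  loss 0.6123  val_dice 0.5648
#> ...
#> epoch  30  lr 0.05  loss 0.0862  val_dice 0.9633

evaluate_dataset(model, val[1:4])
#>            id       sen       spe       acc       auc
#> 1 phantom0101 0.9849116 0.9964580 0.9946636 0.9996393
#> 2 phantom0102 0.9866255 0.9961627 0.9946636 0.9996335
#> 3 phantom0103 0.9748458 0.9975636 0.9936934 0.9997000
#> 4 phantom0104 0.9308943 0.9973077 0.9867400 0.9980797
#> 5      pooled 0.9692734 0.9968698 0.9924402 0.9992269
```

Each row is one held-out phantom; `sen` is the fraction of vessel pixels
recovered, `spe` the fraction of background kept, `acc` overall pixel
agreement, and `auc` the area under the ROC curve of the probability map
(1.0 = vessels perfectly ranked above background). The `pooled` row sums
confusion counts over images before computing rates. On these phantoms
the small network recovers ~97% of vessel pixels at ~99.7% specificity
in a few minutes on one CPU.

Predict on a single image and write the mask:

```r
res <- predict(model, preprocess_image(val[[1]]$image))
write_mask(res$mask, "mask.png")
```

A command-line front end wraps the same functions
(`inst/cli/vesselseg`): `make-phantoms`, `preprocess`, `augment`,
`train`, `predict`, `evaluate`, `summary`.

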