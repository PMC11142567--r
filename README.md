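# ultraseg

Residual attention U-Net for segmenting tumors in breast ultrasound
images, implemented natively in R.

Breast ultrasound shows tumors as hypoechoic (darker-than-tissue) regions
buried in speckle, and delineating them pixel-by-pixel is a standard
computer-aided-diagnosis task. `ultraseg` provides a complete, tested
implementation of an attention-gated residual U-Net for this task:

* **Network** — a residual U-Net (3×3 conv + batch norm + ReLU blocks with
  identity shortcuts, 2×2 stride-2 downsampling, transposed-convolution
  upsampling, sigmoid head) for 128×128 grayscale inputs.
* **PCBAM skip gating** — each skip connection passes through a positional
  convolutional block attention module: the sum of CBAM (per-channel gate
  `σ(mlp(gap F) + mlp(gmp F))` followed by a per-pixel gate from a 7×7
  dilation-4 convolution of channel-pooled maps) and a position attention
  module (softmax affinity `s_ji = softmax_i(B_i · Z_j)` over all pixel
  pairs, output `α Σ_i s_ji D_i + F_j` with learnable `α` starting at 0).
* **SWA bottleneck block** — per-position query/key/value projections
  fused by a 1×1 convolution and added residually.
* **Objective** — Dice + binary cross-entropy + focal loss (α = 0.25,
  γ = 2) on soft confusion counts, with per-component weights for loss
  ablations.
* **Evaluation** — Dice, IoU, accuracy, precision, recall per image and
  aggregated (per-image mean and micro-pooled).
* **Data** — a seeded synthetic ultrasound-phantom generator (speckled
  background, one hypoechoic star-convex lesion, exact masks), a
  BUSI-layout PNG loader (`<root>/<class>/<name>.png` +
  `<name>_mask*.png`), 70/10/20 and k-fold splitting.
* **Tooling** — Adam training loop with seeded reproducibility and
  best-validation checkpointing, activation heatmap export, and an
  `ultraseg` command-line interface (`inst/cli/ultraseg`).

There is no deep-learning framework underneath: forward and backward
passes of every layer are implemented in the package (R linear algebra
plus two compiled kernels for the pixel-pair attention and convolution
inner loops), which keeps the whole method inspectable and testable
against brute-force oracles. The five ablation variants of the
architecture — plain residual U-Net, +PAM, +CBAM, +PCBAM, +PCBAM+SWA —
are all buildable through `model_config()`.

## Worked example

Train a small model on synthetic phantoms and evaluate it on held-out
phantoms:

```r
library(ultraseg)

cfg <- run_config(
  model = model_config(depth = 3, base_filters = 8,
                       attention_mode = "cbam", use_swa = TRUE, seed = 7),
  data  = phantom_config(n_images = 24, seed = 42),
  learning_rate = 1e-3, epochs = 45, batch_size = 8, seed = 42,
  split = c(0.70, 0.10, 0.20), stop_dice = 0.95,
  output_dir = "run"
)
res <- train_model(cfg, verbose = TRUE)
#> run seed=42 | R 4.3.3 | 18 train / 2 val images
#> epoch   1 | loss 1.5900 | train dice 0.2951 | val dice 0.3289 | 26.6s
#> epoch   2 | loss 1.4069 | train dice 0.3572 | val dice 0.4419 | 14.2s
#> ...
#> epoch  23 | loss 0.2388 | train dice 0.9197 | val dice 0.9701 | 11.0s
#> epoch  24 | loss 0.2719 | train dice 0.8988 | val dice 0.9557 | 12.3s
#> epoch  25 | loss 0.1897 | train dice 0.9542 | val dice 0.9600 | 10.9s
#> early stop: training dice 0.9542 reached target 0.95
#> best epoch 23 | train dice (inference) 0.9564

pairs <- generate_phantom_dataset(phantom_config(n_images = 24, seed = 42))
test  <- split_dataset(pairs, c(0.70, 0.10, 0.20), seed = 42)$test
report <- evaluate_dataset(res$model, test)
report$summary
#>        granularity      dice       iou  accuracy precision    recall
#> 1 mean_over_images 0.9584111 0.9206232 0.9889374 0.9455731 0.9717390
#> 2     micro_pooled 0.9638278 0.9301810 0.9889374 0.9487280 0.9794159
```

The aggregate rows read: on the four held-out phantoms the predicted
masks overlap the ground truth with Dice ≈ 0.96 (IoU ≈ 0.92), 98.9% of
pixels are labeled correctly, and about 95%/97% of predicted/true tumor
pixels are right (precision/recall). `run/` contains the checkpoint,
per-epoch history, resolved config and log. Heatmaps of the attention
taps (`F_a`, `F_b`, bottleneck `F_c`, per-skip attention, SWA) can be
written with `export_heatmaps(res$model, test[[1]], "heatmaps")`.

The same pipeline is available from a shell:

```sh
inst/cli/ultraseg init-config   --out run.yaml
inst/cli/ultraseg make-synthetic --out data --n 100 --seed 1
inst/cli/ultraseg train         --config run.yaml --out run
inst/cli/ultraseg evaluate      --checkpoint run/checkpoint.rds --data data --out run/eval
inst/cli/ultraseg predict       --checkpoint run/checkpoint.rds --input data/synthetic --out run/pred
inst/cli/ultraseg heatmaps      --checkpoint run/checkpoint.rds --image data/synthetic/synthetic_0001.png --out run/maps
```

To use real data instead of phantoms, point `data` (or the config's data
path) at a BUSI-layout directory; images are converted to grayscale and
resized to 128×128, masks are unioned, nearest-neighbor resized and
re-binarized.

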