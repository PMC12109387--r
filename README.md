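# toothseg

Semantic segmentation of intraoral-scanner (IOS) dental arches: every point
of a surface scan is labelled as gingiva or as one of the 32 permanent
teeth in FDI notation (33 classes; positions 1–8 per quadrant map to tooth
types T1–T8). The package is aimed at orthodontic image-analysis work —
aligner design, treatment simulation, progress monitoring — where
segmentation quality degrades exactly in the hard cases: crowded incisors,
missing teeth, malformed crowns and partially erupted third molars.

## The model

Scanner meshes (STL/PLY/OBJ) are surface-sampled into point clouds,
normalized to $[-1,1]^3$, and reduced to $m = 2048$ center points by
farthest point sampling. Each center's $k = 64$ nearest neighbours are
encoded *relatively*: neighbour $j$ of center $i$ contributes
$[\,r_{ij},\, d_{ij},\, p_j\,]$ with $r_{ij} = p_j - p_i$ and
$d_{ij} = \lVert r_{ij}\rVert_2$. A shared point-wise MLP (32–64–128,
linear→batch-norm→ReLU) followed by max pooling over the neighbourhood
yields local features $L_i$; an 8-head self-attention branch
($A = \mathrm{softmax}(QK^\top/\sqrt{d_h})$, $Z = AV$, 8×32 = 256 channels)
captures long-range dependencies along the arch; attention pooling
($\alpha = \mathrm{softmax}(Zw)$, $g_{att} = \sum_i \alpha_i Z_i$) and
channel-wise soft pooling summarize the arch globally. The fused per-center
vector $[L_i, Z_i, g_{att}, g_{soft}, p_i]$ passes through a per-center
head, and predictions return to the full cloud by feature propagation
(inverse-distance interpolation over the 3 nearest centers plus a shared
point-wise classifier). Training minimizes mean per-point cross-entropy
with Adam (lr $10^{-4}$, batch 16, up to 200 epochs, early stopping),
with rotation/scale/translation augmentation. Metrics follow the standard
segmentation set: OA, mAcc, mIoU, mDice, per class and per tooth type.

Because clinical IOS datasets are private, the package ships a synthetic
generator: superquadric crowns on a parabolic arch with a swept gingival
ridge, covering five scenario types (normal, crowded, missing tooth,
malformation, partial eruption). The full pipeline — generate, train,
predict, evaluate — runs on one desktop CPU.

## Worked example

```r
library(toothseg)

# a labelled synthetic arch (lower jaw, 8192 points), normalized
cl  <- generate_arch(arch_spec(scenario = "crowded", jaw = "lower", seed = 7))
ncl <- normalize_cloud(cl)$cloud

# preprocessing: FPS centers, k-NN groups, relative encoding
enc <- preprocess_cloud(ncl, num_centers = 256, k = 16)
enc$m
#> [1] 256
dim(enc$features)
#> [1] 4096    7

# a freshly initialized small model segments (untrained, so labels are noise)
model <- init_model(small_model_config(), seed = 1)
seg   <- segment(ncl, model)
seg
#> segmentation_output: 8192 points, 33 classes; 2 distinct predicted labels

# train on a small synthetic dataset and evaluate
ds     <- generate_dataset(24, seed = 1, points_per_cloud = 2048)
clouds <- lapply(ds$clouds, function(x) normalize_cloud(x)$cloud)
sp     <- split_dataset(24, seed = 1)
fit    <- train_model(clouds[sp$train], clouds[sp$val],
                      small_model_config(),
                      train_config(learning_rate = 3e-3, batch_size = 1,
                                   max_epochs = 8, patience = 8,
                                   augment = FALSE, seed = 1))
fit
#> toothseg_fit: 8 epochs (best epoch 8)
#>   final: train_loss 1.1680  val_loss 1.1308  val_mIoU 0.2749
#>   best val mIoU: 0.2749

cm <- Reduce(`+`, lapply(clouds[sp$test], function(x) {
  unclass(confusion_matrix(segment(x, fit$model)$labels, x$labels))
}))
compute_metrics(cm)$overall$OA
#> [1] 0.582194
```

The printed numbers above were produced by this code (8 epochs on 16
training clouds — a smoke-scale run; the bundled desk-scale protocol in
`desk_protocol()` trains longer on 200 arches and reaches a held-out
tooth-vs-gingiva IoU around 0.95). `plot_cloud(ncl)` shows the labelled
arch in occlusal view; `plot_history(fit)` the training curves.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/toothseg.R synth  --config cfg.yaml --out data/ --seed 1
Rscript inst/cli/toothseg.R train  --config cfg.yaml --data data/ --out run/ --seed 1
Rscript inst/cli/toothseg.R predict --checkpoint run/checkpoint.rds --input data/ --out pred/
Rscript inst/cli/toothseg.R eval   --pred pred/ --ref data/ --out eval/
```

Ablation switches `--no-rel-encoding`, `--no-attn-pool`,
`--no-transformer` disable the three architectural contributions
individually.

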