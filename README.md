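# fgrec — fine-grained image recognition with a graph attention pyramid

`fgrec` is an R toolkit for **fine-grained species recognition**:
telling apart visually similar subcategories (bird species being the
canonical case) that share a global appearance and differ only in small
local parts — beak size and color, wing stripes, an eye ring. It also
handles the detection side of the same field problem: several small,
possibly occluded targets per cluttered scene. Everything runs on one
CPU with no external datasets and no deep-learning runtime; a built-in
synthetic bird generator provides deterministic, genuinely fine-grained
data for development and testing.

## What is inside

**Classifier.** A cross-stage partial (CSP) backbone — each stage splits
into a processed branch `XBase = Fbase(f1x1(X))` and a shortcut branch
`XCross = f1x1(X)`, concatenated, channel-shuffled and downsampled,
`X~ = Fdown(S(XBase, XCross))` — exposes stage-2/3/4 feature maps. A
**cross-stage trilinear attention** (CTA) module turns each stage map
into per-part spatial attention:

    Fc = N(M((1/WH) X^T phi(X)))     (channel relation, C x C)
    Fd = N(M(Fc^T phi(X)))           (one attention map per channel)

with `M` the signed square root and `N` softmax normalization. Applying
CTA at stages k = 2, 3, 4 gives an attention pyramid over part scales.
A **graph-based feature embedding** (GFE) pools part descriptors under
the attention maps, connects them by cosine similarity (`A~ = A + I`),
propagates one graph-convolution layer
`G = ReLU(D^(-1/2) A~ D^(-1/2) K W)`, and fuses levels with adaptive
attention into `C = sum_m I_m softmax(head_m(G_m))`.

**Detector.** A minimal grid-anchor head on stage-3 features trained
with objectness BCE + class cross-entropy + **CIoU** box loss
(`loss = 1 - IOU + rho^2/c^2 + alpha v`), post-processed with
linear-decay **Soft-NMS** (`S_i <- S_i (1 - IOU)` above the overlap
threshold `Nt` instead of deletion), which recovers overlapping objects
that hard NMS suppresses.

**Metrics.** Accuracy, precision, recall, all-point-interpolated AP,
confusion matrices (rendered as heat maps).

**Synthetic data.** Parametric species libraries whose continuous traits
contract as a similarity dial approaches 1 while discrete part traits
(stripes, eye ring, beak length) stay distinct; crop and multi-instance
scene renderers with YOLO-format ground truth; byte-identical under a
seed.

See `vignettes/methods.Rmd` for the model details, design decisions and
limitations (notably: the backbone is a frozen random-feature extractor;
training updates the graph embedding and heads).

## Worked example

Generate the standard toy world (8 species at similarity 0.9, 64x64
crops, 100 train / 10 validation per class), then run the ablation
harness, which trains four variants under one seed and budget:

```r
library(fgrec)
cfg <- fgr_config("ablate", data_dir = "data", out_dir = "run", seed = 1L)
fgr_generate(cfg, "classification")
fgr_ablate(cfg)
```

Output (seed 1):

```
       variant val_acc
1 backbone_gap  0.4875
2          cta  0.6750
3          gfe  0.9625
4      cta_gfe  0.9125
```

Reading: a linear head on globally averaged backbone features
(`backbone_gap`) gets 49% — global statistics barely separate the
classes, which is what "fine-grained" means. Attention-pooled part
features (`cta`) lift that to 68%; embedding part descriptors through
the similarity graph (`gfe`, `cta_gfe`) reaches 91–96%, because the
discriminative signal lives in part-level structure that pooling alone
discards. The full pipeline equivalents:

```r
cfg <- fgr_config("classify", data_dir = "data", out_dir = "run", seed = 1L)
fit <- fgr_train_classifier(cfg)
fit$best_acc          # validation accuracy of the full model
ev <- fgr_evaluate_classifier(fit$checkpoint, cfg)  # ACC + confusion.ppm
```

Detection, end to end on crowded synthetic scenes:

```r
cfg <- fgr_config("detect", data_dir = "data", out_dir = "run", seed = 3L)
fgr_generate(cfg, "detection")
det <- fgr_train_detector(cfg)
fgr_evaluate_detector(det$detector, cfg, nms = "soft")   # P / R / AP
fgr_evaluate_detector(det$detector, cfg, nms = "hard")
```

On overlapping-object scenes the soft-NMS recall is at least the hard-NMS
recall at the same score floor — the motivating property, asserted in the
acceptance suite.

There is also a command-line front end (`exec/fgrec`):

```sh
Rscript exec/fgrec generate --data_dir data --seed 1
Rscript exec/fgrec train-cls --data_dir data --out_dir run --seed 1
Rscript exec/fgrec evaluate --data_dir data --out_dir run --what cls
Rscript exec/fgrec ablate --data_dir data --out_dir run
Rscript exec/fgrec heatmap --image data/cls/test/species_00/crop_0003.ppm --out run/hm
```

`heatmap` writes attention-mass overlays per pyramid level
(`heatmap_level{2,3,4}.ppm`), the standard qualitative check that the
attention concentrates on object parts rather than background.

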