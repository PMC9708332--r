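# hovseg: nuclear instance segmentation and classification

Accurate nuclear instance segmentation and classification in H&E
histopathology tiles is the basis of quantitative pathology: counting
nuclei by type, measuring their morphology, and mapping their spatial
arrangement. Two things make it hard: nuclei of different classes look
alike, and nuclei cluster and touch, so a semantic foreground mask is not
enough — touching instances must be separated.

`hovseg` implements a three-branch deep network plus a classical
marker-controlled watershed that together solve both problems, and a full
evaluation suite to measure how well. It is aimed at image-analysis
researchers who want every stage of this pipeline — target encoding,
architecture, loss, post-processing, metrics — available and testable in R
without a GPU or external datasets.

## The model

Given an RGB tile, a shared encoder feeds three structurally identical
decoder branches:

* **NP branch** — per-pixel nuclear probability `q` (2-class softmax);
* **HV branch** — per-pixel horizontal and vertical distances
  `(p_x, p_y)` to the owning nucleus's centroid, rescaled per instance to
  `[-1, 1]`;
* **NC branch** — per-pixel class probabilities over `C` nuclear types
  plus background.

The encoder is a pre-activated ResNet-50 (units 3/4/6/3, total
downsampling 8) with parameter-free SimAM attention after each residual
block, followed by a 12-layer Transformer (D = 768) over the 33 x 33
feature-map positions and a DecoderCup projection back to a spatial map.
For a 270 x 270 input the stage shapes are

```
residual blocks : (256, 264, 264) (512, 132, 132) (1024, 66, 66) (2048, 33, 33)
transformer     : 1089 tokens x 768
decoder cup     : (1024, 33, 33)
branch outputs  : (2 | 2 | C+1, 80, 80)
```

Training minimizes `L = λ_a l_a + λ_b l_b + λ_c l_c + λ_d l_d + λ_e l_e +
λ_f l_f` (defaults `λ_b = 2`, rest 1): MSE and foreground-masked
Sobel-gradient MSE on the HV maps, cross-entropy and soft Dice on the NP
and NC branches. The schedule trains the decoder first (trunk and
Transformer frozen), then fine-tunes everything, Adam with learning rate
1e-4 dropping to 1e-5.

Inference separates touching nuclei from the HV maps: the Sobel gradient
magnitude of `p_x` and `p_y` is maximal on inter-nucleus boundaries;
thresholding gives the energy landscape `E = (1 - τ(S_m, k)) ⊙ τ(q, h)`
and markers `M = σ(τ(q, h) - τ(S_m, k))`; a marker-controlled watershed
floods `E` to assign every foreground pixel to one nucleus; a majority
vote over the NC probabilities types each instance.

Evaluation implements DICE, the Aggregated Jaccard Index (AJI), detection
/ segmentation / panoptic quality (DQ, SQ, PQ with IoU > 0.5 matching),
and overall plus per-class F1.

Because no R deep-learning framework is assumed, the network runs on a
small reverse-mode autodiff engine included in the package (BLAS-backed
convolutions); a synthetic-scene generator provides labelled
histology-style tiles so the whole pipeline is exercisable end to end.

## Worked example

```r
library(hovseg)

scene <- generate_scene(256, 256, 30, n_types = 4, overlap_fraction = 0.5,
                        noise_sd = 0.01, seed = 7)
stack <- ideal_prediction_stack(scene, blur_sd = 1.0)   # oracle predictions
seg   <- postprocess_stack(stack, postprocess_params(h = 0.5, k = 0.4))
report <- evaluate_panoptic(scene$instances, seg$instances,
                            scene$types, seg$types)
print(report)
```

```
Panoptic report: DICE 0.9972 | AJI 0.9909 | DQ 1.0000 | SQ 0.9896 | PQ 0.9896
  instances: truth 30 | predicted 30 | matched 30 
  detection F1 1.0000 | per-class F1: 1=1.000 2=1.000 3=1.000 4=1.000
```

All 30 nuclei — half of them placed touching a neighbor — are recovered
as separate instances from blurred oracle maps (DQ = 1), with mean
matched IoU 0.99 (SQ) and every nucleus correctly typed. On real trained
predictions these numbers are much lower; here they isolate the
post-processing stage itself.

Model building and the training loop:

```r
model <- build_model(seed = 1)        # full-width: ~150 M parameters
model_summary(model, 270)             # per-stage shape table

tiny  <- build_model(trunk_config(width = 4, input_size = 198),
                     transformer_config(n_layers = 1, embed_dim = 32,
                                        n_heads = 4, mlp_dim = 64))
run   <- run_training(tiny, scenes, smoke_train_config())
```

A thin command-line interface wrapping these functions is installed at
`system.file("cli", "hovseg.R", package = "hovseg")` with subcommands
`generate`, `encode-targets`, `postprocess`, `evaluate`, `train-smoke`
and `remap-labels`.

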