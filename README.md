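# dilatedskinnet

Automatic segmentation of skin lesions in dermoscopic images with a fully
convolutional, pooling-free network built from **atrous (dilated)
convolutions** — an R implementation of DilatedSkinNet, written for
researchers in medical image analysis who want the architecture, its
training recipe and its evaluation metrics as inspectable, testable code
rather than a framework checkpoint.

## The model

The network labels every pixel of a `192x256` RGB dermoscopy image as
*lesion* or *background*. Sixteen convolutional layers in five blocks keep
the full spatial resolution throughout (stride 1, same padding, no
pooling); context is gathered by dilating the `3x3` kernels, i.e. spacing
their taps `r` pixels apart:

```
C[i] = sum_s I[i + s*r] * K[s]        (r = 1 is standard convolution)
```

The dilation schedule `1, 2, 4, 4, 6, 8, 8, 10, 10, 12, 12, 12, 14, 14, 14`
(with interleaved `1x1` channel-reduction layers) grows the receptive field
to `179x179` with only 329,570 learnable parameters. Every layer except the
final `1x1` classifier is followed by batch normalization
(`epsilon = 5e-5`) and leakyReLU (slope `0.1`); a pixelwise softmax feeds
the segmentation argmax. Training minimizes a class-weighted cross-entropy
(inverse-frequency weights) with SGD + momentum: batch 16, learning rate
0.01, momentum 0.9, L2 0.005.

Evaluation uses the pixel confusion matrix per image:
`ACC = (TP+TN)/total`, `JAC = TP/(TP+FP+FN)` (Jaccard index / IoU) and
`DICE = 2TP/(2TP+FP+FN)`, averaged over images.

Because benchmark dermoscopy datasets cannot ship with a package, a
**synthetic phantom generator** renders dermoscopy-like images with exact
ground truth: star-convex lesion blobs with irregular Fourier-perturbed
borders, darker/warmer than the skin tone, overlaid with hairline curves,
gel bubbles, illumination gradients and low contrast. The whole pipeline —
generate, train, evaluate — runs offline and seeded.

## Worked example

```r
library(dilatedskinnet)

## the architecture as data
spec <- dilatedskinnet_spec()
receptive_field(spec)
#> height  width
#>    179    179
count_parameters(spec)$total
#> [1] 329570

## phantoms with ground truth, rendered at 48x64 and downsized (the
## pipeline's own nearest-neighbor preprocessing) to a 24x32 working
## resolution for a CPU-scale run
ds <- generate_dataset(366, phantom_params(image_size = c(48, 64)),
                       seed = 4242)
ds <- lapply(ds, resize_sample, target = c(24, 32))

net <- build_network(spec, input_size = c(24, 32), seed = 4243)
cfg <- train_config(input_size = c(24, 32), epochs = 30, seed = 4244)
fit <- train(net, ds[1:256], val_set = ds[257:366], config = cfg,
             verbose = TRUE)
#> epoch 1/30  loss 0.3540  val JAC 0.3210
#> epoch 2/30  loss 0.1970  val JAC 0.5082
#> ...
#> epoch 30/30  loss 0.0449  val JAC 0.7820

evaluate(fit$model, ds[257:366])
#> Evaluation over 110 images: ACC 0.9591  JAC 0.7820  DICE 0.8752
```

In about twelve minutes of single-CPU training the pipeline demonstrably
learns figure–ground segmentation under hair/bubble/illumination
nuisances: the training loss falls to 13% of its initial value and the
predicted masks overlap the true phantom lesions at 0.78 mean
intersection-over-union. The residual errors are almost entirely a
one-pixel over-segmentation ring (the inverse-frequency class weights
favor lesion recall), which at this tiny working resolution is an
appreciable fraction of a lesion's area — mean JAC rises with resolution
and with lesion size. (The published ISIC benchmark scores require the
real challenge datasets and GPU-scale training; they are out of scope
here.)

A command line wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dilatedskinnet.R", package = "dilatedskinnet"))')
Rscript $CLI report-arch
Rscript $CLI generate --n 16 --seed 7 --out phantoms --height 192 --width 256
Rscript $CLI train --data phantoms --epochs 10 --height 24 --width 32 --out ck.rds
Rscript $CLI eval --checkpoint ck.rds --data phantoms --out scores
```

## Package layout

| Where | What |
| --- | --- |
| `R/core-ops.R` | reference numerics: `atrous_convolve()`, `batch_normalize()`, `leaky_relu()`, `weighted_cross_entropy()`, `sgdm_step()` |
| `R/architecture.R` | the layer table as data, shape/parameter/receptive-field reports |
| `R/network.R` | runnable model: initialization, im2col forward/backward |
| `R/metrics.R` | confusion counts, ACC/JAC/DICE, per-image aggregation |
| `R/phantom.R` | phantom generator, nearest-neighbor resize, affine augmentation |
| `R/pipeline.R` | `train()`, `predict_mask()`, `evaluate()`, checkpoints |
| `R/cli.R` + `inst/cli/` | command-line interface |
| `vignettes/` | methods vignette: model, assumptions, parameter choices, limitations |
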