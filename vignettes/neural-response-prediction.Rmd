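---
title: "Decoding ANN activations into neural responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding ANN activations into neural responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpredict)
```

## The problem

How brain-like is an artificial neural network? One operational answer is
*neural predictivity*: if the network's internal activations, recorded while
it processes a stimulus, suffice to predict the firing rates that a
biological brain produces for the same stimulus, the two systems carry
similar information. The canonical setting is primate ventral-stream
electrophysiology: normalized firing rates from V4 and IT recording sites
while a macaque views natural images, paired with the activations an image
classifier computes on those images.

Earlier approaches score this correspondence with correlation measures,
which implicitly assume the activation-to-response relationship is linear.
Activations are themselves products of stacked nonlinear transformations,
and there is no layer-to-layer correspondence between a deep network and
cortex, so this package takes the opposite stance: fit an explicit
*nonlinear* decoder

$$\widehat{NR} = f\!\left(\bigcup_{i=1}^{L} \mathrm{Act}_i\right),$$

where $f$ is itself a small neural network trained on the recordings, and
report the *NRP-error*

$$\delta\!\left(\widehat{NR},\, NR_{\mathrm{measured}}\right)
  = \mathrm{mean}\,\bigl|\widehat{NR} - NR_{\mathrm{measured}}\bigr|,$$

computed separately per brain region and averaged (unweighted) into an
overall score. Lower NRP-error means higher neural predictivity.

## The decoder architecture

The decoder has exactly two intermediate layers before the output:

* **L1, locally dense.** Each source layer of the base network feeds its own
  block of units; there are no cross-layer weights at this stage. For two
  1000-unit source layers with 50 block units each, local density needs
  100,100 L1 parameters where a dense layer over the concatenation would
  need 200,100 — the halving matters because recording datasets are small
  (thousands of stimuli), and parameter economy is what makes the decoder
  trainable at all.
* **L2, dense.** The block outputs are concatenated and mixed.
* **Output, linear.** One unit per recording site. ReLU follows L1 and L2
  only; the output stays linear because a normalized rate may legitimately
  fall below the blank-gray baseline, i.e. be negative after normalization.

Adding further intermediate layers buys no accuracy at these data sizes,
which is why the depth is fixed at two and the search space is over widths,
input layers and learning rate instead.

## Training

The decoder is trained by mean squared error with Adam on mini-batches,
while the base network's weights stay frozen — the decoder consumes
precomputed activations and never backpropagates into the network being
scored. Note the deliberate asymmetry: MSE is the *training* loss, but the
*reported* metric is MAE, and validation MAE also drives both early
stopping and best-weight selection, since MAE is what the NRP-error
measures.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 1e-3 | Adam step size; grid searches span 1e-2–1e-4 |
| `batch_size` | 64 | mini-batch rows |
| `max_epochs` | 500 | epoch budget |
| `patience` | 20 | early-stop window on validation MAE |
| `lr_schedule` | constant | optional cosine annealing to 0.1% of the base rate |
| `n_restarts` | 1 | independent inits; best validation kept |
| split fraction | 0.8 / 0.2 | train / validation rows, seeded |

The last two deserve comment. Small ReLU networks fit to noise-free targets
routinely stall in poor local minima in a way that depends only on the
initialization draw; cosine annealing plus a handful of restarts is the
standard remedy and is used by the recovery experiments below. Both are off
by default because on noisy recordings (the realistic case) a single
constant-rate run with early stopping is already at the noise floor.

All stochasticity — initialization, the train/validation split, batch
shuffling, restarts — is controlled by explicit integer seeds, and every
pipeline stage is reproducible byte-for-byte from them.

## The linear baseline

The comparator is a multi-output affine map from the concatenated
activations to all sites, fit in closed form by normal equations with an
optional ridge penalty on the Gram diagonal (intercepts unpenalized,
handled by centering). The default penalty is `1e-3 * trace(Gram)/d`,
scale-aware and mild: concatenated activation dimension can exceed the
stimulus count, where plain least squares is singular. Setting
`ridge_lambda = 0` recovers plain regression whenever it is well posed.
The per-site $R^2$ of this baseline, computed on held-out rows, is the
diagnostic of linear insufficiency: when the true activation-to-response
map is nonlinear, held-out $R^2$ stays far from 1 no matter how much data
the linear fit sees.

Two decisions here were genuinely open. The baseline's regularization is
not specified in the setting this package models, so ridge is exposed with
a mild default and an exact λ = 0 mode; and $R^2$ is computed on held-out
rows (the conservative choice) rather than training rows.

## The synthetic ground truth

The generator replaces both external dependencies of the real experiment —
a pretrained image network and macaque recordings — with a controlled
truth:

* activations are i.i.d. standard Gaussian per layer (default geometry:
  3,200 stimuli, two source layers, 256 sites split 88 "V4" / 168 "IT",
  mirroring the canonical dataset's shape);
* responses are a known function of the activations — `linear` (inside the
  baseline's family) or `mlp` (a ReLU hidden layer, provably outside it) —
  plus Gaussian observation noise (default sd 0.1; no repeat-reliability
  figures exist for the real recordings, so this is a free parameter);
* output columns are rescaled so each site has unit-ish response spread,
  keeping MAE values interpretable as fractions of response variability,
  on the same numeric scale as published region errors (~0.2–0.4).

What the generator does **not** emulate: spiking dynamics, the 70–170 ms
averaging window, stimulus structure (images), correlated noise across
sites, and any real correspondence between layers and brain areas. Passing
recovery tests therefore demonstrates that the machinery — decoder,
training, metric, baseline, search, pruning harness — is correct and well
calibrated, not that any particular real network is brain-like.

Three properties anchor the test suite:

1. **Noise floor.** With linear truth and noise sd $\sigma$, the baseline's
   held-out MAE must approach $\sigma\sqrt{2/\pi}$, the mean absolute value
   of a centered Gaussian — with $\sigma = 0.05$, that is 0.0399.
2. **Realizable recovery.** Recordings generated by a random decoder-family
   model with zero noise must be recoverable by training a fresh
   same-architecture decoder to held-out MAE below 0.02 on a unit response
   scale. The packaged protocol uses a 10-d source layer, 16 + 16 hidden
   units, 5 sites, 3,200 stimuli, cosine-annealed lr 1e-2 over 800 epochs
   and 8 restarts: same-width teacher–student recovery is the hardest
   optimization case in the package, and the restarts are what make it
   reliable across seeds.
3. **Nonlinear separation.** With `mlp` truth (hidden width 64), zero
   noise, 3,200 stimuli and 256 sites, the decoder's held-out MAE must be
   at most 0.8× the linear baseline's. This is the package's central claim
   in miniature; in the packaged configuration the observed ratio is
   typically 0.05–0.25, and the baseline's held-out mean $R^2$ sits near
   0.75 — clearly short of a linear fit's 1.0, the qualitative signature
   that motivates a nonlinear readout. (A ReLU unit on Gaussian input
   keeps roughly three quarters of its variance in its best linear
   approximation, which is why $R^2$ lands there rather than lower.)

## Grid search and pruning harness

`grid_search()` enumerates the Cartesian product of input-layer subsets, L1
and L2 widths, and learning rates in a fixed order, trains each cell once
per seed from a fresh initialization, averages validation MAE across seeds,
and returns the full table plus the argmin (ties to the first cell; failed
cells are excluded but reported). Averaging over seeds before the argmin
keeps the selection from rewarding a lucky initialization.

`pruning_sweep()` measures how compressing the base network changes the
predictability of responses from its activations: at each sparsity level it
prunes the base network's weight matrices, re-extracts activations, trains
a fresh decoder under the identical protocol, and records the overall
held-out NRP-error. Pruning is **one-shot global magnitude pruning without
fine-tuning** — all weight entries ranked by absolute value across
matrices, the smallest `floor(s·n)` zeroed, biases exempt; stable
tie-breaking makes zero sets nested across levels. This is a deliberately
simple, fully specified scheme; production pruning pipelines (iterative,
fine-tuned) differ, so sweep *curves* from this harness characterize the
harness fixture, not any published network. For the same reason the
direction of the sparsity–error relationship is documented as a finding
where observed, never asserted as an invariant. The desk-scale base
network is a 3-layer ReLU perceptron trained on a seeded Gaussian-cluster
classification task, standing in for an image classifier.

## Numerical choices and degenerate inputs

* Weight init: fan-in-scaled Gaussian, sd $\sqrt{2/\mathrm{fan}}$ for
  ReLU layers, $\sqrt{1/\mathrm{fan}}$ for the linear output; biases zero.
* Non-finite training loss aborts with a diagnostic rather than continuing.
* Validation ties in best-epoch selection go to the earliest epoch.
* Zero-variance sites make $R^2$ undefined; they are dropped from the mean
  with a warning rather than silently propagating `NaN`.
* A region label with no sites is excluded from the report with a warning.
* An empty stimulus intersection in `align_by_stimulus()` is a hard error
  naming both ID-set sizes.
* Convolutional feature maps are mean-pooled per channel by default
  (`pool_spatial()`); very wide layers can additionally be compressed with
  a seeded Gaussian random projection (`reduce_dims()`, default target
  1024), chosen over PCA because it is fit-free, deterministic and
  reusable on validation rows. Both are conditioning conveniences for real
  activations; how such conditioning is done in the original setting is
  unspecified, and the synthetic experiments bypass it.

## Problem sizes

The packaged experiments are sized for a single CPU: the separation and
recovery experiments use the full 3,200-stimulus geometry (tens of seconds
to a few minutes each); unit fixtures use tens to hundreds of stimuli. The
pruning sweep fixture uses 600 stimuli and a 10-24-16-4 base network.

## Known limitations

* The decoder is a fixed two-intermediate-layer family; depth is not
  searched, by design.
* The pruning stand-in is not the iterative, fine-tuned pruning used to
  compress production networks.
* Adapters that extract activations from real pretrained model zoos are
  out of scope; the package consumes activation tables.
* Determinism is guaranteed within a BLAS/platform; bit-identity across
  different BLAS builds is not promised.
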