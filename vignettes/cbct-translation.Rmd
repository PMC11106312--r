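---
title: "Unpaired CBCT-to-CT translation: model, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired CBCT-to-CT translation: model, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctgan)
```

## The problem

Cone-beam CT (CBCT) is acquired in the treatment room during radiotherapy,
but its images carry cupping/shading fields, streaks, and noise that make
Hounsfield units unreliable. Because matched CBCT/CT pairs are hard to
obtain (patients move, anatomy changes between scans), the mapping from
CBCT-like images (domain A) to CT-like images (domain B) has to be learned
from *unpaired* collections. `cbctgan` implements a cycle-consistent
adversarial translator for this setting: two generators
\(G_{A\to B}, G_{B\to A}\), two patch discriminators \(D_A, D_B\), and a
loss family that constrains the translation without ever seeing a paired
example.

## The generator: a U-net with a transformer bottleneck

Each generator is a U-net. A stem convolution lifts the input slice to a
\((w_0, h_0, f_0)\) feature map; each of `encoder_depth` blocks (stride-2
3x3 convolution, LeakyReLU) halves the spatial dimensions and doubles the
channels; skip connections carry each level to the mirrored decoder stage.
At the bottleneck, the \(w \times h\) feature map is flattened **row-major**
(token \(t = \mathrm{row} \cdot w + \mathrm{col}\), 0-based) into a token
sequence of length \(w h\). Each token is concatenated with a 2-D Fourier
positional embedding — sines and cosines of the normalized row and column
coordinates at geometrically spaced frequencies \(2^k\), filling `fourier_dim`
channels — and linearly mapped to `token_dim`. A stack of
`transformer_depth` encoder blocks then alternates pre-norm multi-head
self-attention and a feed-forward network, each residual branch scaled by a
trainable **rezero** gate \(\alpha\) initialized to exactly zero, so the
whole stack is the identity map at initialization and the early training
dynamics are those of a plain convolutional U-net.

The feed-forward network is the method's distinctive piece: instead of a
plain MLP, tokens are re-gridded to their \(w \times h\) lattice
(`Seq2Img`), passed through a 1x1 expansion convolution, a 3x3 depth-wise
convolution, a GELU, and a 1x1 projection, then flattened back
(`Img2Seq`). The depth-wise convolution gives each token a local
neighbourhood exchange that complements the global attention. Both variants
are available (`ffn_variant = "dwconv"` or `"mlp"`); switching them is the
DCN ablation axis.

The decoder mirrors the encoder with nearest-neighbour upsampling followed
by convolution (chosen over transposed convolution to avoid checkerboard
artifacts), concatenating the matching skip at each level, and ends in a
3x3 convolution squashed by tanh, so outputs always live in \([-1, 1]\).

Defaults for the quantities the architecture description leaves open:
\(f_0 = 48\), `fourier_dim` 32, `token_dim` 384 with 6 heads, expansion 4,
3x3 depth-wise kernel, 12 transformer blocks at 256x256 input. All are
configurable; the reduced study below shrinks them deliberately.

## Discriminators

Each domain has a patch discriminator: `n_layers` stride-2 4x4
convolutions with LeakyReLU (channels doubling, capped at 8x the base
width), one stride-1 4x4 layer, and a 4x4 projection to a one-channel
realness map (with `n_layers = 3` the receptive field is the classic 70x70
patch). There are **no normalization layers**: the gradient penalty below
regularizes \(\lVert \nabla_x D \rVert\), and batch/instance normalization
would couple pixels and samples into that gradient.

## The loss family

With \(\ell_{\mathrm{GAN}}\) the least-squares classification loss (real
images labelled 1, generated 0; binary cross-entropy available via
`gan_form`) and \(\ell_{reg}\) an L1 regression loss by default:

* **Adversarial**: \(D_B\) scores \(G_{A\to B}(a)\) against label 1 in the
  generator objective; each discriminator scores real vs generated.
* **Cycle consistency** (\(\lambda_{cyc} = 10\)):
  \(\ell_{reg}(G_{B\to A}(G_{A\to B}(a)), a)\) and the mirror image.
* **Identity** (\(\lambda_{idt} = 0.5\)):
  \(\ell_{reg}(G_{B\to A}(a), a)\) for \(a \sim A\), and mirrored.
* **Pixel-wise consistency** (\(\lambda_{consist} = 1\)): L1 between
  bilinear 32x32 downsizings (a low-pass filter) of the source and its
  translation, anchoring coarse anatomy while leaving high-frequency
  artifact removal unconstrained. This is the PL ablation axis.
* **Gradient penalty** (\(\lambda_{GP} = 10\), \(\gamma = 1\)): each
  discriminator loss adds
  \(\lambda_{GP}\, \mathbb{E}\!\left[(\lVert \nabla_x D(x) \rVert_2 - \gamma)^2 / \gamma^2\right]\),
  the gamma-centred penalty, evaluated on both the real and the generated
  batch and averaged (the expectation's sampling distribution is not pinned
  down by the formula; regularizing where the discriminator actually
  operates is the stabler reading). This is the GP ablation axis.

The generator total per direction is
\(\mathcal{L}_{GAN} + \lambda_{cyc}\mathcal{L}_{cyc} + \lambda_{idt}\mathcal{L}_{idt} + \lambda_{consist}\mathcal{L}_{consist}\).

One notational wrinkle: the direction-A adversarial generator term is
written in some accounts as \(D_A(G_{A\to B}(x))\) — a domain-B image scored
by the domain-A discriminator. The package scores \(G_{A\to B}(x)\) with
\(D_B\), consistent with how the discriminator losses are defined.

## Training loop and the gradient of the penalty

The update schedule is 5:1: each training step performs five generator
updates, each on freshly drawn batches, then one discriminator update.
Optimization is Adam (betas 0.5/0.99), learning rate `1e-4` at full scale.
Batch size defaults to 5 and epochs to 200, the full-scale settings.

Networks are trained by a small reverse-mode autodiff engine built into the
package (R tape, C++ convolution/resize kernels). The engine is
first-order; the gradient penalty, whose *training* gradient needs the
derivative of an input-gradient, is handled by constructing
\(\nabla_x D(x)\) itself as a graph of transposed convolutions with the
LeakyReLU derivative masks held constant — piecewise-linear networks make
this almost-everywhere exact, and it is the same treatment mainstream
autodiff frameworks apply. The unit tests verify the penalty value and its
weight gradients against finite differences.

Checkpoints store raw parameter arrays plus the architecture configuration
and its hash; loading verifies the hash so weights can never silently enter
a mismatched model. With zero learning rates a training step leaves every
parameter bit-identical, and fixed seeds make runs bit-reproducible on one
device — both are tested.

## The synthetic phantom generator

No public CBCT/CT corpus backs this package, so it ships a seeded phantom
simulator that emulates the study conditions end to end. A CT-like phantom
is a piecewise-constant image: air background (-1000 HU), an elliptical
soft-tissue body, and internal ellipses drawn from configurable intensity
classes (air cavities, soft tissue ~40 HU, bone ~700 HU). The CBCT
degradation applies, in order: Gaussian blur (sigma 0.8 px), a quadratic
radial cupping bowl (0 at the corners, -120 HU at the centre), eight
full-width one-pixel streaks with amplitudes uniform in +-80 HU, and white
Gaussian noise (sigma 50 HU). Training CBCT images additionally get a small
rigid misalignment (<= 2 px, <= 1 degree) to emulate setup differences;
test pairs are generated aligned. The magnitudes are chosen to resemble the
artifact burden reported for clinical cone-beam systems — shading of order
100 HU, noise of a few tens of HU — not calibrated to any particular
scanner.

Randomness is consumed in a fixed documented order (body geometry, then
per-structure parameters; streaks, then noise), so datasets are
bit-reproducible from `(spec, seed)` and adding parameters later cannot
silently shift existing seeds. Body masks emulate clinician contours by
thresholding at -500 HU, keeping the largest connected component, and
filling internal holes (a body outline includes internal air).

What the phantoms do **not** emulate: physically accurate scatter and
beam-hardening, cone-beam reconstruction geometry, anatomical texture, and
organ deformation. A model that passes the phantom study has demonstrated
that the full optimization machinery works and that the degradations it saw
can be undone; it says nothing about clinical image quality.

## Preprocessing and metrics

Images are masked (outside-body pixels read as air, not 0 HU), normalized
to \([-1, 1]\) by an affine window (default -1000..1000 HU, wide enough to
cover the -500..500 HU band usually analysed, with headroom for bone), and
resized bilinearly (half-pixel-centre convention: constants stay constant;
resizing to the same size is the identity).

Evaluation on aligned pairs reports MAE, PSNR, and SSIM, by default inside
the body mask and in HU-like units. Two PSNR conventions are exposed:
`standard` (\(10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})\), the default) and
`as_printed` (\(20\log_{10}(\mathrm{MAX}/\mathrm{MSE})\), dividing by the
MSE rather than the RMSE), because the second form circulates in the
literature this package follows; MAX defaults to the maximum synthetic-CT
pixel, also configurable. SSIM uses an 11x11 Gaussian window (sigma 1.5)
over valid positions with the community constants
\(c_1 = (0.01L)^2, c_2 = (0.03L)^2\); a global single-window variant is
available. Histogram (-500..500 HU), per-axis mean-intensity profiles, and
rainbow-mapped difference images mirror the usual visual summaries.

## The reduced reference study

`run_phantom_study()` is the package's end-to-end experiment at a size a
CPU handles in minutes: 64x64 phantoms, 200 unpaired training images per
domain, 8 aligned test pairs, generators with encoder depth 2, base width
16, 2 transformer blocks (token dim 48, 4 heads, expansion 2), patch
discriminators of width 16, batch size 5, 4 epochs, learning rate 1e-3.
The raised learning rate (vs the 1e-4 full-scale default) matches the far
smaller model and step budget; validation runs after every training step
and the best-by-validation-MAE parameters are kept, so the reported model
is the best the run saw — standard practice when training is short and
adversarial dynamics oscillate. The study's claim is deliberately modest: after
training, masked MAE(sCT, CT) on held-out pairs is lower than masked
MAE(CBCT, CT) before training, with all loss traces finite. The weight
initialization is the N(0, 0.02) convolution init conventional in this
model family, which also keeps the untrained U-net close enough to a
smooth map that the short schedule suffices.

```r
study <- run_phantom_study(seed = 1, verbose = TRUE)
study$baseline$mae   # CBCT vs CT, HU, masked
study$trained$mae    # sCT vs CT, HU, masked
study$improved
```

`scripts/acceptance.R` runs exactly this study from scratch and writes the
measured quantities as JSON.

## Numerical choices and degenerate inputs

* Normalization clips to \([-1, 1]\); denormalization inverts it exactly
  inside the window (tested to 1e-6).
* PSNR of identical images returns `Inf` flagged with an `identical`
  attribute rather than erroring.
* An all-air slice has no body mask; `generate_body_mask()` errors rather
  than returning an empty mask.
* Encoder depth 0 is allowed for testing (bottleneck = stem output, no
  skips); transformer depth must be >= 1.
* Rezero gates start at exactly 0; layer normalization uses eps 1e-5;
  attention softmax subtracts the row maximum before exponentiation.
* Non-finite losses abort training with an error pointing at the last
  saved checkpoint instead of continuing silently.
* The on-disk phantom format is 16-bit TIFF with a JSON sidecar recording
  the affine HU packing (exact to 1/65535 of the window); PNG is read in
  both depths but written at 8 bits, and a packed image without its sidecar
  is an error, never a silent rescale. DICOM is out of scope.

## Known limitations

Training at the full 256x256 scale with 12 transformer blocks is far
outside a single-CPU budget; the package is exercised and tested at reduced
scale, and the full-scale configuration is provided as defaults, not as a
validated reproduction. Phantom realism is limited as described above.
Multi-GPU data parallelism, mixed precision, Wasserstein critics, spectral
normalization, multi-scale discriminators, and 3-D volumetric generators
are out of scope.
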