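---
title: "Reconstructing sparse-view optical projection tomography data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing sparse-view optical projection tomography data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optrecon)
```

## The problem

Optical projection tomography (OPT) is the optical analogue of X-ray CT: a
rotating, optically clear sample is imaged in wide field at many angles, and
each transverse slice is recovered from its sinogram — the matrix of line
integrals indexed by detector position and rotation angle. When the sample
fits the depth of field and scatters negligibly, the parallel-beam forward
model applies:

$$Y = R X + n,$$

with $X$ the fluorescence distribution of the slice, $R$ the Radon
transform, $n$ measurement noise. Densely sampled sinograms invert
analytically by filtered back projection (FBP). In vivo, anesthesia time and
phototoxicity cap the number of projections far below the Shannon–Nyquist
requirement, and FBP of such angularly undersampled data is corrupted by
radial streak artifacts.

This package implements and compares three reconstruction routes on
synthetic sparse-fluorescence phantoms:

1. **FBP** with a ramp filter, optionally apodized by a Hann window whose
   support is compressed to a fraction of Nyquist;
2. **compressed sensing** — total-variation-regularized least squares,
   $\min_X \tfrac12\lVert Y - RX\rVert_2^2 + \tau\,\Phi_{TV}(X)$, solved with
   the two-step iterative shrinkage/thresholding algorithm (TwIST);
3. a **modified U-net** trained to map the streak-corrupted undersampled FBP
   reconstruction $I_0$ to an estimate $\hat I$ of the fully sampled
   reconstruction $I$.

## Synthetic phantoms: what they emulate, and what they do not

No public OPT datasets accompany the workflow this package reproduces, so
all experiments run on synthetic slices that emulate the *statistical*
structure of sparse fluorescence samples: a handful of bright, compact
islet-like Gaussian blobs and curvilinear vessel-like tubes on a dark
background, with all signal confined to the inscribed circle minus a support
margin (a rotating sample's signal must stay inside the field swept by the
rotation). Neighboring slices of a volume share structure: slice $s+1$
perturbs the scene of slice $s$ with noise of magnitude
$1 - \texttt{slice\_correlation}$, giving the monotone decay of inter-slice
correlation that motivates block-wise train/test splitting. At
`slice_correlation = 0` scenes are resampled independently — the natural
limit of the perturbation mechanism, since no bounded perturbation of a
previous scene reproduces the exact independent distribution; at 1 the scene
repeats.

Defaults (`phantom_config()`): 128 px slices, 3–12 blobs of radius 2–8 px,
0–4 tubes of width 1–3 px, peak intensities 0.3–1.0, zero background,
support margin 10% of the side. These are implementer-chosen — the source
workflow reports no quantitative sparsity statistics — and with them the
fraction of pixels above 10% of a slice's maximum stays below 0.15.

What passing tests on these phantoms do **not** show: performance on real
tissue, where structures are not Gaussian, backgrounds are non-zero and
textured, the point-spread function varies with depth, and noise is not
additive Gaussian. The phantoms validate the *algorithms* (projector
consistency, solver correctness, learning dynamics, method ordering), not
instrument-grade image quality.

## Numerical choices

**Projector.** Pixel-driven with linear splatting onto detector bins; the
backprojector gathers with identical weights and is therefore the exact
matrix adjoint of the projector — a requirement for the TwIST gradient to be
the true gradient. Conventions: square images, rotation axis at the pixel
center $((H-1)/2, (W-1)/2)$, detector bins = image side, angles
counterclockwise from the x axis, degrees throughout, full 360° acquisitions
(parallel-beam data are 180°-redundant; opposing views are simply both used
and average noise). Against a brute-force ray-marching oracle the projector
agrees to better than 1% relative L2 on random images.

**FBP.** Projections are zero-padded to 4× the detector length before
frequency-domain filtering: with 2× padding the discrete $|f|$ ramp
under-recovers low frequencies (a centered disk reconstructs to 0.98 of its
true plateau); 4× padding removes the bias while keeping the exact zero
response at DC. Backprojection is normalized by $\pi / n_\text{angles}$.
With a Hann window at frequency scale $s$, the response is
$|f| \cdot \tfrac12(1 + \cos(\pi f / (s f_{Nyq})))$ below $s f_{Nyq}$ and
identically zero above; "scale 0.4" therefore means the filter passes
nothing above 40% of Nyquist. Ground-truth reconstructions use Hann 0.4;
undersampled inputs use the plain ramp (the window choice for inputs is
exposed as configuration).

**TwIST.** The operator is rescaled to unit spectral norm (power iteration,
cached per geometry); $\tau$ is quoted in that convention, default 0.004 for
all reconstructions. Two-step weights derive from the assumed eigenvalue
range $[\lambda_1, 1]$ with the severely ill-conditioned default
$\lambda_1 = 10^{-4}$. The TV proximal step runs a fixed number of Chambolle
dual iterations (default 10; raise `tv_inner_iters` when probing asymptotic
regimes — the dual algorithm converges only at rate $O(1/k)$, so the default
trades prox accuracy for speed). Iterates are clipped at zero (fluorescence
is nonnegative), initialization is the ramp FBP reconstruction, and in
monotone mode any objective increase triggers a damped fallback step, so the
objective trace is non-increasing by construction. Stopping: relative
objective change below `rel_tol` (default 1e-4) or `max_iters` (default
200).

**U-net.** Four contracting blocks (two zero-padded 3×3 convolutions, each
followed by batch normalization and ReLU, then 2×2 max pooling), features
doubling from `base_features`; expanding blocks upsample by bilinear
interpolation, concatenate the matching skip, and quarter the concatenated
channel count through two convolutions, giving expanding widths half those
of a conventional U-net (at base 64: contracting 64/128/256/512,
concatenations 1024/512/256/128, outputs 256/128/64/32). The only channel
scheme consistent with both the "quartered" and the "half-width" rules puts
no convolutions at the deepest (1/16) scale: the pooled 512-channel features
are upsampled directly and concatenated with the 512-channel skip. The
output head is a linear 1×1 convolution — reconstructions live on an
arbitrary normalized intensity scale, so no output nonlinearity is
appropriate — and the network predicts the image directly rather than a
residual. Inference reflect-pads any input to side multiples of
$2^\text{depth}$ and crops back.

**Training.** Pairs are built by projecting a phantom at $P$ angles,
relabeling a random start angle (a circular sinogram shift, equivalent to
rotating the sample — the paper-style acquisition-phase augmentation),
reconstructing $I$ (full sinogram, Hann 0.4) and $I_0$ ($N$-projection
subsample, ramp), then flipping both images identically at random. Each pair
is normalized by the *input's* mean and standard deviation so the input is
zero-mean/unit-variance while target and input stay on a common scale;
outputs are de-normalized with the same affine map, and PSNR is always
computed in raw intensity units so all three methods are compared on one
scale. The l1 loss is minimized with Adam at its conventional defaults
(learning rate $10^{-3}$, moment decays 0.9/0.999) over random crops, batch
by batch. The held-out set — assigned in contiguous blocks of 10 neighboring
slices, 80/20 — doubles as the early-stopping monitor: training stops when
the held-out l1 has not improved on its best value for 2 consecutive epochs
and the best-epoch weights are kept. Re-using the monitoring set as the test
set is methodologically impure but is retained deliberately as the
protocol's defined behavior; a separate validation split can be created by
splitting twice. Flips and crops are re-randomized every epoch; the start
angle is fixed per pair at creation (re-projecting every epoch would
dominate run time for little benefit at these problem sizes). One master
seed fans out to independent streams for initialization, the split,
shuffling, crops and flips; frozen seeds reproduce training bit-for-bit.

**Degenerate inputs.** Zero-variance slices cannot be normalized and are
skipped with a warning during training and rejected at inference;
identical-image PSNR returns an infinite sentinel that the benchmark
excludes from averages (with a count) rather than contaminating them;
all-background ground-truth slices are likewise excluded.

## Problem sizes used by the test-suite experiments

The package's own experiments are desk-scale by design: the benchmark
training run uses 30 volumes of 10 correlated 128 px slices (300 pairs),
$P = 160$, $N = 20$, `base_features = 8`, 64 px crops, batch 16, patience 2,
and a `max_epochs` cap of 30 for that configuration; solver comparisons use
20 slices per undersampling level. These sizes were chosen so the full
pipeline — phantom synthesis through training and benchmarking — completes
on a single CPU core while leaving the learning signal clearly measurable:
the trained network improves mean held-out PSNR over its FBP input by well
over the 2 dB margin the package's acceptance tests assert.

## Known limitations

- The projector models ideal parallel-beam line integrals: no point-spread
  function, depth of field, attenuation, scattering, or camera noise physics
  beyond optional additive Gaussian noise.
- 2D slice-wise TV only; no volumetric regularization.
- The TV proximal operator is inexact at its default iteration budget (see
  above).
- Training runs on the CPU; the implementation favors clarity and exact
  reproducibility over throughput and is not suited to the multi-thousand
  slice datasets of a production OPT facility.
- The Hann/0.4 ground-truth convention and the plain-ramp input convention
  are defaults, not laws; both are configuration.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
cfg <- phantom_config(image_size = 64)
slice <- generate_slice(cfg, seed = 7)
sino <- radon_project(slice, full_rotation_angles(160))
gt <- fbp(sino, filter_spec("hann", 0.4))
sub <- apply_scheme(sino, subsample_indices(160, 20))
streaky <- fbp(sub)
cs <- twist_reconstruct(sub)$image
c(FBP = psnr(streaky, gt), CS = psnr(cs, gt))
```

The undersampled FBP lands in the teens of dB against the fully sampled
ground truth; TwIST typically gains more than 10 dB on these sparse
phantoms. Training a CNN and closing the loop is shown in the README's
worked example.
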