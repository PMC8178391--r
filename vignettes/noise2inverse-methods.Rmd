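---
title: "Self-supervised tomographic denoising: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised tomographic denoising: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Synchrotron tomography reconstructs a volume from projections of a rotating
sample.  When exposure time or dose is limited — fast dynamics, radiation
damage, detector frame-rate caps — the measured sinograms are photon-starved
and the reconstruction is noisy.  Supervised CNN denoising would need paired
noisy/clean reconstructions, which are exactly what such experiments cannot
provide.  This package implements *self-supervised* denoising for linear
tomographic reconstruction: training pairs are manufactured from a single
noisy data set by splitting the measurement into disjoint sections.

## The estimator

Let $A$ be the linear forward projector and $y$ the noisy sinogram.  Split
the measured angles into $J$ disjoint *target sections*; the *input section*
of each target is its complement.  With $x_j$ the filtered-backprojection
(FBP) reconstruction of target section $j$ and $x_{\ne j}$ the
reconstruction of its input section, the network $f_\theta$ is trained to
minimise

$$\sum_{j=1}^{J} \lVert f_\theta(x_{\ne j}) - x_j \rVert_2^2 .$$

Because (i) the noise in $x_{\ne j}$ and $x_j$ is statistically independent
(they derive from disjoint measurements and reconstruction is linear) and
(ii) the noise is zero-mean in the corrected sinogram, this loss equals, in
expectation, the supervised loss against the unavailable noise-free
reconstructions plus a constant noise-variance term.  Minimising it
therefore trains a genuine denoiser.  `verify_loss_decomposition()` checks
the identity empirically for any fixed linear denoiser, and
`verify_conditions()` checks the two premises on any `split_scheme`:
section disjointness, and equal use of every measurement unit as target.

Three acquisition regimes are supported by three pairing strategies:

* **static 2.5D** — each slice's sinogram is split in angle (strided mod-$J$
  so adjacent angles fall in different target sections); the network input
  is a stack of $2c+1$ context slices reconstructed from the input section,
  the target a single slice from the target section.
* **dynamic** — an interlaced acquisition displaces each time step's angle
  grid so that $K$ consecutive steps tile the full turn.  On time steps
  before the dynamic process starts, input = one sparse step, target = the
  FBP of the other $K-1$ steps combined.  The target is deliberately built
  from *more* data than the input, so the network learns to remove streak
  artifacts along with noise.
* **multi-channel** — diffraction-style data (one sinogram per scattering
  channel) is split in angle only, identically for every channel; inputs
  and targets both carry all channels, letting the network exploit the
  correspondence between locations sharing a material.

At inference time the default (`predict(fit, data, mode = "full")`) applies
the trained network once to the reconstruction of *all* measurements; the
alternative averages per-section outputs (`mode = "split_average"`).
`experiment_inference_modes()` measures the comparison over repeated seeds
rather than assuming a winner and reports the win count: at the package's
study sizes the two modes land within a few percent of each other, so the
direction is reported, not asserted.  The comparison only makes sense for
converged models — heavily under-trained networks systematically favour
the split mode, whose averaging suppresses residual output noise — so the
repetitions train at full length on reduced images.

## Network

The denoiser is a width-one mixed-scale dense network: hidden layer $i$
sees the input channels plus all previous feature maps, applies one
3×3 convolution per incoming map with dilation $((i-1) \bmod 10) + 1$,
and emits a single feature map through a ReLU; a 1×1 linear layer maps all
features to the output.  Dense connectivity plus cycling dilations give a
large receptive field at a very small parameter count —
`count_parameters(msd_config(100, 11, 1))` is 54,662 — which is why
overfitting to noise is unlikely and no early stopping or validation split
is used.  Convolutions pad by reflection without repeating the edge pixel;
a periodic mode exists purely as a test hook for translation-equivariance
checks, and a linear-activation hook turns the network into a linear
operator for the decomposition diagnostics.

Inputs and targets are normalised by a global affine map sending the
training data's 1st/99th percentiles to $[0,1]$ (stored in the model and
inverted at inference).  Percentiles rather than min/max are used because
FBP of sparse or noisy data overshoots; the map must not be dominated by
those tails.

## Geometry and reconstruction

The projector is ray-driven: each ray is sampled at unit steps and the
image interpolated bilinearly; the backprojector scatters with identical
weights and is therefore the exact matrix transpose (the adjoint identity
holds to rounding error, which the Chambolle–Pock baseline requires).
Angle 0 sends rays along +x, the object rotates counterclockwise, and the
rotation centre is fixed at the detector midpoint — centre finding is out
of scope.  FBP zero-pads each projection to the next power of two at least
twice the detector width, applies the band-limited ramp (the discrete
impulse response whose DC term is nonzero; the naive $|f|$ sampling biases
gray values several percent low), optionally shaped by Shepp–Logan or
cosine windows, backprojects and scales by $\pi/M$ for $M$ angles.  The
same scale covers full-turn data, where opposing rays are each covered
twice.  Both 180° and 360° ranges are supported; interlaced dynamic
schedules span 360°.

## Noise model

Counts follow Beer–Lambert transmission: $\mathrm{Poisson}(I_0 t e^{-p}) +
\text{dark}$, corrected by the standard dark/flat/log chain with a
photon-starvation floor of one count.  The *virtual time fraction* $t$
scales expected counts only — not the number of angles — so reduced
acquisition time appears purely as a $1/t$ growth of noise variance at
fixed sampling, which `experiment_noise_model()` verifies (ratio 5 between
$t=1$ and $t=0.2$).  The log correction carries a second-order bias of
$1/(2\mu)$ at $\mu$ expected counts; at the 20-count starvation boundary
this stays under 1% of the signal, and the zero-mean premise of the loss
decomposition is satisfied at Monte-Carlo precision in the count regimes
the studies use.  A seeded additive-Gaussian mode exists because the theory
only needs zero-mean noise, not a particular distribution.

## Synthetic studies: what they emulate, and what they do not

All data is generated by the phantom module: porous multi-slice volumes
(cylindrical matrix with ellipsoidal/cylindrical inclusions of 2–3
materials), dynamically growing spherical inclusions that appear only after
a configurable start step, multi-channel slices whose materials carry
sparse positive channel signatures (identical wherever the material
occurs), and interlaced angle schedules with optional per-step rigid
jitter.  Attenuation values (≈0.005–0.04 per pixel) are chosen so line
integrals stay in the low single digits: a regime where a few hundred
incident photons per ray give visible but non-starved noise, as in
photon-limited imaging.  Phantoms are piecewise-constant by design, which
makes TV minimisation a fair baseline and makes its stair-casing visible.

The generators emulate counting noise, sparse-angle streaks and
channel-coupled structure.  They do **not** emulate detector blur, ring
artifacts, beam hardening, scatter, phase contrast, sample drift or
realistic microstructure; passing studies therefore demonstrate the
estimator's statistical behaviour under its stated assumptions, not
beamline-grade image quality.

## Study sizes and defaults

The built-in studies are sized for minutes on a single CPU core:

* static: 8 slices of 128², 256 angles over π, $I_0 = 200$, $J = 2$,
  depth-25 network with 2 context slices, 2000 Adam iterations at batch 2.
  The inference-mode comparison repeats a 64²/4-slice/128-angle variant of
  the same study over 10 seeds at full training length: the full-mode
  advantage is a property of converged models (an under-trained network can
  favour the noise-averaging of the split mode), so the repetitions shrink
  the images, not the training budget.
* dynamic: 6 interlaced steps × 50 angles over 2π at 64², $I_0 = 1000$,
  training on the 6-step static window, evaluation on the three static
  steps after it (total 12 steps, process starts at step 10, growth 1.5
  px/step).  Groups of interlaced steps are consecutive and disjoint.
* multi-channel: 11 channels at 64², $J = 3$, 128 angles, $I_0 = 300$,
  depth 15.
* decomposition: 64² phantom, 200 realizations, identity and 5×5-blur
  denoisers at $J = 2, 4$.
* TV baseline: 96², 144 angles, $I_0 = 500$, 400 Chambolle–Pock
  iterations per candidate $\lambda$ on a 5-point log grid scaled by the
  data magnitude; the grid search against ground-truth MSE replaces visual
  tuning, which automated runs cannot do.

Optimiser defaults (Adam, learning rate $10^{-3}$, batch 4 — the studies
use smaller batches to spread a fixed iteration budget over more update
steps) are the package's own choices and are config-overridable; the
method is deliberately insensitive to them at these scales.

## Numerical choices and degenerate inputs

* Splitting: remainder angles (when $M \bmod J \ne 0$) go to the
  lowest-index target sections, so section sizes are deterministic and
  differ by at most one.  $J = 1$ is rejected (its input section would be
  empty); combining time steps with duplicated angles is rejected (it
  would correlate input and target noise).
* The condition checker treats "equally often" literally: angular schemes
  use every angle in exactly one target section, the round-robin dynamic
  scheme uses every step in exactly $K-1$.
* 2.5D assembly mirrors out-of-range slices about the boundary *excluding*
  the edge slice, avoiding duplicated edge statistics.
* Chambolle–Pock runs on the stacked operator $[A;\, \alpha\nabla]$ with
  dual radius $\lambda/\alpha$ and $\alpha = \max(\sqrt{\lambda},
  \lVert A\rVert/\sqrt{8})$: the scaling balances the two dual blocks, so
  large $\lambda$ (whose TV multiplier would otherwise sit far above the
  primal scale) converges at the same rate as moderate ones.  Steps are
  $\sigma = \tau = 0.95/L$ with $L$ the scaled norm from seeded power
  iteration; isotropic TV with forward differences and Neumann boundaries;
  zero initialisation (so a zero sinogram provably stays zero).
* Training aborts on non-finite loss rather than continuing silently; all
  RNG streams (phantom, noise, weights, shuffling) are separate named
  seeds, and every stochastic routine restores the caller's RNG state.

## Limitations

Real acquisitions need centre-of-rotation correction, ring-artifact
handling and (for dynamic data) drift correction before this estimator
applies; none are provided.  The FBP here is a reference implementation —
adequate at desk scale, not tuned for beamline-sized volumes.  Training is
single-threaded CPU code: the compact network makes that workable at study
sizes, but real data sets would require a GPU implementation of the same
architecture.  Finally, self-supervision removes only what behaves like
independent zero-mean noise: systematic artifacts shared by input and
target sections (e.g. global angular undersampling) are learned as signal
and preserved.
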