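---
title: "Single-shot quantitative phase imaging: model, solver and network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot quantitative phase imaging: model, solver and network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tieqpi)
```

## The problem

Unstained cells delay light without absorbing it. A brightfield camera
records only intensity, so an in-focus image of such a pure phase object
is featureless; the morphology lives in the optical phase
$\varphi(x,y)$, which standard detectors cannot see. Quantitative phase
imaging (QPI) recovers $\varphi$ and, through the refractive index
contrast $\Delta n$ between specimen and medium, the physical thickness
$h = \lambda\,\varphi / (2\pi\,\Delta n)$.

The transport of intensity equation (TIE) is the non-interferometric
route: under the paraxial approximation, intensity and phase of a
coherent beam obey

$$ \frac{\partial I}{\partial z}
   = -\frac{1}{k}\,\nabla\!\cdot\!\big(I\,\nabla\varphi\big),
   \qquad k = \frac{2\pi n_m}{\lambda}, $$

so two slightly defocused images (to estimate $\partial I/\partial z$)
plus the in-focus image determine the phase. The price is the
multi-shot acquisition and the focus search. This package implements
that conventional solver, an optical forward model to synthesize its
inputs, and a conditional GAN that, once trained on (defocused
intensity, TIE phase) pairs, maps a *single* defocused frame to a
quantitative phase map with no focus decision and no propagation at
inference time.

## Optical forward model

Fields are sampled complex amplitudes $u(x,y)$ with a physical pitch of
`camera_pixel_um / magnification` (0.08625 µm for the default 3.45 µm
camera pixel behind a 40×/0.65 objective, 627 nm LED illumination,
water immersion $n_m = 1.33$). Defocus uses the exact scalar
angular-spectrum transfer function

$$ H(f_x,f_y; \Delta z)
   = \exp\!\Big(i\,2\pi\,\Delta z
     \sqrt{(n_m/\lambda)^2 - f_x^2 - f_y^2}\Big), $$

with evanescent components ($f_x^2+f_y^2 > (n_m/\lambda)^2$) set to
zero rather than raising an error. A paraxial (Fresnel) propagator is
available behind `optical_config(propagator = "fresnel")` for
consistency checks against the TIE's own paraxial derivation. The model
is fully coherent and scalar: the partial coherence of an LED source,
high-NA vectorial effects, aberrations and the camera MTF are out of
scope, so simulated frames are *cleaner* than microscope frames — tests
passing on phantoms demonstrate the correctness of the numerics, not
robustness to every nuisance of real data. Optional Poisson shot noise
(seeded, parameterized by expected photons per unit intensity) is the
one concession to detector realism.

Two phantom families emulate the study's samples:

* **Microbeads** (`bead_spec()`): 4 µm polystyrene-like spheres,
  $n = 1.68$, in water, linear attenuation 0.843 µm⁻¹. A sphere of
  radius $r$ has chord thickness $h(\rho) = 2\sqrt{r^2-\rho^2}$, giving
  peak phase $2\pi\,\Delta n\, d / \lambda \approx 14.03$ rad — a
  deliberately hard, steep object used for calibration.
* **Cell-like blobs** (`cell_spec()`): seeded, band-limited random
  phase textures (cut off at $1/\text{smoothness}$) under a smooth cell
  envelope with a denser nucleus bump; non-negative, reproducible,
  weak-to-moderate phase. These stand in for unstained buccal cells;
  they share the smoothness and magnitude of real cell phase maps but
  none of their biological structure.

During stack generation the field is embedded in a twice-larger grid
(filled with the mean border value) before propagation and cropped
back, which suppresses periodic wrap-around. The padding value is only
consistent when the object's tails do not reach the frame edge, so
phantoms are sized to stay well inside the field of view; tests that
need exact propagation identities use strictly band-limited fields.

## The TIE solver

`tie_solve()` implements the spectral solution

$$ \varphi = \nabla^{-2}\,\nabla\!\cdot\!
   \Big[\tfrac{1}{I}\,\nabla\,
   \nabla^{-2}\big(-k\,\partial_z I\big)\Big] $$

with $\nabla^{-2}$ the FFT inverse Laplacian (division by
$-(4\pi^2(f_x^2+f_y^2)+\varepsilon)$, DC mode nulled). Numerical
choices, all exposed in `tie_config()`:

* **Prefactor.** The solver carries $k = 2\pi n_m/\lambda$; with
  $n_m = 1$ this is the textbook $-2\pi/\lambda$ form. Carrying the
  medium index keeps the inversion exactly consistent with
  angular-spectrum propagation in immersion media — dropping it would
  bias every recovered phase by $n_m$.
* **Boundaries.** Default even-mirror extension (reflect to a doubled
  grid, solve periodically, crop), i.e. Neumann-like boundaries; plain
  periodic mode is kept for oracle tests against the dense 5-point
  Laplacian. Mirror boundaries avoid wrap-around phase artifacts when
  an object approaches the frame edge.
* **Division by I.** The in-focus intensity is clamped below
  `intensity_floor_fraction × max(I)` (default 10⁻³) before the
  $1/I$ step, so dark pixels never blow up the gradient flow.
* **Regularization.** $\varepsilon = 0$ by default (the synthetic data
  are noiseless); a Tikhonov $\varepsilon > 0$ is available for noisy
  stacks.
* **Axial derivative.** Central difference over an equally spaced
  bracketing pair (`forward` scheme available). The output phase is
  mean-subtracted: the TIE determines phase only up to a constant
  (gauge freedom), so comparisons align backgrounds first.

Focus is selected by the Tamura coefficient
$\sqrt{\sigma(I)/\mu(I)}$ — scale-invariant, zero for a flat image. A
pure phase object has its *flattest* intensity in focus, so the default
picks the minimum; absorbing samples use the maximum. Ties break toward
$z = 0$.

**Fine ground-truth pair.** A coarse ±60 µm, 15 µm-step scan is what
the microscope records for training variety, but a central difference
over ±15 µm badly under-resolves $\partial I/\partial z$ for steep
objects (a 14-rad bead's intensity oscillates on a much finer axial
scale). Synthetic stacks therefore carry an extra ±1 µm pair around
focus used only for the ground-truth TIE solve (`fine_dz_um` in
`pipeline_config()`); the 1 µm choice matches the defocus the bead
calibration found optimal. With it, the Gaussian self-consistency check
recovers a 3-rad object to <0.1% peak error, and the 4 µm bead
round-trips through phase-to-thickness within 10%.

**Known limitation.** The steep bead is recovered within ~10% only for
derivative spacings ≲1 µm; at Δz = 2 µm the finite difference leaves
the linear regime and the interior phase is underestimated by tens of
percent. This is a property of the measurement model, not of the
solver: the same inversion recovers smooth objects at <0.1% error over
the same spacings. The bead-recovery test therefore asserts 10%
accuracy at Δz ∈ {0.5, 1} µm, estimating the peak after smoothing at a
third of the diffraction limit $\lambda/2\mathrm{NA}$ (≈0.16 µm, well
below the optical resolution, so only non-physical single-pixel spikes
are suppressed).

## Dataset construction

`build_pairs()` pairs **every** selected defocused frame of a stack
with that stack's *single* fine-pair TIE phase map. This one-target-
per-object pairing is what teaches the network to ignore defocus: the
same phase answer is demanded from inputs at −60 … +60 µm. Tiles are
min–max normalized to [−1, 1] per tile with the records kept, so a
network output can be mapped back to radians — without the records the
output would be an image, not a measurement. Splits are disjoint by
source object, never by frame; with whole-object allocation the exact
split sizes are reached by proportional assignment plus seeded
trimming, and infeasible requests fail loudly rather than silently
leaking objects across splits.

## The conditional GAN

The generator is a U-Net: stride-2 4×4 convolutions halving a 256 tile
eight times to 1×1 (Leaky ReLU 0.2; batch norm on all but the first and
the 1×1 bottleneck stage), mirrored by transposed convolutions with
skip concatenations (ReLU, batch norm, dropout 0.5 in the first three
decoder stages), tanh output in [−1, 1]. Channels start at
`base_channels` (64) and double to a 512 cap. Smaller tiles reduce the
effective depth with a warning. The discriminator is a 5-conv PatchGAN
over the concatenated (intensity, phase) pair — three stride-2 stages
(64/128/256), a stride-1 512 stage, and a stride-1 map to one channel
whose sigmoid gives per-patch realness scores (a 30×30 patch map for a
256 tile).

Training alternates one discriminator ascent of the conditional
adversarial objective
$\mathbb{E}[\log D(x,y)] + \mathbb{E}[\log(1 - D(x, G(x)))]$
(as binary cross-entropy on patch logits) with one generator descent of
the non-saturating loss $-\log D(x, G(x))$ plus an L1 reconstruction
term weighted `l1_weight = 100`. The printed adversarial objective
alone is ill-posed for paired translation; the L1 term is the
conventional addition and can be switched off (`l1_weight = 0`) to
recover the bare objective. The stochastic input $z$ of the conditional
objective is realized as decoder dropout, which is also why inference
disables dropout and is deterministic. Adam uses the printed learning
rate 10⁻⁴ and batch size 4 with moments (0.5, 0.999) — the image-to-
image translation convention, as the moments are not otherwise fixed.

Because no deep-learning framework is part of the package's
dependencies, the layers (im2col convolutions in C++, batch norm,
dropout, Adam) and the full backward pass are implemented in the
package and verified against finite-difference gradients in the test
suite. Everything is seeded: initialization, shuffling, dropout; two
runs with the same seed produce identical histories, and a saved model
reloads to bit-identical inference.

At inference the input frame is min–max normalized exactly as training
tiles were, one forward pass produces a [−1, 1] map, and the pooled
training phase range (stored in the model) converts it to radians; a
per-tile record can be supplied when one exists. The best-validation-
SSIM snapshot is used by default.

## Metrics

MSE, PSNR ($10\log_{10}(L^2/\mathrm{MSE})$), SSIM and UIQI with
$C_1 = (K_1 L)^2$, $C_2 = (K_2 L)^2$, $K_1 = 0.01$, $K_2 = 0.03$.
Choices the formulas leave open:

* Metrics are computed on 8-bit renderings (min–max stretch to 0…255,
  $L = 255$) of both maps — this is the only scale on which MSE values
  of order 100 are meaningful, and the stretch removes the TIE's
  arbitrary phase offset. Raw-radian evaluation is available by
  calling the metric functions directly.
* SSIM/UIQI default to the mean over all sliding 8×8 windows (the
  conventional estimator); a whole-image global mode is a flag.
  Population (divide-by-N) variances by default.
* UIQI is the SSIM formula with $C_1 = C_2 = 0$; degenerate windows
  (zero variance or zero mean energy) are stabilized with small
  SSIM-style constants instead of returning NaN.

`evaluate_sweep()` reproduces the defocus-robustness comparison: at
every scan plane the conventional TIE is re-run with the three frames
centred there (as happens when one reconstructs away from true focus)
and the model infers from the single frame; both are scored against the
stack's ground truth. Planes without a symmetric bracketing pair are
skipped, which is why sweep ensembles are simulated with a ±75 µm scan
when the ±60 µm planes must be evaluable.

## Problem sizes and design choices for the shipped experiments

The deterministic checks run at full fidelity (512² grids for the
Gaussian self-consistency and derivative oracles, 256² for the bead).
The learned-reconstruction studies are scaled-down analogs of the
original experiments, chosen so the whole suite runs comfortably on a
single CPU: 24 phantom objects per sample type at 64×64 (14 train /
4 validation / 6 test objects, 9 scan planes each), 16 base channels,
12–16 epochs. At this scale the qualitative findings reproduce — the
trained model beats its untrained initialization on held-out objects by
a wide margin, conventional TIE peaks at focus and collapses toward
±60 µm, and the single-shot curve is much flatter across the sweep —
but the absolute SSIM values sit well below the ~0.95–0.98 of the
full-scale study (hundreds of 256² pairs, 200–300 epochs, GPU-days of
arithmetic), and the sweep ensemble includes the training objects, so
its curves describe the fitted model's behaviour rather than
generalization. The acceptance script prints exactly what it computes;
nothing is extrapolated from the scaled runs.

The spectral-vs-dense Poisson oracle is evaluated on smooth
(band-limited) random fields: the FFT solver applies the exact spectral
symbol $-4\pi^2 f^2$ while the 5-point stencil's symbol deviates at
high frequency, so the two agree only in the resolved-frequency regime
— on white noise the discrepancy is discretization, not error.

## Reproducing the pipeline

```{r pipeline}
cfg <- smoke_profile(out_dir = "smoke_run", seed = 1)
run_pipeline(cfg)                       # simulate ... evaluate
report <- read.csv(file.path("smoke_run", "report.csv"))
summarize_metrics(report)$summary
```

`scripts/acceptance.R --seed S --out results.json` runs the full
scaled-down study (both phantom types) and writes every headline
quantity it computes as JSON.
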