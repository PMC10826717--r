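# tieqpi

Single-shot quantitative phase imaging (QPI) in R: a transport-of-
intensity (TIE) phase solver, a synthetic optical forward model that
produces its inputs, and a conditional GAN that learns the
intensity-to-phase mapping so that **one** defocused brightfield frame
yields a quantitative phase map — no focus search, no axial scan at
inference time.

## Who this is for

Computational-imaging and microscopy researchers who want a
self-contained, CPU-only reference implementation of the TIE-plus-
learned-reconstruction pipeline: simulate defocused intensity stacks of
phase objects, generate conventional TIE ground truth, train the
image-to-image translation network, and score both reconstructions with
the standard quality metrics.

## The science in brief

A transparent specimen delays light by a phase
$\varphi(x,y) = 2\pi\,\Delta n\,h(x,y)/\lambda$, invisible to an
in-focus intensity camera. Under the paraxial approximation intensity
and phase are linked by the transport of intensity equation

$$ \frac{\partial I}{\partial z}
   = -\frac{1}{k}\nabla\cdot(I\,\nabla\varphi), \qquad
   k = \frac{2\pi n_m}{\lambda}, $$

a Poisson-type equation solved spectrally with an FFT inverse Laplacian
from an in-focus frame plus a defocused pair:

$$ \varphi = \nabla^{-2}\,\nabla\cdot\Big[\tfrac1I\,\nabla\,
   \nabla^{-2}\big(-k\,\partial_z I\big)\Big]. $$

Thickness follows as $h = \lambda\varphi/(2\pi\Delta n)$. The in-focus
frame is found automatically by the Tamura coefficient
$\sqrt{\sigma/\mu}$ (minimal for a phase object in focus). A U-Net
generator / PatchGAN discriminator pair is then trained on (defocused
intensity, TIE phase) tiles — every defocus plane of an object maps to
that object's single phase map — after which a lone defocused frame
anywhere in the trained ±60 µm range is translated to phase in one
forward pass. Reconstructions are compared by MSE, PSNR, SSIM and UIQI
on 8-bit renderings.

## Worked example

Simulate the calibration bead (4 µm polystyrene, n = 1.68, in water),
record a defocus stack, recover the phase with the conventional TIE and
convert it to thickness:

```r
library(tieqpi)

cfg  <- optical_config()            # 627 nm, 40x/0.65, 3.45 um pixel
bead <- make_bead_field(bead_spec(), c(256, 256), cfg)
max(field_phase(bead))
#> [1] 14.02944                      # 2*pi*0.35*4/0.627 rad

stack <- generate_stack(bead, z_um = c(-1, 0, 1), cfg)
rec   <- tie_solve(stack)           # mean-subtracted phase, radians
aligned <- rec$phase_rad - median(rec$phase_rad)
thick <- phase_to_thickness(phase_map(aligned, cfg$pitch_um),
                            delta_n = 1.68 - 1.33, cfg)
max(thick$thickness_um)
#> [1] 4.362528                      # 4 um bead, 9% peak error
```

The peak of the recovered thickness map lands within 10% of the true
4 µm diameter; a smooth 3-rad Gaussian phase is recovered with SSIM
0.997 against ground truth and 0.04% peak error.

The full pipeline — phantoms → TIE ground truth → dataset → GAN →
single-shot inference → metric sweep — runs from one configuration:

```r
cfg <- smoke_profile(out_dir = "smoke_run", seed = 1)   # 64 px, minutes
run_pipeline(cfg)
report <- read.csv(file.path("smoke_run", "report.csv"))
```

A thin CLI wrapper ships in `inst/scripts/tieqpi`
(`tieqpi --smoke`, or `tieqpi --config pipeline.yaml`).

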