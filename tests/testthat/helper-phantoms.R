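# Shared fixtures, all generated in code at test time.

default_cfg <- optical_config()

# A strictly band-limited random complex field (no content beyond the
# evanescent cutoff), for exact propagation round-trip checks.
bandlimited_field <- function(n = 64, seed = 1, cfg = default_cfg,
                              cutoff_frac = 0.25) {
  withr::with_seed(seed, {
    spec <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)),
                   n, n)
    fx <- tieqpi:::fft_freq(n, cfg$pitch_um)
    keep <- outer(fx^2, fx^2, `+`) <=
      (cutoff_frac * cfg$medium_index / cfg$wavelength_um)^2
    u <- tieqpi:::ifft2(spec * keep)
    u <- u / max(Mod(u))
    complex_field(u + 2, cfg$pitch_um)  # offset keeps |u| well off zero
  })
}

# Gaussian pure-phase object on a grid large enough that its tails do not
# reach the field edge.
gaussian_phase_field <- function(n = 512, peak = 3, sigma_um = 5,
                                 cfg = default_cfg) {
  ax <- (seq_len(n) - (n / 2 + 1)) * cfg$pitch_um
  ph <- peak * exp(-outer(ax^2, ax^2, `+`) / (2 * sigma_um^2))
  complex_field(exp(1i * ph), cfg$pitch_um, phase_rad = ph)
}

# Small bead phantom stacks with a fine ground-truth pair around focus,
# shared by the GAN and sweep tests.
make_bead_stacks <- function(n_stacks, tile = 64, z_all, seed,
                             cfg = default_cfg) {
  half_um <- tile * cfg$pitch_um / 2
  withr::with_seed(seed, {
    lapply(seq_len(n_stacks), function(i) {
      off <- runif(2, -0.1, 0.1) * half_um
      fld <- make_bead_field(bead_spec(centers = list(off)),
                             c(tile, tile), cfg)
      generate_stack(fld, z_all, cfg,
                     source_id = sprintf("bead%03d", i))
    })
  })
}

make_cell_stacks <- function(n_stacks, tile = 64, z_all, seed,
                             cfg = default_cfg) {
  lapply(seq_len(n_stacks), function(i) {
    fld <- make_cell_field(cell_spec(seed = seed + i, cell_radius_um = 2,
                                     smoothness_um = 0.8),
                           c(tile, tile), cfg)
    generate_stack(fld, z_all, cfg, source_id = sprintf("cell%03d", i))
  })
}

# Tiny synthetic pair tibble for data-module tests (frames are cheap
# random tiles, not propagated physics).
make_toy_stacks <- function(n_stacks, n_z = 9, tile = 8, seed = 1,
                            cfg = default_cfg) {
  withr::with_seed(seed, {
    stacks <- lapply(seq_len(n_stacks), function(i) {
      frames <- replicate(n_z, matrix(runif(tile * tile), tile, tile),
                          simplify = FALSE)
      intensity_stack(frames, seq(-60, 60, length.out = n_z),
                      cfg$pitch_um, cfg, source_id = sprintf("obj%03d", i))
    })
    phases <- lapply(seq_len(n_stacks), function(i) {
      phase_map(matrix(rnorm(tile * tile), tile, tile), cfg$pitch_um)
    })
    list(stacks = stacks, phases = phases)
  })
}

# Peak estimate at the optical resolution scale: smooths with a Gaussian
# whose width is a third of the diffraction limit lambda/(2 NA), so only
# sub-resolution (non-physical) spikes are suppressed.
diffraction_limited_peak <- function(m, cfg = default_cfg) {
  res_um <- cfg$wavelength_um / (2 * cfg$numerical_aperture)
  sigma_px <- res_um / 3 / cfg$pitch_um
  n1 <- nrow(m); n2 <- ncol(m)
  fx <- tieqpi:::fft_freq(n1, 1)
  fy <- tieqpi:::fft_freq(n2, 1)
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fx^2, fy^2, `+`))
  max(Re(tieqpi:::ifft2(tieqpi:::fft2(m) * H)))
}

quiet_gan <- function(expr) suppressWarnings(expr)
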