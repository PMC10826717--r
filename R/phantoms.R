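#' Microbead phantom specification
#'
#' Describes a field of spherical polystyrene-like microbeads immersed in
#' a medium.  The defaults reproduce the calibration sample used
#' throughout the package: 4 um beads of refractive index 1.68 in water
#' (n = 1.33), with a linear attenuation coefficient of 0.843 per um.
#'
#' A sphere of radius r has chord thickness `h(rho) = 2*sqrt(r^2 - rho^2)`
#' at transverse distance rho from its centre, so the accumulated optical
#' phase is `phi = 2*pi*delta_n*h/lambda` (peaking at
#' `2*pi*delta_n*d/lambda` on the axis) and the transmitted amplitude is
#' `exp(-attenuation*h/2)`.
#'
#' @param diameter_um Bead diameter in micrometres.
#' @param bead_index Refractive index of the bead material.
#' @param attenuation_per_um Linear (intensity) attenuation coefficient in
#'   1/um.
#' @param centers List of `c(x, y)` bead centres in micrometres, relative
#'   to the centre of the field of view.
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(diameter_um = 4, bead_index = 1.68,
                      attenuation_per_um = 0.843,
                      centers = list(c(0, 0))) {
  stopifnot(diameter_um > 0, attenuation_per_um >= 0, length(centers) >= 1)
  structure(list(diameter_um = diameter_um, bead_index = bead_index,
                 attenuation_per_um = attenuation_per_um, centers = centers),
            class = "bead_spec")
}

#' Cell-like phantom specification
#'
#' Describes a smooth random phase object emulating an unstained cell: a
#' band-limited cytoplasm texture plus a denser, smoothly-bounded nucleus.
#' The generated phase is non-negative, band-limited below the spatial
#' frequency `1 / smoothness_um`, and reproducible for a fixed seed.
#'
#' @param cytoplasm_phase_rad Length-2 range (radians) spanned by the
#'   cytoplasm phase texture.
#' @param nucleus_phase_rad Length-2 range (radians) of the additional
#'   nucleus phase bump.
#' @param smoothness_um Smallest feature scale; the phase spectrum is cut
#'   off at `1 / smoothness_um` cycles/um.
#' @param cell_radius_um Radius of the cell envelope in micrometres.
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(cytoplasm_phase_rad = c(0, 1.5),
                      nucleus_phase_rad = c(0.5, 1.5),
                      smoothness_um = 2, cell_radius_um = 7,
                      seed = 1L) {
  stopifnot(length(cytoplasm_phase_rad) == 2, length(nucleus_phase_rad) == 2,
            all(cytoplasm_phase_rad >= 0), all(nucleus_phase_rad >= 0),
            smoothness_um > 0, cell_radius_um > 0)
  structure(list(cytoplasm_phase_rad = sort(cytoplasm_phase_rad),
                 nucleus_phase_rad = sort(nucleus_phase_rad),
                 smoothness_um = smoothness_um,
                 cell_radius_um = cell_radius_um,
                 seed = as.integer(seed)),
            class = "cell_spec")
}

# Object-plane coordinate axes (um) centred so that 0 is on-grid.
grid_axes <- function(shape, pitch) {
  list(x = (seq_len(shape[1]) - (shape[1] %/% 2 + 1)) * pitch,
       y = (seq_len(shape[2]) - (shape[2] %/% 2 + 1)) * pitch)
}

#' Synthesize a microbead object field
#'
#' Builds the in-focus complex field of a set of spherical beads from
#' their chord-thickness profile: phase `2*pi*delta_n*h/lambda` and
#' amplitude `exp(-attenuation*h/2)`, where
#' `h(rho) = 2*sqrt(r^2 - rho^2)` and `delta_n = bead_index -
#' medium_index`.
#'
#' @param spec A [bead_spec()].
#' @param shape Integer grid size `c(nx, ny)` (even).
#' @param config An [optical_config()]; supplies the wavelength, medium
#'   index and sampling pitch.
#' @return A [complex_field()] whose phase peaks at
#'   `2*pi*delta_n*diameter/lambda` at each bead centre and is zero
#'   outside the beads.
#' @examples
#' f <- make_bead_field(bead_spec(), c(128, 128), optical_config())
#' max(field_phase(f))  # ~ 2*pi*0.35*4/0.627 = 14.03 rad
#' @export
make_bead_field <- function(spec, shape, config = optical_config()) {
  stopifnot(inherits(spec, "bead_spec"), length(shape) == 2)
  ax <- grid_axes(shape, config$pitch_um)
  r <- spec$diameter_um / 2
  half_x <- shape[1] * config$pitch_um / 2
  half_y <- shape[2] * config$pitch_um / 2
  h <- matrix(0, shape[1], shape[2])
  for (ctr in spec$centers) {
    if (abs(ctr[1]) + r > half_x || abs(ctr[2]) + r > half_y) {
      stop(sprintf(
        "bead at (%.3g, %.3g) um with radius %.3g um extends beyond the %.3g x %.3g um field of view",
        ctr[1], ctr[2], r, 2 * half_x, 2 * half_y), call. = FALSE)
    }
    rho2 <- outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, `+`)
    h <- h + 2 * sqrt(pmax(r^2 - rho2, 0))
  }
  delta_n <- spec$bead_index - config$medium_index
  phase <- 2 * pi * delta_n * h / config$wavelength_um
  amp <- exp(-spec$attenuation_per_um * h / 2)
  complex_field(amp * exp(1i * phase), config$pitch_um, phase_rad = phase)
}

# Isotropic low-pass with a raised-cosine roll-off ending at f = cutoff;
# guarantees (numerically) zero spectral power beyond the cutoff.
lowpass_filter <- function(shape, pitch, cutoff) {
  fx <- fft_freq(shape[1], pitch)
  fy <- fft_freq(shape[2], pitch)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  w <- matrix(0, shape[1], shape[2])
  pass <- fr <= cutoff / 2
  taper <- fr > cutoff / 2 & fr < cutoff
  w[pass] <- 1
  w[taper] <- 0.5 * (1 + cos(pi * (fr[taper] - cutoff / 2) / (cutoff / 2)))
  w
}

#' Synthesize a cell-like phase object field
#'
#' Generates a smooth, non-negative random phase field: seeded white noise
#' is low-pass filtered below `1 / smoothness_um`, windowed by a smooth
#' cell envelope, rescaled to the cytoplasm phase range, and a Gaussian
#' nucleus bump (width tied to the smoothness scale so the result stays
#' band-limited) is added at a random position inside the cell.  The
#' amplitude is unity everywhere: cells are modelled as pure phase
#' objects.
#'
#' @param spec A [cell_spec()].
#' @param shape Integer grid size `c(nx, ny)` (even).
#' @param config An [optical_config()].
#' @return A [complex_field()]; identical seeds give bit-identical fields.
#' @export
make_cell_field <- function(spec, shape, config = optical_config()) {
  stopifnot(inherits(spec, "cell_spec"), length(shape) == 2)
  pitch <- config$pitch_um
  ax <- grid_axes(shape, pitch)
  cutoff <- 1 / spec$smoothness_um
  w <- lowpass_filter(shape, pitch, cutoff)
  phase <- with_seed(spec$seed, {
    noise <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    smooth <- Re(ifft2(fft2(noise) * w))
    rng <- range(smooth)
    smooth <- if (diff(rng) > 0) (smooth - rng[1]) / diff(rng) else smooth * 0
    # smooth cell envelope, wider than the nucleus
    rho2 <- outer(ax$x^2, ax$y^2, `+`)
    envelope <- exp(-(rho2 / spec$cell_radius_um^2)^2)
    cyt <- spec$cytoplasm_phase_rad
    ph <- (cyt[1] + diff(cyt) * smooth) * envelope
    # nucleus: band-limited Gaussian bump offset randomly inside the cell
    off <- runif(2, -0.3, 0.3) * spec$cell_radius_um
    sig <- max(spec$smoothness_um, spec$cell_radius_um / 3)
    nuc_amp <- spec$nucleus_phase_rad[1] +
      diff(spec$nucleus_phase_rad) * runif(1)
    bump <- nuc_amp * exp(-(outer((ax$x - off[1])^2, (ax$y - off[2])^2,
                                  `+`)) / (2 * sig^2))
    ph <- ph + bump
    # the envelope product slightly broadens the spectrum: filter once
    # more, then lift any (tiny) undershoot so the phase stays >= 0
    ph <- Re(ifft2(fft2(ph) * w))
    ph - min(ph, 0)
  })
  complex_field(exp(1i * phase), pitch, phase_rad = phase)
}
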