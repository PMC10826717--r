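#' TIE solver configuration
#'
#' Numerical knobs of the transport-of-intensity solver.  The equation
#' itself leaves the discretization open; these defaults are the
#' conventional safe choices: central axial differences, an even-mirror
#' (Neumann-like) boundary extension to avoid wrap-around artifacts, a
#' relative intensity floor before the 1/I division, and an optional
#' Tikhonov term added to the inverse-Laplacian denominator for noisy
#' data.
#'
#' @param derivative_scheme `"central"` (uses the frames at z +/- dz) or
#'   `"forward"` (z and one neighbour).
#' @param poisson_regularizer_eps Non-negative Tikhonov constant added to
#'   `4*pi^2*(u^2+v^2)` in the spectral inverse Laplacian.
#' @param intensity_floor_fraction In-focus intensity is clamped below
#'   this fraction of its maximum before division; must be in (0, 1).
#' @param boundary `"mirror"` (even reflection, default) or `"periodic"`.
#' @return An object of class `tie_config`.
#' @export
tie_config <- function(derivative_scheme = c("central", "forward"),
                       poisson_regularizer_eps = 0,
                       intensity_floor_fraction = 1e-3,
                       boundary = c("mirror", "periodic")) {
  derivative_scheme <- match.arg(derivative_scheme)
  boundary <- match.arg(boundary)
  stopifnot(poisson_regularizer_eps >= 0,
            intensity_floor_fraction > 0, intensity_floor_fraction < 1)
  structure(list(derivative_scheme = derivative_scheme,
                 poisson_regularizer_eps = poisson_regularizer_eps,
                 intensity_floor_fraction = intensity_floor_fraction,
                 boundary = boundary),
            class = "tie_config")
}

#' Quantitative phase map
#'
#' @param phase_rad Finite numeric matrix of phase values in radians.
#' @param pitch_um Sampling pitch in micrometres.
#' @param normalization Optional `c(min_rad, max_rad)` record describing
#'   how the map is rendered to 8 bits (and inverted back).
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase_rad, pitch_um, normalization = NULL) {
  stopifnot(is.matrix(phase_rad), all(is.finite(phase_rad)), pitch_um > 0)
  structure(list(phase_rad = phase_rad, pitch_um = pitch_um,
                 normalization = normalization),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d, range [%.4g, %.4g] rad\n",
              nrow(x$phase_rad), ncol(x$phase_rad),
              min(x$phase_rad), max(x$phase_rad)))
  invisible(x)
}

# ---- mirror extension helpers -------------------------------------------

# Even (whole-sample) reflection to a doubled, periodic grid; DCT-II-type
# symmetry, so FFT-periodic operators act as Neumann operators on the
# original domain.
mirror_extend <- function(f) {
  f2 <- cbind(f, f[, rev(seq_len(ncol(f)))])
  rbind(f2, f2[rev(seq_len(nrow(f2))), ])
}

mirror_crop <- function(f, n1, n2) f[seq_len(n1), seq_len(n2)]

# Spectral inverse Laplacian on a periodic grid: divide by
# -(4*pi^2*(u^2+v^2) + eps), null the DC mode.
inv_laplacian_periodic <- function(f, pitch, eps = 0) {
  n1 <- nrow(f); n2 <- ncol(f)
  fx <- fft_freq(n1, pitch)
  fy <- fft_freq(n2, pitch)
  den <- -(4 * pi^2 * outer(fx^2, fy^2, `+`) + eps)
  Fh <- fft2(f) / den
  Fh[1, 1] <- 0
  g <- Re(ifft2(Fh))
  g - mean(g)
}

# Spectral gradient on a periodic grid (cycles/um frequencies).
spectral_gradient <- function(f, pitch) {
  n1 <- nrow(f); n2 <- ncol(f)
  fx <- fft_freq(n1, pitch)
  fy <- fft_freq(n2, pitch)
  Fh <- fft2(f)
  gx <- Re(ifft2(Fh * (2i * pi * fx)))
  gy <- Re(ifft2(t(t(Fh) * (2i * pi * fy))))
  list(gx = gx, gy = gy)
}

spectral_divergence <- function(gx, gy, pitch) {
  n1 <- nrow(gx); n2 <- ncol(gx)
  fx <- fft_freq(n1, pitch)
  fy <- fft_freq(n2, pitch)
  dx <- Re(ifft2(fft2(gx) * (2i * pi * fx)))
  dy <- Re(ifft2(t(t(fft2(gy)) * (2i * pi * fy))))
  dx + dy
}

#' Inverse Laplacian of a 2-D field
#'
#' Solves the Poisson equation `laplacian(g) = f` spectrally: the Fourier
#' transform of `f` is divided by `-(4*pi^2*(u^2+v^2) + eps)` and the
#' zero-frequency (DC) mode is nulled, so the solution is the zero-mean
#' representative of the solution family.  With `boundary = "mirror"` the
#' input is first extended by even reflection onto a doubled grid
#' (Neumann-like boundaries) and the result cropped back.
#'
#' @param f Finite numeric matrix.
#' @param pitch_um Sampling pitch in micrometres.
#' @param config A [tie_config()]; supplies `boundary` and the
#'   regularizer.
#' @return Zero-mean numeric matrix `g` with `laplacian(g) ~ f` (up to the
#'   nulled DC mode).
#' @export
inverse_laplacian <- function(f, pitch_um, config = tie_config()) {
  stopifnot(is.matrix(f), all(is.finite(f)))
  if (config$boundary == "mirror") {
    g <- inv_laplacian_periodic(mirror_extend(f), pitch_um,
                                config$poisson_regularizer_eps)
    g <- mirror_crop(g, nrow(f), ncol(f))
    g - mean(g)
  } else {
    inv_laplacian_periodic(f, pitch_um, config$poisson_regularizer_eps)
  }
}

#' Axial intensity derivative of a stack
#'
#' Estimates `dI/dz` at a given plane by finite differences over the
#' recorded frames: `(I(z + dz) - I(z - dz)) / (2 dz)` for the central
#' scheme, `(I(z + dz) - I(z)) / dz` for the forward scheme.
#'
#' @param stack An [intensity_stack()].
#' @param at_z Plane (micrometres) at which the derivative is taken;
#'   defaults to the frame nearest z = 0.
#' @param config A [tie_config()].
#' @return Numeric matrix, intensity units per micrometre.
#' @export
axial_derivative <- function(stack, at_z = NULL, config = tie_config()) {
  stopifnot(inherits(stack, "intensity_stack"))
  z <- stack$z_um
  if (is.null(at_z)) at_z <- z[which.min(abs(z))]
  i0 <- which(abs(z - at_z) < 1e-9)
  if (length(i0) != 1) {
    stop(sprintf("no frame at z = %g; available z: %s", at_z,
                 paste(signif(z, 4), collapse = ", ")), call. = FALSE)
  }
  if (config$derivative_scheme == "central") {
    if (i0 == 1 || i0 == length(z)) {
      stop(sprintf(
        "central derivative at z = %g needs bracketing frames; available z: %s",
        at_z, paste(signif(z, 4), collapse = ", ")), call. = FALSE)
    }
    dzm <- z[i0] - z[i0 - 1]
    dzp <- z[i0 + 1] - z[i0]
    if (abs(dzp - dzm) > 1e-9 * max(dzp, dzm)) {
      stop("central scheme needs equally spaced bracketing frames",
           call. = FALSE)
    }
    (stack$frames[[i0 + 1]] - stack$frames[[i0 - 1]]) / (dzp + dzm)
  } else {
    if (i0 == length(z)) {
      stop(sprintf(
        "forward derivative at z = %g needs a following frame; available z: %s",
        at_z, paste(signif(z, 4), collapse = ", ")), call. = FALSE)
    }
    (stack$frames[[i0 + 1]] - stack$frames[[i0]]) / (z[i0 + 1] - z[i0])
  }
}

#' Phase retrieval by the transport of intensity equation
#'
#' Recovers the object phase from an in-focus frame and a bracketing
#' defocus pair.  Under the paraxial approximation the axial intensity
#' derivative and the transverse phase satisfy
#' `dI/dz = -(1/k) div(I grad(phi))` with `k = 2*pi*n/lambda`, so the
#' phase is obtained by the nested spectral solution
#' `phi = invlap( div( (1/I) grad( invlap( -k dI/dz ) ) ) )`,
#' where `invlap` is the regularized inverse Laplacian.  For n = 1 the
#' prefactor reduces to the familiar `-2*pi/lambda`; carrying the medium
#' index keeps the solver consistent with propagation in immersion media.
#' The in-focus intensity is clamped below
#' `intensity_floor_fraction * max(I)` before the division, and the
#' returned phase is mean-subtracted (the TIE determines phase only up to
#' an additive constant).
#'
#' @param stack An [intensity_stack()] containing the in-focus frame and
#'   an equally spaced bracketing pair.
#' @param config A [tie_config()].
#' @param optical An [optical_config()]; supplies lambda and the medium
#'   index.
#' @param at_z In-focus plane; defaults to the frame nearest z = 0.
#' @param dz_index How many frames to either side form the derivative
#'   pair (1 = nearest neighbours).
#' @return A [phase_map()] (zero mean, radians).
#' @export
tie_solve <- function(stack, config = tie_config(),
                      optical = stack$config, at_z = NULL, dz_index = 1) {
  stopifnot(inherits(stack, "intensity_stack"))
  z <- stack$z_um
  if (is.null(at_z)) at_z <- z[which.min(abs(z))]
  i0 <- which(abs(z - at_z) < 1e-9)
  if (length(i0) != 1) {
    stop(sprintf("no frame at z = %g; available z: %s", at_z,
                 paste(signif(z, 4), collapse = ", ")), call. = FALSE)
  }
  if (i0 - dz_index < 1 || i0 + dz_index > length(z)) {
    stop(sprintf(
      "frames bracketing z = %g at offset %d are missing; available z: %s",
      at_z, dz_index, paste(signif(z, 4), collapse = ", ")), call. = FALSE)
  }
  dz <- (z[i0 + dz_index] - z[i0 - dz_index]) / 2
  dIdz <- (stack$frames[[i0 + dz_index]] - stack$frames[[i0 - dz_index]]) /
    (2 * dz)
  I0 <- stack$frames[[i0]]
  pitch <- stack$pitch_um
  k <- 2 * pi * optical$medium_index / optical$wavelength_um
  eps <- config$poisson_regularizer_eps

  n1 <- nrow(I0); n2 <- ncol(I0)
  mirror <- config$boundary == "mirror"
  if (mirror) {
    dIdz <- mirror_extend(dIdz)
    I0 <- mirror_extend(I0)
  }
  floor_val <- config$intensity_floor_fraction * max(I0)
  I0 <- pmax(I0, floor_val)

  psi <- inv_laplacian_periodic(-k * dIdz, pitch, eps)
  g <- spectral_gradient(psi, pitch)
  div <- spectral_divergence(g$gx / I0, g$gy / I0, pitch)
  phi <- inv_laplacian_periodic(div, pitch, eps)
  if (mirror) phi <- mirror_crop(phi, n1, n2)
  phi <- phi - mean(phi)
  phase_map(phi, pitch)
}

#' Tamura coefficient of an image
#'
#' Sharpness/contrast measure `sqrt(sd(I) / mean(I))` (population
#' standard deviation).  It is invariant under multiplication of the
#' image by a positive constant, and zero for a constant image.  For a
#' pure phase object the in-focus intensity is the flattest of a defocus
#' stack, so the in-focus frame minimizes the coefficient; absorbing
#' objects are sharpest in focus and maximize it.
#'
#' @param image Non-negative numeric matrix with positive mean.
#' @return Non-negative scalar.
#' @export
tamura_coefficient <- function(image) {
  stopifnot(is.matrix(image) || is.numeric(image))
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  m <- mean(image)
  if (m <= 0) stop("image mean must be positive", call. = FALSE)
  s <- sqrt(mean((image - m)^2))
  sqrt(s / m)
}

#' Select the in-focus frame of a stack
#'
#' Scores every frame with the Tamura coefficient and returns the index
#' of the extremal frame.  The default `mode = "min"` suits
#' phase-dominant samples (least intensity contrast in focus); use
#' `mode = "max"` for absorbing samples.  Ties are broken toward the
#' frame nearest z = 0.
#'
#' @param stack An [intensity_stack()] with at least 3 frames.
#' @param mode `"min"` or `"max"`.
#' @return Integer frame index.
#' @export
select_focus <- function(stack, mode = c("min", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "intensity_stack"))
  if (length(stack$frames) < 3) {
    stop("focus selection needs at least 3 frames", call. = FALSE)
  }
  tc <- vapply(stack$frames, tamura_coefficient, numeric(1))
  best <- if (mode == "min") min(tc) else max(tc)
  cand <- which(abs(tc - best) <= 1e-12 * max(abs(tc), 1e-300))
  cand[which.min(abs(stack$z_um[cand]))]
}

#' Thickness map
#'
#' @param thickness_um Numeric matrix of physical thickness in
#'   micrometres.
#' @param delta_n Refractive index difference used in the conversion.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(thickness_um, delta_n) {
  stopifnot(is.matrix(thickness_um), all(is.finite(thickness_um)))
  structure(list(thickness_um = thickness_um, delta_n = delta_n),
            class = "thickness_map")
}

#' Convert phase to physical thickness
#'
#' Applies `h = lambda * phi / (2 * pi * delta_n)` element-wise, mapping
#' measured phase delay (radians) to object thickness (micrometres) given
#' the refractive index contrast between object and medium.
#'
#' @param phase A [phase_map()] (or bare matrix of radians).
#' @param delta_n Non-zero refractive index difference.
#' @param optical An [optical_config()]; supplies the wavelength.
#' @return A [thickness_map()].
#' @examples
#' pm <- phase_map(matrix(14.03, 2, 2), 0.08625)
#' phase_to_thickness(pm, 0.35)$thickness_um\[1, 1\]  # ~ 4 um
#' @export
phase_to_thickness <- function(phase, delta_n, optical = optical_config()) {
  if (delta_n == 0) {
    stop("delta_n must be non-zero to convert phase to thickness",
         call. = FALSE)
  }
  phi <- if (inherits(phase, "phase_map")) phase$phase_rad else phase
  thickness_map(optical$wavelength_um * phi / (2 * pi * delta_n), delta_n)
}

#' Render a phase map to 8-bit and back
#'
#' `phase_to_uint8()` linearly rescales phase to 0..255 integers and
#' records the (min, max) range; `uint8_to_phase()` inverts the mapping
#' using the record (exact up to quantization, i.e. within
#' `(max - min)/255`).
#'
#' @param phase A [phase_map()].
#' @return `phase_to_uint8()`: integer matrix with a `normalization`
#'   attribute; `uint8_to_phase()`: a [phase_map()].
#' @export
phase_to_uint8 <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  rng <- range(phase$phase_rad)
  scale <- if (diff(rng) > 0) 255 / diff(rng) else 0
  q <- round((phase$phase_rad - rng[1]) * scale)
  storage.mode(q) <- "integer"
  attr(q, "normalization") <- rng
  q
}

#' @rdname phase_to_uint8
#' @param q Integer matrix from `phase_to_uint8()`.
#' @param normalization `c(min, max)` record; defaults to the attribute
#'   stored on `q`.
#' @param pitch_um Pitch of the reconstructed map.
#' @export
uint8_to_phase <- function(q, normalization = attr(q, "normalization"),
                           pitch_um = 1) {
  stopifnot(!is.null(normalization))
  rng <- normalization
  phi <- if (diff(range(rng)) > 0) {
    rng[1] + q * (rng[2] - rng[1]) / 255
  } else {
    matrix(rng[1], nrow(q), ncol(q))
  }
  phase_map(matrix(phi, nrow(q), ncol(q)), pitch_um, normalization = rng)
}
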