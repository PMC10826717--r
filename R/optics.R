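#' Microscope configuration
#'
#' Bundles the optical constants that fix the physics of the forward model
#' and of the phase solver: illumination wavelength, objective
#' magnification and numerical aperture, camera pixel size and the
#' refractive index of the immersion medium.  The object-plane sampling
#' pitch is derived as `camera_pixel_um / magnification` (0.08625 um at the
#' defaults, which describe a 40x/0.65 objective with a 3.45 um camera
#' pixel and a 627 nm LED).
#'
#' @param wavelength_um Illumination (vacuum) wavelength in micrometres.
#' @param camera_pixel_um Physical camera pixel size in micrometres.
#' @param magnification Lateral magnification of the objective.
#' @param numerical_aperture Objective NA; must be below `medium_index`.
#' @param medium_index Refractive index of the immersion medium
#'   (1.33 for water).
#' @param propagator Either `"angular_spectrum"` (exact scalar transfer
#'   function) or `"fresnel"` (paraxial quadratic approximation, useful to
#'   cross-check the paraxial derivation behind the TIE).
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$pitch_um   # 0.08625
#' @export
optical_config <- function(wavelength_um = 0.627,
                           camera_pixel_um = 3.45,
                           magnification = 40,
                           numerical_aperture = 0.65,
                           medium_index = 1.33,
                           propagator = c("angular_spectrum", "fresnel")) {
  propagator <- match.arg(propagator)
  stopifnot(wavelength_um > 0, camera_pixel_um > 0, magnification > 0,
            numerical_aperture > 0)
  if (numerical_aperture >= medium_index) {
    stop("numerical_aperture must be smaller than medium_index", call. = FALSE)
  }
  structure(
    list(wavelength_um = wavelength_um,
         camera_pixel_um = camera_pixel_um,
         magnification = magnification,
         numerical_aperture = numerical_aperture,
         medium_index = medium_index,
         pitch_um = camera_pixel_um / magnification,
         propagator = propagator),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength  : %.4g um\n", x$wavelength_um))
  cat(sprintf("  pixel/mag   : %.4g um / %gx -> pitch %.6g um\n",
              x$camera_pixel_um, x$magnification, x$pitch_um))
  cat(sprintf("  NA / medium : %.3g / n = %.3g\n",
              x$numerical_aperture, x$medium_index))
  cat(sprintf("  propagator  : %s\n", x$propagator))
  invisible(x)
}

#' Complex scalar field
#'
#' A 2-D complex amplitude u(x, y) sampled on a regular grid.  The squared
#' modulus is the intensity a camera would record, the argument is the
#' optical phase in radians.
#'
#' @param u Complex (or real) matrix with even side lengths.
#' @param pitch_um Sampling pitch in micrometres.
#' @param phase_rad Optional matrix of the (unwrapped) phase that
#'   generated `u`; phantom constructors attach it so the continuous
#'   ground-truth phase survives even where `Arg(u)` would wrap.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(u, pitch_um, phase_rad = NULL) {
  if (!is.matrix(u)) stop("u must be a matrix", call. = FALSE)
  if (any(dim(u) %% 2 != 0)) {
    stop("field dimensions must be even for FFT-based propagation",
         call. = FALSE)
  }
  storage.mode(u) <- "complex"
  if (any(!is.finite(Re(u))) || any(!is.finite(Im(u)))) {
    stop("field contains non-finite values", call. = FALSE)
  }
  stopifnot(pitch_um > 0)
  structure(list(u = u, pitch_um = pitch_um, phase_rad = phase_rad),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d, pitch %.5g um, power %.5g\n",
              nrow(x$u), ncol(x$u), x$pitch_um, field_power(x)))
  invisible(x)
}

#' Field intensity and phase
#'
#' @param field A `complex_field`.
#' @return `field_intensity()` the squared modulus, `field_phase()` the
#'   unwrapped generating phase when the field carries one (phantoms do),
#'   otherwise the wrapped argument `Arg(u)`; `field_power()` the total
#'   power sum(|u|^2) * pitch^2.
#' @export
field_intensity <- function(field) Mod(field$u)^2

#' @rdname field_intensity
#' @export
field_phase <- function(field) {
  if (!is.null(field$phase_rad)) field$phase_rad else Arg(field$u)
}

#' @rdname field_intensity
#' @export
field_power <- function(field) sum(Mod(field$u)^2) * field$pitch_um^2

# FFT sample frequencies in cycles per micrometre, fftshift-free order.
fft_freq <- function(n, pitch) {
  k <- c(seq.int(0L, n %/% 2L - 1L), seq.int(-(n %/% 2L), -1L))
  k / (n * pitch)
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

#' Free-space propagation of a complex field
#'
#' Propagates a sampled scalar field over a signed axial distance using
#' the angular-spectrum method: the field's Fourier transform is
#' multiplied by the transfer function
#' `H = exp(i * 2 * pi * dz * sqrt((n/lambda)^2 - fx^2 - fy^2))`, with
#' evanescent components (negative radicand) suppressed.  With
#' `propagator = "fresnel"` in the configuration the paraxial quadratic
#' phase `exp(i*2*pi*n*dz/lambda) * exp(-i*pi*lambda*dz*(fx^2+fy^2)/n)` is
#' used instead, matching the approximation under which the transport of
#' intensity equation is derived.
#'
#' @param field A [complex_field()].
#' @param dz_um Signed defocus distance in micrometres; `dz_um = 0`
#'   returns the input unchanged.
#' @param config An [optical_config()].
#' @return The propagated `complex_field`.
#' @export
propagate <- function(field, dz_um, config = optical_config()) {
  stopifnot(inherits(field, "complex_field"))
  if (dz_um == 0) return(field)
  u <- field$u
  n1 <- nrow(u); n2 <- ncol(u)
  fx <- fft_freq(n1, field$pitch_um)
  fy <- fft_freq(n2, field$pitch_um)
  f2 <- outer(fx^2, fy^2, `+`)
  n_med <- config$medium_index
  lam <- config$wavelength_um
  if (config$propagator == "fresnel") {
    H <- exp(1i * 2 * pi * n_med * dz_um / lam) *
      exp(-1i * pi * lam * dz_um * f2 / n_med)
  } else {
    rad <- (n_med / lam)^2 - f2
    H <- matrix(0 + 0i, n1, n2)
    prop <- rad > 0
    H[prop] <- exp(1i * 2 * pi * dz_um * sqrt(rad[prop]))
  }
  complex_field(ifft2(fft2(u) * H), field$pitch_um)
}

# Embed a field in a larger grid filled with the mean border value; used
# to suppress periodic wrap-around during phantom stack generation.
pad_field <- function(field, factor = 2) {
  u <- field$u
  n1 <- nrow(u); n2 <- ncol(u)
  m1 <- n1 * factor; m2 <- n2 * factor
  border <- c(u[1, ], u[n1, ], u[, 1], u[, n2])
  big <- matrix(mean(border), m1, m2)
  i0 <- (m1 - n1) %/% 2; j0 <- (m2 - n2) %/% 2
  big[i0 + seq_len(n1), j0 + seq_len(n2)] <- u
  list(field = complex_field(big, field$pitch_um), i0 = i0, j0 = j0,
       n1 = n1, n2 = n2)
}

crop_field <- function(field, pad) {
  complex_field(field$u[pad$i0 + seq_len(pad$n1), pad$j0 + seq_len(pad$n2)],
                field$pitch_um)
}

#' Defocused intensity stack
#'
#' An ordered set of non-negative intensity frames with their axial
#' positions.  This is the data a TIE microscope records while scanning
#' the focus along z.
#'
#' @param frames List of non-negative numeric matrices, one per plane.
#' @param z_um Strictly increasing numeric vector of axial positions
#'   (micrometres) of the frames.
#' @param pitch_um Object-plane sampling pitch in micrometres.
#' @param config The [optical_config()] that produced (or describes) the
#'   stack.
#' @param source_id Optional identifier of the imaged object.
#' @return An object of class `intensity_stack`.
#' @export
intensity_stack <- function(frames, z_um, pitch_um,
                            config = optical_config(), source_id = NULL) {
  if (length(frames) != length(z_um)) {
    stop("need exactly one frame per z position", call. = FALSE)
  }
  if (is.unsorted(z_um, strictly = TRUE)) {
    stop("z positions must be strictly increasing", call. = FALSE)
  }
  for (f in frames) {
    if (!is.matrix(f) || any(f < 0) || any(!is.finite(f))) {
      stop("frames must be finite non-negative matrices", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, z_um = as.numeric(z_um), pitch_um = pitch_um,
         config = config, source_id = source_id),
    class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  cat(sprintf("<intensity_stack> %d frames of %d x %d, z = [%g, %g] um\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              min(x$z_um), max(x$z_um)))
  invisible(x)
}

#' Record an intensity stack from a complex object field
#'
#' Propagates the in-focus object field to every requested defocus plane
#' and records the intensity there, emulating the axial scan of a TIE
#' microscope (by default +/-60 um in 15 um steps).  Before propagation
#' the field is embedded in a grid twice as large (filled with the border
#' value) and cropped back afterwards, so that periodic FFT wrap-around
#' does not contaminate the frames.
#'
#' @param field The in-focus [complex_field()].
#' @param z_um Sorted vector of defocus distances in micrometres.
#' @param config An [optical_config()].
#' @param noise Optional shot-noise spec, `list(photons = P, seed = S)`:
#'   each frame is replaced by `rpois(P * I) / P`, i.e. Poisson counting
#'   noise at `P` expected photons per unit intensity.
#' @param pad_factor Internal zero-defocus padding factor (>= 1).
#' @param source_id Optional identifier stored on the stack.
#' @return An [intensity_stack()].
#' @examples
#' cfg <- optical_config()
#' f <- make_bead_field(bead_spec(centers = list(c(0, 0))), c(64, 64), cfg)
#' st <- generate_stack(f, z_um = seq(-60, 60, by = 15), config = cfg)
#' length(st$frames)  # 9
#' @export
generate_stack <- function(field, z_um = seq(-60, 60, by = 15),
                           config = optical_config(), noise = NULL,
                           pad_factor = 2, source_id = NULL) {
  if (length(z_um) == 0) stop("z_um must be non-empty", call. = FALSE)
  if (is.unsorted(z_um, strictly = TRUE)) {
    stop("z_um must be strictly increasing", call. = FALSE)
  }
  padded <- if (pad_factor > 1) pad_field(field, pad_factor) else NULL
  frames <- lapply(z_um, function(z) {
    fz <- if (is.null(padded)) {
      propagate(field, z, config)
    } else {
      crop_field(propagate(padded$field, z, config), padded)
    }
    field_intensity(fz)
  })
  if (!is.null(noise)) {
    stopifnot(is.list(noise), !is.null(noise$photons))
    photons <- noise$photons
    if (!is.null(noise$seed)) {
      frames <- withr::with_seed(noise$seed, lapply(frames, function(fr) {
        matrix(rpois(length(fr), photons * fr) / photons, nrow(fr), ncol(fr))
      }))
    } else {
      frames <- lapply(frames, function(fr) {
        matrix(rpois(length(fr), photons * fr) / photons, nrow(fr), ncol(fr))
      })
    }
  }
  intensity_stack(frames, z_um, field$pitch_um, config, source_id = source_id)
}
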