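test_that("optical config derives the object-plane pitch and validates", {
  cfg <- optical_config()
  expect_equal(cfg$pitch_um, 3.45 / 40)
  expect_equal(cfg$wavelength_um, 0.627)
  expect_error(optical_config(numerical_aperture = 1.4, medium_index = 1.33),
               "numerical_aperture")
  expect_error(optical_config(wavelength_um = -1))
})

test_that("bead field phase matches the chord-thickness closed form", {
  cfg <- optical_config()
  f <- make_bead_field(bead_spec(), c(128, 128), cfg)
  expected_peak <- 2 * pi * (1.68 - 1.33) * 4 / 0.627
  expect_equal(max(field_phase(f)), expected_peak, tolerance = 1e-6)
  # phase is zero outside the bead footprint
  phase <- field_phase(f)
  ax <- (seq_len(128) - 65) * cfg$pitch_um
  outside <- outer(ax^2, ax^2, `+`) > 2.2^2
  expect_true(all(phase[outside] == 0))
})

test_that("index-matched beads vanish and zero attenuation means unit amplitude", {
  cfg <- optical_config()
  f0 <- make_bead_field(bead_spec(bead_index = cfg$medium_index),
                        c(64, 64), cfg)
  expect_true(all(field_phase(f0) == 0))
  f1 <- make_bead_field(bead_spec(attenuation_per_um = 0), c(64, 64), cfg)
  expect_equal(max(abs(Mod(f1$u) - 1)), 0, tolerance = 1e-12)
})

test_that("beads outside the field of view are rejected with coordinates", {
  cfg <- optical_config()
  expect_error(
    make_bead_field(bead_spec(centers = list(c(10, 0))), c(64, 64), cfg),
    "field of view")
})

test_that("cell phantoms are reproducible, seed-sensitive and band-limited", {
  cfg <- optical_config()
  spec <- cell_spec(seed = 42, cell_radius_um = 2, smoothness_um = 0.8)
  f1 <- make_cell_field(spec, c(64, 64), cfg)
  f2 <- make_cell_field(spec, c(64, 64), cfg)
  expect_identical(f1$u, f2$u)
  f3 <- make_cell_field(cell_spec(seed = 43, cell_radius_um = 2,
                                  smoothness_um = 0.8), c(64, 64), cfg)
  expect_false(identical(f1$u, f3$u))
  ph <- field_phase(f1)
  expect_true(all(ph >= 0))
  # spectral power beyond 1/smoothness is negligible
  fx <- tieqpi:::fft_freq(64, cfg$pitch_um)
  spec_pow <- Mod(tieqpi:::fft2(ph))^2
  beyond <- outer(fx^2, fx^2, `+`) >= (1 / 0.8)^2
  expect_lt(sum(spec_pow[beyond]) / sum(spec_pow), 1e-6)
})

test_that("zero phase ranges give a zero-phase cell", {
  f <- make_cell_field(cell_spec(cytoplasm_phase_rad = c(0, 0),
                                 nucleus_phase_rad = c(0, 0),
                                 seed = 1), c(32, 32), optical_config())
  expect_true(all(field_phase(f) == 0))
})

test_that("propagation is the identity at dz = 0 and unitary on band-limited fields", {
  cfg <- optical_config()
  f <- bandlimited_field(64, seed = 2)
  expect_identical(propagate(f, 0, cfg)$u, f$u)
  fp <- propagate(f, 9.7, cfg)
  fb <- propagate(fp, -9.7, cfg)
  expect_lt(max(Mod(fb$u - f$u)) / max(Mod(f$u)), 1e-10)
})

test_that("propagation conserves power and composes over distances", {
  cfg <- optical_config()
  f <- bandlimited_field(64, seed = 3)
  p0 <- field_power(f)
  fp <- propagate(f, 13.1, cfg)
  expect_lt(abs(field_power(fp) - p0) / p0, 1e-9)
  f_ab <- propagate(propagate(f, 4.2, cfg), 8.9, cfg)
  expect_lt(max(Mod(f_ab$u - fp$u)) / max(Mod(fp$u)), 1e-9)
})

test_that("a uniform plane wave is an eigenfunction of free-space propagation", {
  cfg <- optical_config()
  pw <- complex_field(matrix(1 + 0i, 32, 32), cfg$pitch_um)
  out <- propagate(pw, 37, cfg)
  intensity <- field_intensity(out)
  expect_lt(diff(range(intensity)) / mean(intensity), 1e-10)
})

test_that("the fresnel propagator agrees with angular spectrum in the paraxial band", {
  cfg_as <- optical_config()
  cfg_fr <- optical_config(propagator = "fresnel")
  f <- bandlimited_field(64, seed = 4, cutoff_frac = 0.05)
  a <- propagate(f, 5, cfg_as)
  b <- propagate(f, 5, cfg_fr)
  expect_lt(max(Mod(a$u - b$u)) / max(Mod(a$u)), 1e-3)
})

test_that("generate_stack records one frame per plane and validates z", {
  cfg <- optical_config()
  f <- make_bead_field(bead_spec(), c(64, 64), cfg)
  st <- generate_stack(f, seq(-60, 60, by = 15), cfg)
  expect_length(st$frames, 9)
  expect_true(all(vapply(st$frames, min, numeric(1)) >= 0))
  expect_error(generate_stack(f, c(0, -15, 15), cfg), "increasing")
  expect_error(generate_stack(f, numeric(0), cfg), "non-empty")
})

test_that("a pure-phase object has a flat in-focus intensity", {
  cfg <- optical_config()
  f <- make_cell_field(cell_spec(seed = 5, cell_radius_um = 2,
                                 smoothness_um = 0.8), c(64, 64), cfg)
  st <- generate_stack(f, c(-15, 0, 15), cfg)
  infocus <- st$frames[[2]]
  expect_lt(diff(range(infocus)) / mean(infocus), 1e-9)
})

test_that("stacks are deterministic, and shot noise is seeded", {
  cfg <- optical_config()
  f <- make_bead_field(bead_spec(), c(64, 64), cfg)
  s1 <- generate_stack(f, c(-15, 0, 15), cfg)
  s2 <- generate_stack(f, c(-15, 0, 15), cfg)
  expect_identical(s1$frames, s2$frames)
  n1 <- generate_stack(f, c(-15, 0, 15), cfg,
                       noise = list(photons = 500, seed = 9))
  n2 <- generate_stack(f, c(-15, 0, 15), cfg,
                       noise = list(photons = 500, seed = 9))
  expect_identical(n1$frames, n2$frames)
  expect_false(identical(n1$frames, s1$frames))
  expect_true(all(vapply(n1$frames, min, numeric(1)) >= 0))
})
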