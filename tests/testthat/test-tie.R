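test_that("inverse Laplacian inverts its spectral forward operator", {
  cfg <- tie_config(boundary = "periodic")
  n <- 32; h <- 0.5
  expect_equal(inverse_laplacian(matrix(0, n, n), h, cfg),
               matrix(0, n, n))
  # sine eigenfunction: f = sin(2 pi x / L) -> g = -(L/2pi)^2 f
  L <- n * h
  x <- (seq_len(n) - 1) * h
  f <- matrix(sin(2 * pi * x / L), n, n)
  g <- inverse_laplacian(f, h, cfg)
  expect_equal(g, -(L / (2 * pi))^2 * f, tolerance = 1e-10)
})

test_that("FFT inverse Laplacian agrees with a dense pseudo-inverse of the 5-point operator", {
  n <- 32; h <- 0.5
  idx <- function(i, j) ((i - 1) %% n) + n * ((j - 1) %% n) + 1
  L <- matrix(0, n * n, n * n)
  for (ii in 1:n) for (jj in 1:n) {
    r <- idx(ii, jj)
    L[r, r] <- L[r, r] - 4 / h^2
    for (nb in list(c(ii + 1, jj), c(ii - 1, jj),
                    c(ii, jj + 1), c(ii, jj - 1))) {
      L[r, idx(nb[1], nb[2])] <- L[r, idx(nb[1], nb[2])] + 1 / h^2
    }
  }
  Lpinv <- MASS::ginv(L)
  # random field restricted to well-resolved frequencies, where the
  # spectral and 5-point discretizations coincide
  f <- withr::with_seed(8, {
    fx <- tieqpi:::fft_freq(n, 1)
    lp <- exp(-2 * pi^2 * 2^2 * outer(fx^2, fx^2, `+`))
    Re(tieqpi:::ifft2(tieqpi:::fft2(matrix(rnorm(n * n), n, n)) * lp))
  })
  f <- f - mean(f)
  g_dense <- matrix(Lpinv %*% as.vector(f), n, n)
  g_dense <- g_dense - mean(g_dense)
  g_fft <- inverse_laplacian(f, h, tie_config(boundary = "periodic"))
  expect_lt(sqrt(sum((g_dense - g_fft)^2) / sum(g_dense^2)), 1e-2)
  # exact round trip through the spectral forward Laplacian
  fx <- tieqpi:::fft_freq(n, h)
  lap <- Re(tieqpi:::ifft2(tieqpi:::fft2(g_fft) *
                             (-4 * pi^2 * outer(fx^2, fx^2, `+`))))
  expect_lt(max(abs(lap - f)), 1e-10)
})

test_that("axial derivative is exact on constant and linear-in-z stacks", {
  cfg <- optical_config()
  frames <- replicate(3, matrix(2, 8, 8), simplify = FALSE)
  st <- intensity_stack(frames, c(-1, 0, 1), cfg$pitch_um, cfg)
  expect_equal(axial_derivative(st), matrix(0, 8, 8))
  # I(z) = 5 + c * z with c = 0.3
  ramp <- lapply(c(-1, 0, 1), function(z) matrix(5 + 0.3 * z, 8, 8))
  str <- intensity_stack(ramp, c(-1, 0, 1), cfg$pitch_um, cfg)
  expect_equal(axial_derivative(str), matrix(0.3, 8, 8))
  expect_equal(axial_derivative(str, config = tie_config("forward")),
               matrix(0.3, 8, 8))
  expect_error(axial_derivative(str, at_z = 1), "bracketing")
  expect_error(axial_derivative(str, at_z = 7), "available z")
})

test_that("finite-difference axial derivative matches a fine-step oracle", {
  cfg <- optical_config()
  f <- gaussian_phase_field(512, peak = 3, sigma_um = 5)
  st <- generate_stack(f, c(-1, 0, 1), cfg)
  d_test <- axial_derivative(st)
  # Richardson-extrapolated derivative from 0.01 um steps
  h <- 0.01
  st_fine <- generate_stack(f, c(-2 * h, -h, 0, h, 2 * h), cfg)
  Dh <- (st_fine$frames[[4]] - st_fine$frames[[2]]) / (2 * h)
  D2h <- (st_fine$frames[[5]] - st_fine$frames[[1]]) / (4 * h)
  d_oracle <- (4 * Dh - D2h) / 3
  rel_rms <- sqrt(mean((d_test - d_oracle)^2)) / sqrt(mean(d_oracle^2))
  expect_lt(rel_rms, 0.02)
  # lossless pure-phase field: mean derivative ~ 0
  expect_lt(abs(mean(d_test)) / stats::sd(d_oracle), 0.01)
})

test_that("tie_solve returns zero phase for a z-invariant stack", {
  cfg <- optical_config()
  frames <- replicate(3, matrix(1, 16, 16), simplify = FALSE)
  st <- intensity_stack(frames, c(-1, 0, 1), cfg$pitch_um, cfg)
  ph <- tie_solve(st)
  expect_lt(max(abs(ph$phase_rad)), 1e-12)
})

test_that("tie_solve recovers a smooth Gaussian phase", {
  cfg <- optical_config()
  f <- gaussian_phase_field(512, peak = 3, sigma_um = 5)
  st <- generate_stack(f, c(-1, 0, 1), cfg)
  rec <- tie_solve(st)
  truth <- field_phase(f) - mean(field_phase(f))
  expect_equal(mean(rec$phase_rad), 0, tolerance = 1e-10)
  expect_lt(abs(max(rec$phase_rad) - max(truth)) / 3, 0.05)
  expect_gt(score_images(rec$phase_rad, truth)$ssim, 0.95)
})

test_that("tie_solve is gauge invariant and linear in the weak-phase regime", {
  cfg <- optical_config()
  # gauge: a global phase offset leaves every intensity unchanged
  base <- gaussian_phase_field(128, peak = 0.2, sigma_um = 1.2)
  shifted <- complex_field(base$u * exp(1i * 0.7), base$pitch_um)
  st1 <- generate_stack(base, c(-1, 0, 1), cfg)
  st2 <- generate_stack(shifted, c(-1, 0, 1), cfg)
  expect_equal(tie_solve(st1)$phase_rad, tie_solve(st2)$phase_rad,
               tolerance = 1e-12)
  # linearity: scaling a weak phase by alpha scales the recovery by alpha
  alpha <- 3
  f1 <- gaussian_phase_field(128, peak = 0.05, sigma_um = 1.2)
  f2 <- gaussian_phase_field(128, peak = 0.05 * alpha, sigma_um = 1.2)
  r1 <- tie_solve(generate_stack(f1, c(-1, 0, 1), cfg))
  r2 <- tie_solve(generate_stack(f2, c(-1, 0, 1), cfg))
  ratio <- max(r2$phase_rad) / max(r1$phase_rad)
  expect_lt(abs(ratio - alpha) / alpha, 0.03)
})

test_that("tie_solve survives zero in-focus intensity via the floor", {
  cfg <- optical_config()
  withr::with_seed(3, {
    frames <- list(matrix(runif(256), 16, 16),
                   matrix(runif(256, 0, 1), 16, 16),
                   matrix(runif(256), 16, 16))
  })
  frames[[2]][5:8, 5:8] <- 0  # dead pixels in the in-focus frame
  st <- intensity_stack(frames, c(-1, 0, 1), optical_config()$pitch_um, cfg)
  expect_true(all(is.finite(tie_solve(st)$phase_rad)))
})

test_that("bead diameter is recovered through the thickness conversion", {
  cfg <- optical_config()
  bead <- make_bead_field(bead_spec(), c(256, 256), cfg)
  for (dz in c(0.5, 1)) {
    st <- generate_stack(bead, c(-dz, 0, dz), cfg)
    rec <- tie_solve(st)
    aligned <- rec$phase_rad - median(rec$phase_rad)
    peak_phase <- diffraction_limited_peak(aligned, cfg)
    h_peak <- phase_to_thickness(phase_map(matrix(peak_phase, 1, 1),
                                           cfg$pitch_um),
                                 delta_n = 0.35, cfg)$thickness_um[1, 1]
    expect_lt(abs(h_peak - 4) / 4, 0.10)
  }
})

test_that("tamura coefficient is sqrt(sd/mean), scale invariant, and guarded", {
  expect_equal(tamura_coefficient(matrix(3, 4, 4)), 0)
  expect_equal(tamura_coefficient(matrix(c(0, 2), 1, 2)), 1)
  img <- matrix(runif(64, 0.1, 1), 8, 8)
  expect_equal(tamura_coefficient(img), tamura_coefficient(5 * img),
               tolerance = 1e-12)
  expect_error(tamura_coefficient(matrix(0, 4, 4)), "mean")
  expect_error(tamura_coefficient(matrix(c(-1, 2), 1, 2)), "non-negative")
})

test_that("focus selection finds z = 0 and breaks ties toward focus", {
  cfg <- optical_config()
  bead <- make_bead_field(bead_spec(attenuation_per_um = 0), c(64, 64), cfg)
  st <- generate_stack(bead, seq(-60, 60, by = 15), cfg)
  expect_equal(st$z_um[select_focus(st)], 0)
  # identical frames: tie-break toward the frame nearest z = 0
  same <- replicate(5, matrix(1:16 / 16, 4, 4), simplify = FALSE)
  st2 <- intensity_stack(same, c(-30, -15, 0, 15, 30), cfg$pitch_um, cfg)
  expect_equal(select_focus(st2), 3L)
  # absorbing (amplitude-only) disk is sharpest in focus
  disk <- make_bead_field(bead_spec(bead_index = cfg$medium_index),
                          c(64, 64), cfg)
  st3 <- generate_stack(disk, seq(-60, 60, by = 15), cfg)
  expect_equal(st3$z_um[select_focus(st3, mode = "max")], 0)
  expect_error(select_focus(intensity_stack(same[1:2], c(0, 1),
                                            cfg$pitch_um, cfg)),
               "3 frames")
})

test_that("phase-to-thickness conversion is the printed linear map", {
  cfg <- optical_config()
  pm <- phase_map(matrix(2 * pi * 0.35 * 4 / 0.627, 2, 2), cfg$pitch_um)
  th <- phase_to_thickness(pm, 0.35, cfg)
  expect_equal(th$thickness_um[1, 1], 4, tolerance = 1e-12)
  expect_equal(phase_to_thickness(phase_map(matrix(0, 2, 2), 1), 0.35,
                                  cfg)$thickness_um,
               matrix(0, 2, 2))
  th2 <- phase_to_thickness(pm, 0.70, cfg)
  expect_equal(th2$thickness_um, th$thickness_um / 2)
  expect_error(phase_to_thickness(pm, 0, cfg), "non-zero")
})

test_that("8-bit round trip stays within quantization", {
  pm <- phase_map(matrix(runif(64, -2, 12), 8, 8), 1)
  q <- phase_to_uint8(pm)
  back <- uint8_to_phase(q)
  rng <- attr(q, "normalization")
  expect_lt(max(abs(back$phase_rad - pm$phase_rad)), diff(rng) / 255)
})
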