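# Layer-level finite-difference gradient checks plus architecture and
# training-step contracts for the conditional GAN.

num_grad <- function(fn, a, i, h = 1e-6) {
  a1 <- a; a1[i] <- a1[i] + h
  a2 <- a; a2[i] <- a2[i] - h
  (fn(a1) - fn(a2)) / (2 * h)
}

test_that("convolution forward/backward match finite differences", {
  withr::with_seed(42, {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    w <- array(rnorm(4 * 4 * 2 * 3, 0, 0.3), c(4, 4, 2, 3))
    b <- rnorm(3)
    y <- tieqpi:::nn_conv_fwd(x, w, b, 2, 1)
    dy <- array(rnorm(length(y)), dim(y))
    g <- tieqpi:::nn_conv_bwd(x, w, dy, 2, 1)
    loss <- function(x, w, b) sum(tieqpi:::nn_conv_fwd(x, w, b, 2, 1) * dy)
    for (i in sample(length(x), 5)) {
      expect_equal(g$dx[i], num_grad(function(a) loss(a, w, b), x, i),
                   tolerance = 1e-5)
    }
    for (i in sample(length(w), 5)) {
      expect_equal(g$dW[i], num_grad(function(a) loss(x, a, b), w, i),
                   tolerance = 1e-5)
    }
    expect_equal(g$db[2], num_grad(function(a) loss(x, w, a), b, 2),
                 tolerance = 1e-5)
  })
})

test_that("transposed convolution doubles the grid and back-propagates exactly", {
  withr::with_seed(43, {
    x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
    w <- array(rnorm(4 * 4 * 2 * 3, 0, 0.3), c(4, 4, 2, 3))
    b <- rnorm(2)
    y <- tieqpi:::nn_convT_fwd(x, w, b, 2, 1, 10, 10)
    expect_equal(dim(y), c(10, 10, 2, 2))
    dy <- array(rnorm(length(y)), dim(y))
    g <- tieqpi:::nn_convT_bwd(x, w, dy, 2, 1)
    loss <- function(x, w, b) {
      sum(tieqpi:::nn_convT_fwd(x, w, b, 2, 1, 10, 10) * dy)
    }
    for (i in sample(length(x), 4)) {
      expect_equal(g$dx[i], num_grad(function(a) loss(a, w, b), x, i),
                   tolerance = 1e-5)
    }
    for (i in sample(length(w), 4)) {
      expect_equal(g$dW[i], num_grad(function(a) loss(x, a, b), w, i),
                   tolerance = 1e-5)
    }
  })
})

test_that("batch normalization gradients match finite differences", {
  withr::with_seed(44, {
    C <- 3
    x <- array(rnorm(5 * 5 * C * 4), c(5, 5, C, 4))
    p <- list(gamma = runif(C, 0.5, 1.5), beta = rnorm(C),
              rmean = numeric(C), rvar = rep(1, C))
    r <- tieqpi:::nn_bn_fwd(x, p, training = TRUE)
    dy <- array(rnorm(length(r$y)), dim(r$y))
    g <- tieqpi:::nn_bn_bwd(dy, r$cache)
    loss <- function(x, gamma) {
      p2 <- p; p2$gamma <- gamma
      sum(tieqpi:::nn_bn_fwd(x, p2, training = TRUE)$y * dy)
    }
    for (i in sample(length(x), 5)) {
      expect_equal(g$dx[i], num_grad(function(a) loss(a, p$gamma), x, i),
                   tolerance = 1e-4)
    }
    expect_equal(g$dgamma[1],
                 num_grad(function(a) loss(x, a), p$gamma, 1),
                 tolerance = 1e-5)
  })
})

test_that("generator halves the grid per encoder stage and maps tiles to tiles", {
  arch <- build_generator(gan_config(tile = 256, base_channels = 4))
  expect_equal(arch$spatial, c(128, 64, 32, 16, 8, 4, 2, 1))
  expect_equal(arch$depth, 8)
  G <- quiet_gan(build_generator(gan_config(tile = 64, base_channels = 8,
                                            seed = 5)))
  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  y1 <- tieqpi:::generator_forward(G, x, training = FALSE)$y
  expect_equal(dim(y1), c(64, 64, 1, 1))
  expect_true(all(abs(y1) <= 1))
  # inference is deterministic (dropout disabled)
  y2 <- tieqpi:::generator_forward(G, x, training = FALSE)$y
  expect_identical(y1, y2)
  # same config seed, same weights
  G2 <- quiet_gan(build_generator(gan_config(tile = 64, base_channels = 8,
                                             seed = 5)))
  expect_identical(G$par, G2$par)
})

test_that("discriminator follows the declared patch plan and score codomain", {
  D256 <- build_discriminator(gan_config(tile = 256))
  # strides 2,2,2,1,1 on 256: 128, 64, 32, 31, 30
  expect_equal(D256$patch, 30)
  expect_equal(D256$strides, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(D256$ch, c(64L, 128L, 256L, 512L, 1L))
  cfg <- gan_config(tile = 64, base_channels = 8, seed = 6)
  D <- build_discriminator(cfg)
  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  y <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  out <- tieqpi:::discriminator_forward(D, x, y, training = FALSE)
  scores <- tieqpi:::sigmoid(out$logits)
  expect_true(all(scores > 0 & scores < 1))
  bad <- array(0, c(32, 32, 1, 1))
  expect_error(tieqpi:::discriminator_forward(D, x, bad, training = FALSE),
               "matching")
})

test_that("the adversarial generator loss is -log D on a frozen uninformative critic", {
  cfg <- gan_config(tile = 32, base_channels = 4, seed = 7, l1_weight = 0,
                    learning_rate = 1e-9, dropout_rate = 0)
  G <- quiet_gan(build_generator(cfg))
  D <- build_discriminator(cfg)
  # zero the final discriminator stage: logits identically 0, D = 0.5
  last <- paste0("d", D$n)
  D$par[[paste0(last, "_W")]][] <- 0
  D$par[[paste0(last, "_b")]][] <- 0
  withr::with_seed(1, {
    batch <- list(x = array(rnorm(32 * 32 * 2), c(32, 32, 1, 2)),
                  y = array(tanh(rnorm(32 * 32 * 2)), c(32, 32, 1, 2)))
  })
  st <- cgan_step(G, D, batch, cfg)
  expect_equal(st$losses$g_adv, -log(0.5), tolerance = 1e-6)
  # l1_weight = 0 reduces the generator objective to the adversarial term
  expect_equal(st$losses$g_loss, st$losses$g_adv)
  expect_true(all(is.finite(unlist(st$losses))))
})

test_that("one adversarial step moves both networks' parameters", {
  cfg <- gan_config(tile = 32, base_channels = 4, seed = 8)
  G <- quiet_gan(build_generator(cfg))
  D <- build_discriminator(cfg)
  withr::with_seed(2, {
    batch <- list(x = array(rnorm(32 * 32 * 2), c(32, 32, 1, 2)),
                  y = array(tanh(rnorm(32 * 32 * 2)), c(32, 32, 1, 2)))
  })
  st <- cgan_step(G, D, batch, cfg)
  expect_false(identical(st$generator$par$enc1_W, G$par$enc1_W))
  expect_false(identical(st$discriminator$par$d1_W, D$par$d1_W))
})

test_that("training with zero epochs returns an initialized model and empty history", {
  toy <- make_toy_stacks(3, n_z = 3, tile = 32, seed = 9)
  pairs <- build_pairs(toy$stacks, toy$phases)
  model <- quiet_gan(gan_train(pairs, gan_config(tile = 32,
                                                 base_channels = 4,
                                                 epochs = 0, seed = 10)))
  expect_s3_class(model, "tie_gan")
  expect_equal(nrow(model$history), 0)
  pred <- gan_infer(model, toy$stacks[[1]]$frames[[1]])
  expect_s3_class(pred, "phase_map")
  expect_true(all(is.finite(pred$phase_rad)))
})

test_that("training is reproducible and serializes bit-identically", {
  toy <- make_toy_stacks(4, n_z = 3, tile = 32, seed = 11)
  pairs <- build_pairs(toy$stacks, toy$phases,
                       split_sizes = c(6, 3, 3), seed = 12)
  cfg <- gan_config(tile = 32, base_channels = 4, epochs = 2, batch_size = 3,
                    seed = 13)
  m1 <- quiet_gan(gan_train(pairs, cfg))
  m2 <- quiet_gan(gan_train(pairs, cfg))
  expect_equal(m1$history, m2$history)
  expect_identical(m1$best$val_ssim, m2$best$val_ssim)
  path <- file.path(tempdir(), "model.rds")
  save_gan(m1, path)
  m3 <- load_gan(path)
  frame <- toy$stacks[[1]]$frames[[2]]
  expect_identical(gan_infer(m1, frame)$phase_rad,
                   gan_infer(m3, frame)$phase_rad)
})

test_that("inference handles constant frames, crops large ones, rejects small ones", {
  toy <- make_toy_stacks(3, n_z = 3, tile = 32, seed = 14)
  pairs <- build_pairs(toy$stacks, toy$phases)
  model <- quiet_gan(gan_train(pairs, gan_config(tile = 32,
                                                 base_channels = 4,
                                                 epochs = 0, seed = 15)))
  flat <- gan_infer(model, matrix(1, 32, 32))
  expect_true(all(is.finite(flat$phase_rad)))
  big <- gan_infer(model, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(big$phase_rad), c(32, 32))
  expect_error(gan_infer(model, matrix(0, 16, 16)), "smaller")
})
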