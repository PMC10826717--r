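#' Conditional GAN configuration
#'
#' Architecture and optimization settings of the intensity-to-phase
#' translation network.  The defaults follow the conventional paired
#' image-to-image translation recipe: a 256 tile fully reduced by an
#' 8-stage encoder, 64 base channels doubling to a 512 cap, a 5-conv
#' PatchGAN discriminator, Adam at learning rate 1e-4 with batch size 4,
#' and an L1 reconstruction term weighted 100 alongside the adversarial
#' objective (set `l1_weight = 0` for the bare adversarial objective).
#'
#' @param tile Square tile side in pixels.
#' @param base_channels First-stage channel count (doubles per stage,
#'   capped at 512).
#' @param encoder_depth Number of stride-2 encoder stages requested;
#'   effectively limited to `log2(tile)`.
#' @param discriminator_convs Number of discriminator convolution stages
#'   (three stride-2 stages, then stride-1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Training batch size.
#' @param epochs Training epochs.
#' @param l1_weight Weight of the mean-absolute-error reconstruction
#'   term added to the generator objective.
#' @param dropout_rate Dropout rate in the first three decoder stages
#'   (the stochastic input of the conditional objective is realized as
#'   decoder dropout).
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @param beta1,beta2 Adam moment decay rates.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(tile = 256, base_channels = 64, encoder_depth = 8,
                       discriminator_convs = 5, learning_rate = 1e-4,
                       batch_size = 4, epochs = 200, l1_weight = 100,
                       dropout_rate = 0.5, seed = 1L,
                       beta1 = 0.5, beta2 = 0.999) {
  stopifnot(tile >= 8, learning_rate > 0, batch_size >= 1, epochs >= 0,
            l1_weight >= 0, dropout_rate >= 0, dropout_rate < 1,
            discriminator_convs >= 2)
  if (2^round(log2(tile)) != tile) {
    stop("tile must be a power of two", call. = FALSE)
  }
  structure(list(tile = as.integer(tile),
                 base_channels = as.integer(base_channels),
                 encoder_depth = as.integer(encoder_depth),
                 discriminator_convs = as.integer(discriminator_convs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 l1_weight = l1_weight,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2),
            class = "gan_config")
}

#' Build the U-Net generator
#'
#' An encoder of stride-2 4x4 convolutions (Leaky ReLU, batch norm on all
#' but the first and the 1x1 innermost stage) halves the tile down to
#' 1x1; a mirrored decoder of stride-2 transposed convolutions (ReLU,
#' batch norm, dropout in the first three stages) doubles it back, with
#' skip concatenation of each encoder feature into the matching decoder
#' stage.  The final stage maps to one channel through tanh, so outputs
#' live in \[-1, 1\].  If the tile is smaller than `2^encoder_depth` the
#' effective depth is reduced (with a warning).
#'
#' @param config A [gan_config()].
#' @return An object of class `tie_generator` (architecture plan,
#'   parameters, batch-norm statistics).
#' @export
build_generator <- function(config = gan_config()) {
  tile <- config$tile
  max_depth <- as.integer(log2(tile))
  d <- min(config$encoder_depth, max_depth)
  if (d < config$encoder_depth) {
    warning(sprintf(
      "tile %d supports only %d encoder stages (requested %d)",
      tile, d, config$encoder_depth))
  }
  base <- config$base_channels
  enc_out <- pmin(base * 2^(seq_len(d) - 1), 512L)
  enc_in <- c(1L, enc_out[-d])
  spatial <- tile / 2^seq_len(d)
  bn_enc <- seq_len(d) > 1 & spatial > 1
  dec_in <- integer(d); dec_out <- integer(d)
  for (j in seq_len(d)) {
    dec_in[j] <- if (j == 1) enc_out[d] else dec_out[j - 1] + enc_out[d - j + 1]
    dec_out[j] <- if (j < d) enc_out[d - j] else 1L
  }
  bn_dec <- seq_len(d) < d
  drop_dec <- seq_len(d) <= 3 & seq_len(d) < d

  par <- list()
  with_seed(config$seed, {
    for (i in seq_len(d)) {
      cv <- nn_conv_init(4, enc_in[i], enc_out[i])
      par[[paste0("enc", i, "_W")]] <- cv$W
      par[[paste0("enc", i, "_b")]] <- cv$b
      if (bn_enc[i]) {
        par[[paste0("enc", i, "_g")]] <- rep(1, enc_out[i])
        par[[paste0("enc", i, "_be")]] <- numeric(enc_out[i])
      }
    }
    for (j in seq_len(d)) {
      cv <- nn_conv_init(4, dec_out[j], dec_in[j])  # convT convention
      par[[paste0("dec", j, "_W")]] <- cv$W
      par[[paste0("dec", j, "_b")]] <- numeric(dec_out[j])
      if (bn_dec[j]) {
        par[[paste0("dec", j, "_g")]] <- rep(1, dec_out[j])
        par[[paste0("dec", j, "_be")]] <- numeric(dec_out[j])
      }
    }
  })
  stats <- list()
  for (i in seq_len(d)) if (bn_enc[i]) {
    stats[[paste0("enc", i)]] <- list(rmean = numeric(enc_out[i]),
                                      rvar = rep(1, enc_out[i]))
  }
  for (j in seq_len(d)) if (bn_dec[j]) {
    stats[[paste0("dec", j)]] <- list(rmean = numeric(dec_out[j]),
                                      rvar = rep(1, dec_out[j]))
  }
  structure(
    list(depth = d, tile = tile,
         enc_in = enc_in, enc_out = enc_out, spatial = spatial,
         dec_in = dec_in, dec_out = dec_out,
         bn_enc = bn_enc, bn_dec = bn_dec, drop_dec = drop_dec,
         dropout_rate = config$dropout_rate,
         par = par, stats = stats),
    class = "tie_generator")
}

#' @export
print.tie_generator <- function(x, ...) {
  cat(sprintf("<tie_generator> U-Net, depth %d, tile %d\n", x$depth, x$tile))
  cat("  encoder:", paste(sprintf("%dx%d/%dch", x$spatial, x$spatial,
                                  x$enc_out), collapse = " "), "\n")
  cat(sprintf("  decoder mirrors with skip connections; dropout %g in %d stages\n",
              x$dropout_rate, sum(x$drop_dec)))
  invisible(x)
}

bn_pack <- function(par, stats, key) {
  list(gamma = par[[paste0(key, "_g")]], beta = par[[paste0(key, "_be")]],
       rmean = stats$rmean, rvar = stats$rvar)
}

generator_forward <- function(G, x, training = FALSE) {
  d <- G$depth
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  enc_act <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    key <- paste0("enc", i)
    z <- nn_conv_fwd(h, G$par[[paste0(key, "_W")]],
                     G$par[[paste0(key, "_b")]], 2, 1)
    bn_cache <- NULL
    if (G$bn_enc[i]) {
      r <- nn_bn_fwd(z, bn_pack(G$par, G$stats[[key]], key), training)
      z <- r$y
      bn_cache <- r$cache
      if (training) G$stats[[key]] <- r$p[c("rmean", "rvar")]
    }
    a <- nn_lrelu(z)
    caches$enc[[i]] <- list(x_in = h, bn = bn_cache, a = a)
    enc_act[[i]] <- a
    h <- a
  }
  for (j in seq_len(d)) {
    key <- paste0("dec", j)
    inp <- if (j == 1) h else concat_channels(h, enc_act[[d - j + 1]])
    sz <- dim(inp)[1] * 2
    z <- nn_convT_fwd(inp, G$par[[paste0(key, "_W")]],
                      G$par[[paste0(key, "_b")]], 2, 1, sz, sz)
    bn_cache <- NULL
    if (G$bn_dec[j]) {
      r <- nn_bn_fwd(z, bn_pack(G$par, G$stats[[key]], key), training)
      z <- r$y
      bn_cache <- r$cache
      if (training) G$stats[[key]] <- r$p[c("rmean", "rvar")]
    }
    mask <- NULL
    if (G$drop_dec[j] && training && G$dropout_rate > 0) {
      mask <- array(nn_dropout_mask(length(z), G$dropout_rate), dim(z))
      z <- z * mask
    }
    a <- if (j < d) pmax(z, 0) else tanh(z)
    caches$dec[[j]] <- list(inp = inp, bn = bn_cache, mask = mask, a = a)
    h <- a
  }
  list(y = h, caches = caches, G = G)
}

generator_backward <- function(G, caches, dy) {
  d <- G$depth
  grads <- list()
  enc_extra <- vector("list", d)  # skip-connection gradients
  dh <- dy
  for (j in rev(seq_len(d))) {
    key <- paste0("dec", j)
    cc <- caches$dec[[j]]
    dz <- if (j < d) nn_relu_bwd(dh, cc$a) else nn_tanh_bwd(dh, cc$a)
    if (!is.null(cc$mask)) dz <- dz * cc$mask
    if (!is.null(cc$bn)) {
      r <- nn_bn_bwd(dz, cc$bn)
      dz <- r$dx
      grads[[paste0(key, "_g")]] <- r$dgamma
      grads[[paste0(key, "_be")]] <- r$dbeta
    }
    r <- nn_convT_bwd(cc$inp, G$par[[paste0(key, "_W")]], dz, 2, 1)
    grads[[paste0(key, "_W")]] <- r$dW
    grads[[paste0(key, "_b")]] <- r$db
    if (j == 1) {
      dh <- r$dx
    } else {
      sp <- split_channels(r$dx, dim(cc$inp)[3] - dim(caches$enc[[d - j + 1]]$a)[3])
      dh <- sp$a
      enc_extra[[d - j + 1]] <- sp$b
    }
  }
  for (i in rev(seq_len(d))) {
    key <- paste0("enc", i)
    cc <- caches$enc[[i]]
    if (!is.null(enc_extra[[i]])) dh <- dh + enc_extra[[i]]
    dz <- nn_lrelu_bwd(dh, cc$a)
    if (!is.null(cc$bn)) {
      r <- nn_bn_bwd(dz, cc$bn)
      dz <- r$dx
      grads[[paste0(key, "_g")]] <- r$dgamma
      grads[[paste0(key, "_be")]] <- r$dbeta
    }
    r <- nn_conv_bwd(cc$x_in, G$par[[paste0(key, "_W")]], dz, 2, 1)
    grads[[paste0(key, "_W")]] <- r$dW
    grads[[paste0(key, "_b")]] <- r$db
    dh <- r$dx
  }
  list(grads = grads, dx = dh)
}

#' Build the PatchGAN discriminator
#'
#' Five 4x4 convolution stages over the concatenated
#' (intensity, candidate phase) pair: three stride-2 stages (64, 128, 256
#' channels), a stride-1 512-channel stage, then a stride-1 map to one
#' channel.  Leaky ReLU and batch norm (except first and last stage)
#' throughout; the sigmoid of the final map gives a grid of per-patch
#' realness scores in (0, 1).
#'
#' @param config A [gan_config()].
#' @return An object of class `tie_discriminator`.
#' @export
build_discriminator <- function(config = gan_config()) {
  ncv <- config$discriminator_convs
  base <- config$base_channels
  ch <- c(pmin(base * 2^(seq_len(ncv - 1) - 1), 512L), 1L)
  strides <- c(rep(2L, min(3, ncv - 1)),
               rep(1L, ncv - min(3, ncv - 1)))
  bn <- c(FALSE, rep(TRUE, ncv - 2), FALSE)
  cin <- c(2L, ch[-ncv])
  patch <- config$tile
  for (i in seq_len(ncv)) {
    patch <- (patch + 2 - 4) %/% strides[i] + 1
    if (patch < 1) {
      stop(sprintf("tile %d is too small for %d discriminator stages",
                   config$tile, ncv), call. = FALSE)
    }
  }
  par <- list()
  with_seed(config$seed + 1L, {
    for (i in seq_len(ncv)) {
      cv <- nn_conv_init(4, cin[i], ch[i])
      par[[paste0("d", i, "_W")]] <- cv$W
      par[[paste0("d", i, "_b")]] <- cv$b
      if (bn[i]) {
        par[[paste0("d", i, "_g")]] <- rep(1, ch[i])
        par[[paste0("d", i, "_be")]] <- numeric(ch[i])
      }
    }
  })
  stats <- list()
  for (i in seq_len(ncv)) if (bn[i]) {
    stats[[paste0("d", i)]] <- list(rmean = numeric(ch[i]),
                                    rvar = rep(1, ch[i]))
  }
  structure(list(n = ncv, ch = ch, cin = cin, strides = strides, bn = bn,
                 patch = patch, par = par, stats = stats),
            class = "tie_discriminator")
}

#' @export
print.tie_discriminator <- function(x, ...) {
  cat(sprintf("<tie_discriminator> PatchGAN, %d convs, channels %s, strides %s\n",
              x$n, paste(x$ch, collapse = "/"),
              paste(x$strides, collapse = "/")))
  invisible(x)
}

# Returns patch logits; apply sigmoid() for scores.
discriminator_forward <- function(D, x, y, training = FALSE) {
  if (!all(dim(x) == dim(y))) {
    stop("intensity and phase tiles must have matching shapes",
         call. = FALSE)
  }
  h <- concat_channels(x, y)
  caches <- vector("list", D$n)
  for (i in seq_len(D$n)) {
    key <- paste0("d", i)
    x_in <- h
    z <- nn_conv_fwd(h, D$par[[paste0(key, "_W")]],
                     D$par[[paste0(key, "_b")]], D$strides[i], 1)
    bn_cache <- NULL
    if (D$bn[i]) {
      r <- nn_bn_fwd(z, bn_pack(D$par, D$stats[[key]], key), training)
      z <- r$y
      bn_cache <- r$cache
      if (training) D$stats[[key]] <- r$p[c("rmean", "rvar")]
    }
    a <- if (i < D$n) nn_lrelu(z) else z
    caches[[i]] <- list(x_in = x_in, bn = bn_cache, a = a)
    h <- a
  }
  list(logits = h, caches = caches, D = D)
}

discriminator_backward <- function(D, caches, dlogits) {
  grads <- list()
  dh <- dlogits
  for (i in rev(seq_len(D$n))) {
    key <- paste0("d", i)
    cc <- caches[[i]]
    dz <- if (i < D$n) nn_lrelu_bwd(dh, cc$a) else dh
    if (!is.null(cc$bn)) {
      r <- nn_bn_bwd(dz, cc$bn)
      dz <- r$dx
      grads[[paste0(key, "_g")]] <- r$dgamma
      grads[[paste0(key, "_be")]] <- r$dbeta
    }
    r <- nn_conv_bwd(cc$x_in, D$par[[paste0(key, "_W")]], dz, D$strides[i], 1)
    grads[[paste0(key, "_W")]] <- r$dW
    grads[[paste0(key, "_b")]] <- r$db
    dh <- r$dx
  }
  list(grads = grads, dx = dh)
}

#' One adversarial training step
#'
#' Performs one discriminator update (ascending the conditional
#' adversarial objective
#' `E[log D(x, y)] + E[log(1 - D(x, G(x)))]`, implemented as binary
#' cross-entropy on the patch logits) and one generator update
#' (descending the non-saturating adversarial loss `-log D(x, G(x))`
#' plus `l1_weight * mean(|G(x) - y|)`).
#'
#' @param generator A [build_generator()] network.
#' @param discriminator A [build_discriminator()] network.
#' @param batch List with arrays `x` and `y` of shape
#'   `(tile, tile, 1, n)` in \[-1, 1\].
#' @param config A [gan_config()].
#' @param opt Optimizer state from a previous step (or `NULL` to start).
#' @return List with updated `generator`, `discriminator`, `opt`, and a
#'   one-row `losses` tibble (`d_loss`, `g_adv`, `g_l1`, `g_loss`).
#' @export
cgan_step <- function(generator, discriminator, batch,
                      config = gan_config(), opt = NULL) {
  if (is.null(opt)) {
    opt <- list(g = adam_init(generator$par),
                d = adam_init(discriminator$par))
  }
  x <- batch$x; y <- batch$y
  lr <- config$learning_rate

  gf <- generator_forward(generator, x, training = TRUE)
  generator <- gf$G
  fake <- gf$y

  # --- discriminator update ---
  dr <- discriminator_forward(discriminator, x, y, training = TRUE)
  discriminator <- dr$D
  df <- discriminator_forward(discriminator, x, fake, training = TRUE)
  discriminator <- df$D
  n_el <- length(dr$logits)
  d_loss <- mean(softplus(-dr$logits)) + mean(softplus(df$logits))
  gb_real <- discriminator_backward(discriminator, dr$caches,
                                    (sigmoid(dr$logits) - 1) / n_el)
  gb_fake <- discriminator_backward(discriminator, df$caches,
                                    sigmoid(df$logits) / n_el)
  dgrads <- gb_real$grads
  for (nm in names(gb_fake$grads)) {
    dgrads[[nm]] <- dgrads[[nm]] + gb_fake$grads[[nm]]
  }
  up <- adam_update(discriminator$par, dgrads, opt$d, lr,
                    config$beta1, config$beta2)
  discriminator$par <- up$par
  opt$d <- up$st

  # --- generator update (through the updated discriminator) ---
  dg <- discriminator_forward(discriminator, x, fake, training = TRUE)
  discriminator <- dg$D
  g_adv <- mean(softplus(-dg$logits))
  db <- discriminator_backward(discriminator, dg$caches,
                               (sigmoid(dg$logits) - 1) / length(dg$logits))
  dfake <- split_channels(db$dx, 1)$b  # gradient w.r.t. the phase channel
  g_l1 <- mean(abs(fake - y))
  if (config$l1_weight > 0) {
    dfake <- dfake + config$l1_weight * sign(fake - y) / length(fake)
  }
  gb <- generator_backward(generator, gf$caches, dfake)
  up <- adam_update(generator$par, gb$grads, opt$g, lr,
                    config$beta1, config$beta2)
  generator$par <- up$par
  opt$g <- up$st

  g_loss <- g_adv + config$l1_weight * g_l1
  if (!all(is.finite(c(d_loss, g_adv, g_l1)))) {
    stop("non-finite loss encountered", call. = FALSE)
  }
  list(generator = generator, discriminator = discriminator, opt = opt,
       losses = tibble::tibble(d_loss = d_loss, g_adv = g_adv,
                               g_l1 = g_l1, g_loss = g_loss))
}

pairs_to_batch <- function(pairs, idx) {
  tile <- nrow(pairs$intensity[[1]])
  n <- length(idx)
  x <- array(0, c(tile, tile, 1, n))
  y <- array(0, c(tile, tile, 1, n))
  for (k in seq_along(idx)) {
    x[, , 1, k] <- pairs$intensity[[idx[k]]]
    y[, , 1, k] <- pairs$phase[[idx[k]]]
  }
  list(x = x, y = y)
}

#' Train the conditional GAN on paired tiles
#'
#' Runs the adversarial training loop over the `train` split of a
#' [build_pairs()] dataset, recording per-epoch generator/discriminator
#' losses and validation SSIM, and keeping a snapshot of the generator at
#' the best validation SSIM.  Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param pairs A `qpi_pairs` tibble from [build_pairs()].
#' @param config A [gan_config()].
#' @param pitch_um Object-plane pitch recorded on inferred phase maps.
#' @param verbose Print one line per epoch.
#' @return An object of class `tie_gan`: generator, discriminator,
#'   config, training `history` tibble, the best-epoch generator
#'   snapshot, and the pooled phase normalization range used to convert
#'   inferred tiles back to radians.
#' @export
gan_train <- function(pairs, config = gan_config(), pitch_um = 1,
                      verbose = FALSE) {
  train <- pairs[pairs$split == "train", ]
  val <- pairs[pairs$split == "validation", ]
  if (nrow(train) == 0) stop("no training pairs", call. = FALSE)
  tile <- nrow(train$intensity[[1]])
  if (tile != config$tile) {
    config$tile <- as.integer(tile)
  }
  p_norms <- do.call(rbind, train$p_norm)
  phase_range <- c(min(p_norms[, 1]), max(p_norms[, 2]))

  model <- with_seed(config$seed, {
    G <- build_generator(config)
    D <- build_discriminator(config)
    opt <- NULL
    history <- tibble::tibble(epoch = integer(), d_loss = numeric(),
                              g_adv = numeric(), g_l1 = numeric(),
                              g_loss = numeric(), val_ssim = numeric())
    best <- list(par = G$par, stats = G$stats, val_ssim = -Inf, epoch = 0L)
    n <- nrow(train)
    for (ep in seq_len(config$epochs)) {
      idx <- sample(n)
      ep_losses <- NULL
      for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
        batch <- pairs_to_batch(train, b)
        st <- cgan_step(G, D, batch, config, opt)
        G <- st$generator; D <- st$discriminator; opt <- st$opt
        if (!all(is.finite(unlist(st$losses)))) {
          stop(sprintf("training aborted: non-finite loss in epoch %d", ep),
               call. = FALSE)
        }
        ep_losses <- dplyr::bind_rows(ep_losses, st$losses)
      }
      mean_losses <- dplyr::summarize(ep_losses,
                                      dplyr::across(dplyr::everything(),
                                                    mean))
      val_ssim <- validation_ssim(G, val)
      if (is.nan(val_ssim)) {
        stop(sprintf("validation SSIM is NaN at epoch %d", ep),
             call. = FALSE)
      }
      history <- dplyr::bind_rows(history,
                                  dplyr::bind_cols(
                                    tibble::tibble(epoch = ep), mean_losses,
                                    tibble::tibble(val_ssim = val_ssim)))
      if (is.na(best$val_ssim) || !is.finite(best$val_ssim) ||
          (!is.na(val_ssim) && val_ssim >= best$val_ssim)) {
        best <- list(par = G$par, stats = G$stats,
                     val_ssim = val_ssim, epoch = ep)
      }
      if (verbose) {
        message(sprintf(
          "epoch %3d  d %.4f  g_adv %.4f  g_l1 %.4f  val_ssim %s",
          ep, mean_losses$d_loss, mean_losses$g_adv, mean_losses$g_l1,
          ifelse(is.na(val_ssim), "NA", sprintf("%.4f", val_ssim))))
      }
    }
    list(G = G, D = D, history = history, best = best)
  })
  structure(
    list(generator = model$G, discriminator = model$D, config = config,
         history = model$history, best = model$best,
         phase_range = phase_range, pitch_um = pitch_um),
    class = "tie_gan")
}

validation_ssim <- function(G, val) {
  if (nrow(val) == 0) return(NA_real_)
  scores <- vapply(seq_len(nrow(val)), function(i) {
    b <- pairs_to_batch(val, i)
    pred <- generator_forward(G, b$x, training = FALSE)$y[, , 1, 1]
    ssim(to_uint8_scale(pred), to_uint8_scale(b$y[, , 1, 1]))
  }, numeric(1))
  mean(scores)
}

#' @export
print.tie_gan <- function(x, ...) {
  cat(sprintf("<tie_gan> trained %d epochs; best val SSIM %.4f (epoch %d)\n",
              nrow(x$history),
              ifelse(is.finite(x$best$val_ssim), x$best$val_ssim, NA),
              x$best$epoch))
  invisible(x)
}

#' Single-shot phase inference
#'
#' Runs one forward pass of the (best-epoch) generator on a single
#' defocused intensity frame - no focus search, no propagation - and
#' converts the \[-1, 1\] output back to radians through a normalization
#' record.  The frame is min-max normalized exactly as training tiles
#' were; frames larger than the tile are centre-cropped, smaller frames
#' are rejected.
#'
#' @param model A [gan_train()] model.
#' @param frame Numeric intensity matrix (any defocus within the trained
#'   range).
#' @param normalization `c(min_rad, max_rad)` used to denormalize the
#'   output; defaults to the pooled training phase range stored in the
#'   model.
#' @param use_best Use the best-validation snapshot (default) rather
#'   than the final epoch.
#' @return A [phase_map()].
#' @export
gan_infer <- function(model, frame, normalization = NULL, use_best = TRUE) {
  stopifnot(inherits(model, "tie_gan"), is.matrix(frame))
  tile <- model$generator$tile
  if (nrow(frame) < tile || ncol(frame) < tile) {
    stop(sprintf("frame (%d x %d) is smaller than the model tile (%d)",
                 nrow(frame), ncol(frame), tile), call. = FALSE)
  }
  if (nrow(frame) > tile || ncol(frame) > tile) {
    r0 <- (nrow(frame) - tile) %/% 2
    c0 <- (ncol(frame) - tile) %/% 2
    frame <- frame[r0 + seq_len(tile), c0 + seq_len(tile)]
  }
  G <- model$generator
  if (use_best && is.finite(model$best$val_ssim)) {
    G$par <- model$best$par
    G$stats <- model$best$stats
  }
  xn <- normalize_tile(frame)$tile
  x <- array(xn, c(tile, tile, 1, 1))
  out <- generator_forward(G, x, training = FALSE)$y[, , 1, 1]
  norm <- if (is.null(normalization)) model$phase_range else normalization
  phase_map(denormalize_tile(out, norm), model$pitch_um,
            normalization = norm)
}

#' Save / load a trained model
#'
#' The checkpoint is a single file holding parameters, batch-norm
#' statistics, configuration, normalization policy and training history;
#' reloading reproduces inference bit-identically.
#'
#' @param model A `tie_gan` model.
#' @param path Checkpoint path.
#' @return `save_gan()`: `path` invisibly; `load_gan()`: the model.
#' @export
save_gan <- function(model, path) {
  stopifnot(inherits(model, "tie_gan"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "tie_gan"))
  model
}
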