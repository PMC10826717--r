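# Internal minimal neural-network toolkit backing the cGAN: batched 2-D
# conv / transposed-conv (C++ im2col kernels), batch norm, dropout,
# activations and Adam, all with hand-written backward passes.  Feature
# maps are arrays (H, W, C, N); weights are (k, k, Cin, Cout).

nn_conv_init <- function(k, cin, cout, sd = 0.02) {
  list(W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

nn_bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C))
}

# (H, W, C, N) array  ->  (H*W*N, C) matrix with channels as columns
to_chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

from_chan_mat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

add_channel_bias <- function(x, b) {
  d <- dim(x)
  x + rep(rep(b, each = d[1] * d[2]), times = d[4])
}

channel_sums <- function(x) colSums(to_chan_mat(x))

nn_bn_fwd <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- to_chan_mat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = from_chan_mat(y, d), p = p,
       cache = list(xhat = xhat, invstd = invstd, gamma = p$gamma, d = d,
                    training = training))
}

nn_bn_bwd <- function(dy, cache) {
  dym <- to_chan_mat(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, `*`)
  if (cache$training) {
    M <- nrow(dym)
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * xhat)
    dxm <- sweep(dxhat, 2, mean_dxhat) -
      sweep(xhat, 2, mean_dxhat_xhat, `*`)
    dxm <- sweep(dxm, 2, cache$invstd, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cache$invstd, `*`)
  }
  list(dx = from_chan_mat(dxm, cache$d), dgamma = dgamma, dbeta = dbeta)
}

nn_lrelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
nn_lrelu_bwd <- function(dy, a, slope = 0.2) dy * ifelse(a > 0, 1, slope)
nn_relu_bwd <- function(dy, a) dy * (a > 0)
nn_tanh_bwd <- function(dy, a) dy * (1 - a^2)
sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

nn_dropout_mask <- function(n, rate) {
  (runif(n) >= rate) / (1 - rate)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_update <- function(par, grad, st, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grad)) {
    g <- grad[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, st = st)
}

# ---- layer wrappers over the C++ kernels ---------------------------------

nn_conv_fwd <- function(x, W, b, stride, pad) {
  conv_fwd_cpp(x, W, b, as.integer(stride), as.integer(pad))
}

nn_conv_bwd <- function(x, W, dy, stride, pad) {
  d <- dim(x)
  g <- conv_bwd_w_cpp(x, dy, dim(W)[1], as.integer(stride), as.integer(pad))
  dx <- conv_bwd_x_cpp(dy, W, as.integer(stride), as.integer(pad),
                       d[1], d[2])
  list(dx = dx, dW = g$dw, db = g$db)
}

# Transposed conv: weights stored in the down-conv convention
# (k, k, C_out_up, C_in_up); forward is the conv input-gradient.
nn_convT_fwd <- function(x, W, b, stride, pad, H_out, W_out) {
  y <- conv_bwd_x_cpp(x, W, as.integer(stride), as.integer(pad),
                      as.integer(H_out), as.integer(W_out))
  add_channel_bias(y, b)
}

nn_convT_bwd <- function(x, W, dy, stride, pad) {
  dx <- conv_fwd_cpp(dy, W, numeric(dim(W)[4]), as.integer(stride),
                     as.integer(pad))
  g <- conv_bwd_w_cpp(dy, x, dim(W)[1], as.integer(stride), as.integer(pad))
  list(dx = dx, dW = g$dw, db = channel_sums(dy))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , c1 + seq_len(d[3] - c1), , drop = FALSE])
}
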