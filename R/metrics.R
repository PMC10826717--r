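#' Image quality metric configuration
#'
#' @param dynamic_range_L Dynamic range L of the images (255 for 8-bit
#'   renderings).
#' @param K1,K2 SSIM stabilization factors; the constants are
#'   `C1 = (K1*L)^2`, `C2 = (K2*L)^2`.
#' @param ssim_window Side of the square window used for the windowed
#'   (sliding mean) SSIM/UIQI.
#' @param method `"window"` (mean over all sliding windows, the
#'   conventional choice and the default) or `"global"` (one whole-image
#'   evaluation of the formula).
#' @param population_variance Use the population (divide by N) variance
#'   estimator (default) rather than the sample one.
#' @return An object of class `metrics_config`.
#' @export
metrics_config <- function(dynamic_range_L = 255, K1 = 0.01, K2 = 0.03,
                           ssim_window = 8,
                           method = c("window", "global"),
                           population_variance = TRUE) {
  method <- match.arg(method)
  stopifnot(dynamic_range_L > 0, K1 > 0, K1 < 1, K2 > 0, K2 < 1,
            ssim_window >= 2)
  structure(list(dynamic_range_L = dynamic_range_L, K1 = K1, K2 = K2,
                 ssim_window = as.integer(ssim_window), method = method,
                 population_variance = population_variance),
            class = "metrics_config")
}

check_same_shape <- function(x, y) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(y)))) {
    stop("images must have the same shape", call. = FALSE)
  }
}

#' Mean squared error between two images
#'
#' `MSE(x, y) = mean((x - y)^2)` over all pixels.
#'
#' @param x,y Numeric matrices of the same shape.
#' @return Non-negative scalar; zero iff the images are identical.
#' @export
mse <- function(x, y) {
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(L^2 / MSE)` in decibels, where L is the dynamic
#' range of the images.  Identical images are reported as `Inf`.
#'
#' @param x,y Numeric matrices of the same shape.
#' @param config A [metrics_config()]; supplies L.
#' @return Scalar in dB (possibly `Inf`).
#' @examples
#' psnr(matrix(0, 2, 2), matrix(10, 2, 2))  # 10*log10(255^2/100) = 28.13
#' @export
psnr <- function(x, y, config = metrics_config()) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(config$dynamic_range_L^2 / m)
}

# Sliding-window sums of every w x w window via a 2-D prefix table.
box_sums <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1, W + 1)
  P[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  P[i + w, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
    P[i + w, j, drop = FALSE] + P[i, j, drop = FALSE]
}

# Shared SSIM/UIQI machinery.  Returns per-window (or global) values of
# (2*mx*my + C1)(2*sxy + C2) / ((mx^2 + my^2 + C1)(sx2 + sy2 + C2)).
similarity_index <- function(x, y, C1, C2, config, stabilize_degenerate) {
  check_same_shape(x, y)
  x <- as.matrix(x); y <- as.matrix(y)
  if (config$method == "global") {
    n <- length(x)
    denom_n <- if (config$population_variance) n else n - 1
    mx <- mean(x); my <- mean(y)
    sx2 <- sum((x - mx)^2) / denom_n
    sy2 <- sum((y - my)^2) / denom_n
    sxy <- sum((x - mx) * (y - my)) / denom_n
    vals <- sim_formula(mx, my, sx2, sy2, sxy, C1, C2, stabilize_degenerate)
  } else {
    w <- config$ssim_window
    if (any(dim(x) < w)) {
      stop(sprintf("images must be at least %d x %d for windowed metrics",
                   w, w), call. = FALSE)
    }
    n <- w * w
    denom_n <- if (config$population_variance) n else n - 1
    sx <- box_sums(x, w); sy <- box_sums(y, w)
    sxx <- box_sums(x * x, w); syy <- box_sums(y * y, w)
    sxy_ <- box_sums(x * y, w)
    mx <- sx / n; my <- sy / n
    sx2 <- (sxx - sx * mx) / denom_n
    sy2 <- (syy - sy * my) / denom_n
    sxy <- (sxy_ - sx * my) / denom_n
    vals <- sim_formula(mx, my, sx2, sy2, sxy, C1, C2, stabilize_degenerate)
  }
  mean(vals)
}

sim_formula <- function(mx, my, sx2, sy2, sxy, C1, C2,
                        stabilize_degenerate) {
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sx2 + sy2 + C2)
  vals <- num / den
  if (stabilize_degenerate && (C1 == 0 || C2 == 0)) {
    bad <- !is.finite(vals)
    if (any(bad)) {
      # fall back to SSIM-style constants where the bare formula is 0/0
      C1s <- if (C1 == 0) 1e-8 else C1
      C2s <- if (C2 == 0) 1e-8 else C2
      vals[bad] <- ((2 * mx * my + C1s) * (2 * sxy + C2s) /
                      ((mx^2 + my^2 + C1s) * (sx2 + sy2 + C2s)))[bad]
    }
  }
  vals
}

#' Structural similarity index
#'
#' `SSIM = (2*mx*my + C1)(2*sxy + C2) /
#' ((mx^2 + my^2 + C1)(sx2 + sy2 + C2))` with `C1 = (K1*L)^2` and
#' `C2 = (K2*L)^2`.  By default the formula is evaluated on every sliding
#' `ssim_window` x `ssim_window` window and averaged; `method = "global"`
#' evaluates it once on the whole image.
#'
#' @param x,y Numeric matrices of the same shape.
#' @param config A [metrics_config()].
#' @return Scalar `<= 1`; 1 iff the images are identical.
#' @export
ssim <- function(x, y, config = metrics_config()) {
  L <- config$dynamic_range_L
  similarity_index(x, y, (config$K1 * L)^2, (config$K2 * L)^2, config,
                   stabilize_degenerate = FALSE)
}

#' Universal image quality index
#'
#' `UIQI = 4*sxy*mx*my / ((sx2 + sy2) * (mx^2 + my^2))`, the product of a
#' correlation factor, a luminance-closeness factor and a
#' contrast-similarity factor; its range is \[-1, 1\] and it equals 1 only
#' for identical (non-constant) images.  It is the SSIM formula with
#' `C1 = C2 = 0`; degenerate windows (zero variance or zero mean energy)
#' are stabilized with small SSIM-style constants instead of returning
#' NaN.  Windowing follows [metrics_config()] exactly as for [ssim()].
#'
#' @param x,y Numeric matrices of the same shape.
#' @param config A [metrics_config()].
#' @return Scalar in \[-1, 1\].
#' @export
uiqi <- function(x, y, config = metrics_config()) {
  similarity_index(x, y, 0, 0, config, stabilize_degenerate = TRUE)
}

# Render an arbitrary real image onto the 0..255 scale by min-max
# stretching (constant images map to 0); the scale on which the metric
# suite compares phase maps.
to_uint8_scale <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) * (255 / diff(rng))
}

#' Score one reconstruction against ground truth
#'
#' Renders both maps to the 0..255 scale (min-max stretch, so the TIE's
#' arbitrary phase offset drops out) and computes the four quality
#' metrics.
#'
#' @param recon,truth Numeric matrices (e.g. `phase_map$phase_rad`).
#' @param config A [metrics_config()].
#' @return One-row [tibble::tibble()] with columns `ssim`, `mse`, `psnr`,
#'   `uiqi`.
#' @export
score_images <- function(recon, truth, config = metrics_config()) {
  r8 <- to_uint8_scale(as.matrix(recon))
  t8 <- to_uint8_scale(as.matrix(truth))
  m <- mse(r8, t8)
  tibble::tibble(
    ssim = ssim(r8, t8, config),
    mse = m,
    psnr = if (m == 0) Inf else 10 * log10(config$dynamic_range_L^2 / m),
    uiqi = uiqi(r8, t8, config))
}

#' Defocus-sweep comparison of conventional TIE and single-shot inference
#'
#' For every stack and every interior defocus plane z: (a) runs the
#' conventional TIE solver using the three frames centred at z (treating
#' the frame at z as the in-focus image, as happens when reconstruction
#' is attempted away from true focus), and (b) runs single-frame model
#' inference on the frame at z alone.  Both reconstructions are scored
#' against the stack's ground-truth phase.  Planes lacking bracketing
#' frames are skipped.
#'
#' @param model A trained [gan_train()] model, or `NULL` to evaluate the
#'   conventional TIE only.
#' @param stacks List of [intensity_stack()]s.
#' @param ground_truth List of [phase_map()]s, one per stack.
#' @param config A [metrics_config()].
#' @param tie_cfg A [tie_config()] for the conventional arm.
#' @param z_planes Optional numeric vector restricting the sweep to a
#'   subset of each stack's planes (e.g. the coarse scan, leaving out
#'   fine planes recorded only for ground-truth generation).
#' @param scan_planes Optional numeric vector of the planes that make up
#'   the conventional scan; the TIE arm draws its bracketing frames from
#'   these, so evaluated planes at the edge of `z_planes` can still be
#'   reconstructed when the scan extends further.  Defaults to
#'   `z_planes`.
#' @return A tibble of class `qpi_sweep` with one row per
#'   (method, stack, z): columns `method` ("tie" or "tie_gan"),
#'   `source_id`, `z_um`, `ssim`, `mse`, `psnr`, `uiqi`.
#' @export
evaluate_sweep <- function(model, stacks, ground_truth,
                           config = metrics_config(),
                           tie_cfg = tie_config(), z_planes = NULL,
                           scan_planes = z_planes) {
  stopifnot(length(stacks) == length(ground_truth))
  rows <- purrr::imap(stacks, function(st, si) {
    truth <- ground_truth[[si]]$phase_rad
    id <- if (!is.null(st$source_id)) st$source_id else paste0("stack", si)
    keep <- if (is.null(scan_planes)) seq_along(st$z_um) else
      which(st$z_um %in% union(scan_planes, z_planes))
    sub <- intensity_stack(st$frames[keep], st$z_um[keep], st$pitch_um,
                           st$config, source_id = st$source_id)
    z <- sub$z_um
    eval_idx <- if (is.null(z_planes)) seq_along(z) else
      which(z %in% z_planes)
    purrr::map(eval_idx, function(i) {
      out <- list()
      symmetric <- i > 1 && i < length(z) &&
        abs((z[i + 1] - z[i]) - (z[i] - z[i - 1])) < 1e-9
      if (symmetric) {
        ph <- tie_solve(sub, tie_cfg, at_z = z[i])
        out$tie <- dplyr::bind_cols(
          tibble::tibble(method = "tie", source_id = id, z_um = z[i]),
          score_images(ph$phase_rad, truth, config))
      }
      if (!is.null(model)) {
        pred <- gan_infer(model, sub$frames[[i]])
        out$gan <- dplyr::bind_cols(
          tibble::tibble(method = "tie_gan", source_id = id, z_um = z[i]),
          score_images(pred$phase_rad, truth, config))
      }
      dplyr::bind_rows(out)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qpi_sweep", class(out))
  out
}

#' Aggregate a metrics report
#'
#' Summarizes per-image records into the statistics usually quoted for a
#' reconstruction experiment (min/max/mean of each metric) plus an SSIM
#' histogram.
#'
#' @param report A tibble from [evaluate_sweep()] (or any tibble with
#'   `method`, `ssim`, `mse`, `psnr`, `uiqi` columns).
#' @param breaks Histogram breaks for SSIM.
#' @return A list with elements `summary` (tibble, one row per method)
#'   and `ssim_hist` (tibble of bin counts per method).
#' @export
summarize_metrics <- function(report, breaks = seq(0, 1, by = 0.05)) {
  finite_psnr <- function(p) p[is.finite(p)]
  summary <- report |>
    dplyr::group_by(.data$method) |>
    dplyr::summarize(
      n = dplyr::n(),
      min_ssim = min(.data$ssim), max_ssim = max(.data$ssim),
      mean_ssim = mean(.data$ssim),
      min_mse = min(.data$mse), max_mse = max(.data$mse),
      mean_mse = mean(.data$mse),
      min_psnr = min(finite_psnr(.data$psnr)),
      max_psnr = max(finite_psnr(.data$psnr)),
      min_uiqi = min(.data$uiqi), max_uiqi = max(.data$uiqi),
      .groups = "drop")
  hist <- report |>
    dplyr::mutate(bin = cut(pmax(pmin(.data$ssim, max(breaks)), min(breaks)),
                            breaks = breaks, include.lowest = TRUE)) |>
    dplyr::count(.data$method, .data$bin, .drop = FALSE)
  list(summary = summary, ssim_hist = hist)
}

#' Plot a defocus sweep
#'
#' Mean metric (default SSIM) against defocus distance, one line per
#' method.
#'
#' @param object A `qpi_sweep` tibble from [evaluate_sweep()].
#' @param metric Column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qpi_sweep <- function(object, metric = "ssim", ...) {
  dat <- object |>
    dplyr::group_by(.data$method, .data$z_um) |>
    dplyr::summarize(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$z_um, .data$value,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "defocus z (um)", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}
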