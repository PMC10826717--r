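#' Tidy the training history of a fitted model
#'
#' One row per (epoch, metric): the generator adversarial and L1 losses,
#' the discriminator loss and the validation SSIM.
#'
#' @param x A `tie_gan` model.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.tie_gan <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x A `tie_gan` model.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, tile size, best validation
#'   SSIM and its epoch, final losses.
#' @export
glance.tie_gan <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    tile = x$generator$tile,
    depth = x$generator$depth,
    best_val_ssim = ifelse(is.finite(x$best$val_ssim),
                           x$best$val_ssim, NA_real_),
    best_epoch = x$best$epoch,
    final_g_l1 = if (nrow(h)) h$g_l1[nrow(h)] else NA_real_,
    final_d_loss = if (nrow(h)) h$d_loss[nrow(h)] else NA_real_)
}

#' Plot training curves
#'
#' @param object A `tie_gan` model.
#' @param ... Unused.
#' @return A ggplot object, one panel per recorded metric.
#' @exportS3Method ggplot2::autoplot
autoplot.tie_gan <- function(object, ...) {
  dat <- tidy.tie_gan(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot a phase map
#'
#' @param object A [phase_map()].
#' @param ... Unused.
#' @return A ggplot raster of the phase in radians.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_map <- function(object, ...) {
  d <- dim(object$phase_rad)
  dat <- tidyr::expand_grid(x = seq_len(d[2]), y = seq_len(d[1]))
  dat$phase <- as.vector(object$phase_rad)
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

# Register broom-style generics without importing broom: define local
# generics if the generics package is unavailable at load time.
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")
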