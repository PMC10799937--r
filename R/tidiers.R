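#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.count_comparison <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                error = .data$obs - .data$pred,
                abs_error = abs(.data$obs - .data$pred))
}

#' @export
glance.count_comparison <- function(x, ...) {
  tibble::tibble(n = nrow(x), obs_total = sum(x$obs),
                 pred_total = sum(x$pred), mae = count_mae(x),
                 rte = relative_total_error(x), bias_pct = count_bias(x))
}

#' @export
tidy.segmentation_scores <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.segmentation_scores <- function(x, ...) {
  tibble::tibble(k = nrow(x), miou = attr(x, "miou"))
}

#' @export
tidy.train_state <- function(x, ...) x$history

#' @export
glance.train_state <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_count_mae = x$best_val_count_mae,
                 final_loss = x$history$loss[nrow(x$history)])
}

#' @export
autoplot.train_state <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_count_mae"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation count MAE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.energy_map <- function(object, ...) {
  df <- tibble::tibble(
    level = as.vector(object$levels),
    row = rep(seq_len(nrow(object$levels)), times = ncol(object$levels)),
    col = rep(seq_len(ncol(object$levels)), each = nrow(object$levels)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, object$K)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "energy", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.grid_metric <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = attr(object, "metric"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' True-colour display of a tile with percentile stretch
#'
#' Linear 2nd-98th percentile stretch per band (the convention used for
#' hotspot composites), rendered with per-pixel colours.
#'
#' @param tile a `raster_tile` with at least 3 bands.
#' @param bands band indices mapped to R, G, B.
#' @param probs stretch percentiles.
#' @return a ggplot object.
#' @export
plot_rgb <- function(tile, bands = 1:3, probs = c(0.02, 0.98)) {
  stretch <- function(m) {
    p <- stats::quantile(m, probs, names = FALSE)
    if (p[1] == p[2]) return(matrix(0.5, nrow(m), ncol(m)))
    pmin(1, pmax(0, (m - p[1]) / (p[2] - p[1])))
  }
  r <- stretch(tile$pixels[, , bands[1]])
  g <- stretch(tile$pixels[, , bands[2]])
  b <- stretch(tile$pixels[, , bands[3]])
  df <- tibble::tibble(
    row = rep(seq_len(nrow(r)), times = ncol(r)),
    col = rep(seq_len(ncol(r)), each = nrow(r)),
    colour = grDevices::rgb(as.vector(r), as.vector(g), as.vector(b)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$colour)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
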