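#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a model's edges
#'
#' @param x A [pc_graph()].
#' @param ... Unused.
#' @return Tibble with one row per directed edge: `source`, `target`,
#'   `weight`.
#' @export
tidy.pc_graph <- function(x, ...) {
  idx <- which(x$mask != 0, arr.ind = TRUE)
  tibble::tibble(source = as.integer(idx[, 1]),
                 target = as.integer(idx[, 2]),
                 weight = x$weights[idx]) |>
    dplyr::arrange(.data$source, .data$target)
}

#' One-row model summary
#'
#' @param x A [pc_graph()].
#' @param ... Unused.
#' @return One-row tibble: vertex/edge counts, partition sizes, activation,
#'   and weight scale.
#' @export
glance.pc_graph <- function(x, ...) {
  tibble::tibble(
    n_vertices = x$n_vertices,
    n_sensory = x$n_sensory,
    n_labels = x$n_labels,
    n_edges = as.integer(sum(x$mask)),
    activation = x$activation$name,
    topk = x$activation$topk,
    weight_sd = stats::sd(x$weights[x$mask != 0])
  )
}

#' @rdname tidy.pc_graph
#' @param x A `pc_fit`.
#' @export
tidy.pc_fit <- function(x, ...) x$log

#' @rdname glance.pc_graph
#' @export
glance.pc_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$model),
    tibble::tibble(epochs = nrow(x$log),
                   initial_energy = x$log$energy[1],
                   final_energy = x$log$energy[nrow(x$log)])
  )
}

#' Plot the training energy trajectory
#'
#' @param object A `pc_fit` from [pc_train()].
#' @param ... Unused.
#' @return A ggplot of total post-inference energy per epoch (log10 y scale).
#' @export
autoplot.pc_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch,
                                           y = .data$energy)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "total energy",
                  title = "Prediction-error energy during training") +
    ggplot2::theme_minimal()
}

#' Plot patterns as a raster grid
#'
#' Lays out one or more flattened square patterns side by side, the way
#' associative-memory figures show cue / retrieved / original rows.
#'
#' @param patterns Matrix (m x d) of flattened patterns, d a perfect square,
#'   or a named list of such matrices (one facet row per list element).
#' @param size Side length; default `sqrt(d)`.
#' @return A ggplot raster grid.
#' @export
plot_patterns <- function(patterns, size = NULL) {
  if (!is.list(patterns)) patterns <- list(patterns = patterns)
  long <- purrr::imap(patterns, function(mat, nm) {
    mat <- as_state_matrix(mat)
    d <- ncol(mat)
    s <- size %||% as.integer(round(sqrt(d)))
    tibble::tibble(
      group = nm,
      pattern = rep(seq_len(nrow(mat)), each = d),
      pixel = rep(seq_len(d), times = nrow(mat)),
      value = as.numeric(t(mat))
    ) |>
      dplyr::mutate(row = (.data$pixel - 1) %/% s + 1,
                    col = (.data$pixel - 1) %% s + 1)
  }) |>
    dplyr::bind_rows()
  long$group <- factor(long$group, levels = names(patterns))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), oob = scales_squish) +
    ggplot2::facet_grid(group ~ pattern, switch = "y") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   strip.text.x = ggplot2::element_blank())
}

# clamp out-of-range fill values instead of dropping them (patterns can
# slightly overshoot [0,1] after inference)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
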