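#' @keywords internal
pixel_indices <- function(model) {
  seq_len(model$n_sensory - model$n_labels)
}

#' @keywords internal
label_indices <- function(model) {
  if (model$n_labels == 0) return(integer())
  (model$n_sensory - model$n_labels + 1):model$n_sensory
}

require_label_block <- function(model) {
  if (model$n_labels == 0) {
    stop("this task needs a model trained with a 1-hot label block ",
         "(`n_labels` > 0)", call. = FALSE)
  }
}

mse <- function(a, b) mean((a - b)^2)

#' Classify patterns with a trained graph
#'
#' Clamps the pixel vertices to each pattern, runs inference with frozen
#' weights, and reads the class off the label-block value nodes by argmax
#' (ties broken by lowest class index).
#'
#' @param model A trained [pc_graph()] with a label block.
#' @param patterns Matrix (m x d_pixels) or vector of pixel values.
#' @param config A [pc_config()] providing the query step size and budget.
#' @return Integer vector of predicted class ids (1-based).
#' @export
pc_classify <- function(model, patterns, config = pc_config()) {
  require_label_block(model)
  patterns <- as_state_matrix(patterns)
  pix <- pixel_indices(model)
  if (ncol(patterns) != length(pix)) {
    stop(sprintf("patterns must have %d pixel columns", length(pix)),
         call. = FALSE)
  }
  clamp <- pc_clamp(fixed_idx = pix, fixed_val = patterns,
                    n_vertices = model$n_vertices)
  x <- query_by_conditioning(model, clamp, config)
  label_argmax(x[, label_indices(model), drop = FALSE])
}

label_argmax <- function(scores) {
  apply(scores, 1, function(s) which(s == max(s))[1])
}

#' Generate a class pattern
#'
#' Clamps the label block to the 1-hot encoding of `class_id` and relaxes the
#' rest of the graph; the generated pattern is the pixel block of the
#' converged value nodes.
#'
#' @param model A trained [pc_graph()] with a label block.
#' @param class_id Class to generate (1-based).
#' @param config A [pc_config()].
#' @return Numeric vector of generated pixel values.
#' @export
pc_generate <- function(model, class_id, config = pc_config()) {
  require_label_block(model)
  class_id <- as.integer(class_id)
  if (class_id < 1 || class_id > model$n_labels) {
    stop(sprintf("`class_id` must lie in 1..%d", model$n_labels),
         call. = FALSE)
  }
  onehot <- rep(0, model$n_labels)
  onehot[class_id] <- 1
  clamp <- pc_clamp(fixed_idx = label_indices(model), fixed_val = onehot,
                    n_vertices = model$n_vertices)
  x <- query_by_conditioning(model, clamp, config)
  as.numeric(x[1, pixel_indices(model)])
}

#' Complete a corrupted pattern
#'
#' In `"conditioning"` mode the observed pixels (and, when `label` is given,
#' the 1-hot label block) are clamped for every step, so observed entries are
#' returned exactly; in `"initialization"` mode the corrupted pattern only
#' initializes the pixel vertices and everything relaxes freely (the
#' denoising setting).
#'
#' @param model A trained [pc_graph()].
#' @param corrupted Pixel vector/matrix as produced by [corrupt()].
#' @param visible Logical vector over pixel positions; which entries are
#'   observed (ignored in initialization mode, where all pixels initialize).
#' @param config A [pc_config()].
#' @param mode `"conditioning"` or `"initialization"`.
#' @param label Optional class id clamped alongside the pixels
#'   (conditioning mode only).
#' @return Matrix (m x d_pixels) of completed patterns.
#' @export
pc_reconstruct <- function(model, corrupted, visible = NULL,
                           config = pc_config(),
                           mode = c("conditioning", "initialization"),
                           label = NULL) {
  mode <- match.arg(mode)
  corrupted <- as_state_matrix(corrupted)
  pix <- pixel_indices(model)
  if (ncol(corrupted) != length(pix)) {
    stop(sprintf("corrupted patterns must have %d pixel columns",
                 length(pix)), call. = FALSE)
  }
  if (mode == "conditioning") {
    if (is.null(visible)) visible <- rep(TRUE, length(pix))
    if (!any(visible)) {
      stop("conditioning mode needs at least one visible pixel",
           call. = FALSE)
    }
    fixed_idx <- pix[visible]
    fixed_val <- corrupted[, visible, drop = FALSE]
    if (!is.null(label)) {
      require_label_block(model)
      onehot <- matrix(0, nrow(corrupted), model$n_labels)
      onehot[cbind(seq_len(nrow(corrupted)), as.integer(label))] <- 1
      fixed_idx <- c(fixed_idx, label_indices(model))
      fixed_val <- cbind(fixed_val, onehot)
    }
    clamp <- pc_clamp(fixed_idx = fixed_idx, fixed_val = fixed_val,
                      n_vertices = model$n_vertices)
    x <- query_by_conditioning(model, clamp, config)
  } else {
    clamp <- pc_clamp(init_idx = pix, init_val = corrupted,
                      n_vertices = model$n_vertices)
    x <- query_by_initialization(model, clamp, config)
  }
  x[, pix, drop = FALSE]
}

#' Associative-memory retrieval score
#'
#' Corrupts each stored pattern, queries the trained graph (by conditioning
#' for masked cues, by initialization for noisy cues), and measures the mean
#' squared error of the retrieved pattern against the original.
#'
#' @param model A [pc_graph()] trained on `stored_patterns`.
#' @param stored_patterns Matrix (m x d_pixels) of the memorized patterns.
#' @param corruption A [corruption_spec()].
#' @param config A [pc_config()].
#' @param threshold MSE below which a retrieval counts as successful.
#' @param seed Seed for the corruption noise.
#' @return Tibble with one row per pattern: `pattern`, `mse_corrupted` (cue
#'   vs original, over the full pattern), `mse_retrieved`, `retrieved`
#'   (logical). Mean MSE and success fraction are attached as attributes
#'   `mean_mse` and `fraction_retrieved`.
#' @export
memory_retrieval_score <- function(model, stored_patterns, corruption,
                                   config = pc_config(), threshold = 0.05,
                                   seed = 1) {
  stored_patterns <- as_state_matrix(stored_patterns)
  cue <- corrupt(stored_patterns, corruption, seed = seed)
  mode <- if (corruption$mode == "gaussian_noise") "initialization"
          else "conditioning"
  out <- pc_reconstruct(model, cue$corrupted, cue$visible, config,
                        mode = mode)
  res <- tibble::tibble(
    pattern = seq_len(nrow(stored_patterns)),
    mse_corrupted = purrr::map_dbl(
      seq_len(nrow(stored_patterns)),
      function(i) mse(cue$corrupted[i, ], stored_patterns[i, ])),
    mse_retrieved = purrr::map_dbl(
      seq_len(nrow(stored_patterns)),
      function(i) mse(out[i, ], stored_patterns[i, ]))
  ) |>
    dplyr::mutate(retrieved = .data$mse_retrieved < threshold)
  attr(res, "mean_mse") <- mean(res$mse_retrieved)
  attr(res, "fraction_retrieved") <- mean(res$retrieved)
  res
}
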