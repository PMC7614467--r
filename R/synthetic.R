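#' Synthetic class-structured glyph patterns
#'
#' Generates small grayscale patterns from fixed binary glyph prototypes
#' (stripes, checkerboard, frame, cross, ...) plus i.i.d. Gaussian pixel
#' noise, clipped to \[0, 1\]. The glyphs stand in for image datasets in all
#' tests and examples: they are class-separable, low-resolution, and cheap,
#' which is exactly what end-to-end runs of the training loop need.
#'
#' @param n_classes Number of classes (1 to 8).
#' @param n_per_class Patterns per class (balanced sampling).
#' @param size Side length of the square glyph (default 8, so d = 64).
#' @param noise_sd Within-class pixel noise standard deviation.
#' @param labels Attach a 1-hot label block (`TRUE` by default).
#' @param seed Seed; the dataset is bit-identical under the same seed.
#' @return An object of class `pc_synth`: list with `patterns` (m x d matrix
#'   in \[0, 1\]), `labels` (integer class ids, 1-based), `label_block`
#'   (m x n_classes 1-hot matrix or `NULL`), `prototypes` (n_classes x d),
#'   and the generator parameters.
#' @examples
#' ds <- make_synthetic(n_classes = 2, n_per_class = 3, noise_sd = 0, seed = 1)
#' dim(ds$patterns)
#' @export
make_synthetic <- function(n_classes = 4, n_per_class = 8, size = 8,
                           noise_sd = 0.05, labels = TRUE, seed = 1) {
  stopifnot(n_classes >= 1, n_classes <= 8, n_per_class >= 1, size >= 4)
  protos <- glyph_prototypes(size)[seq_len(n_classes), , drop = FALSE]
  m <- n_classes * n_per_class
  cls <- rep(seq_len(n_classes), each = n_per_class)
  patterns <- withr::with_seed(seed, {
    p <- protos[cls, , drop = FALSE]
    if (noise_sd > 0) {
      p <- p + matrix(stats::rnorm(length(p), sd = noise_sd), nrow = m)
    }
    pmin(pmax(p, 0), 1)
  })
  label_block <- NULL
  if (labels) {
    label_block <- matrix(0, m, n_classes)
    label_block[cbind(seq_len(m), cls)] <- 1
  }
  structure(list(patterns = patterns, labels = cls,
                 label_block = label_block, prototypes = protos,
                 n_classes = n_classes, size = size, noise_sd = noise_sd,
                 seed = seed),
            class = "pc_synth")
}

# fixed library of distinct binary glyphs on a size x size grid, row-major
glyph_prototypes <- function(size) {
  r <- matrix(rep(seq_len(size), each = size), size, byrow = TRUE)  # row idx
  c_ <- matrix(rep(seq_len(size), times = size), size, byrow = TRUE) # col idx
  half <- size %/% 2
  glyphs <- list(
    vstripes = (c_ %% 2 == 1) * 1,
    hstripes = (r %% 2 == 1) * 1,
    checker = ((r + c_) %% 2 == 0) * 1,
    frame = (r == 1 | r == size | c_ == 1 | c_ == size) * 1,
    cross = (r == half | c_ == half) * 1,
    diag = (abs(r - c_) <= 1) * 1,
    quad = (r <= half & c_ <= half | r > half & c_ > half) * 1,
    dot = (abs(r - half) <= 1 & abs(c_ - half) <= 1) * 1
  )
  unname(do.call(rbind, lapply(glyphs, function(g) as.numeric(t(g)))))
}

#' @export
print.pc_synth <- function(x, ...) {
  cat(sprintf("<pc_synth> %d patterns, %d classes, %dx%d, noise sd %g\n",
              nrow(x$patterns), x$n_classes, x$size, x$size, x$noise_sd))
  invisible(x)
}

#' Tidy a synthetic dataset into long pixel form
#'
#' @param x A `pc_synth` dataset.
#' @param ... Unused.
#' @return Tibble with columns `pattern`, `class`, `pixel`, `row`, `col`,
#'   `value` — convenient for ggplot2 raster display.
#' @export
tidy.pc_synth <- function(x, ...) {
  d <- ncol(x$patterns)
  size <- x$size
  tibble::tibble(
    pattern = rep(seq_len(nrow(x$patterns)), each = d),
    class = rep(x$labels, each = d),
    pixel = rep(seq_len(d), times = nrow(x$patterns)),
    value = as.numeric(t(x$patterns))
  ) |>
    dplyr::mutate(row = (.data$pixel - 1) %/% size + 1,
                  col = (.data$pixel - 1) %% size + 1)
}

#' Corruption specification
#'
#' @param mode `"half_mask"` (hide the bottom half of the pixels, row-major),
#'   `"fraction_mask"` (hide the bottom `fraction`), or `"gaussian_noise"`
#'   (add zero-mean pixel noise of variance `sigma2` everywhere).
#' @param fraction Fraction of pixels hidden by `fraction_mask`, in (0, 1).
#' @param sigma2 Noise variance for `gaussian_noise`, >= 0.
#' @return A list of class `pc_corruption`.
#' @export
corruption_spec <- function(mode = c("half_mask", "fraction_mask",
                                     "gaussian_noise"),
                            fraction = 0.5, sigma2 = 0.5) {
  mode <- match.arg(mode)
  if (mode == "fraction_mask" && (fraction <= 0 || fraction >= 1)) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (sigma2 < 0) stop("`sigma2` must be >= 0", call. = FALSE)
  structure(list(mode = mode, fraction = fraction, sigma2 = sigma2),
            class = "pc_corruption")
}

#' Corrupt patterns
#'
#' Applies the corruption a retrieval task presents to the network: masking a
#' trailing block of pixels (hidden entries are zeroed) or adding Gaussian
#' noise to every pixel.
#'
#' @param patterns Numeric matrix (m x d) or vector of length d.
#' @param spec A [corruption_spec()].
#' @param seed Seed for the noise draw.
#' @return List with `corrupted` (same shape as `patterns`) and `visible`
#'   (logical vector of length d; which pixel positions remain observed).
#' @export
corrupt <- function(patterns, spec, seed = 1) {
  patterns <- as_state_matrix(patterns)
  d <- ncol(patterns)
  visible <- rep(TRUE, d)
  corrupted <- patterns
  if (spec$mode %in% c("half_mask", "fraction_mask")) {
    n_hidden <- if (spec$mode == "half_mask") d - d %/% 2
                else round(spec$fraction * d)
    if (n_hidden > 0) visible[(d - n_hidden + 1):d] <- FALSE
    corrupted[, !visible] <- 0
  } else if (spec$sigma2 > 0) {
    corrupted <- corrupted + withr::with_seed(
      seed, matrix(stats::rnorm(length(patterns), sd = sqrt(spec$sigma2)),
                   nrow = nrow(patterns)))
  }
  list(corrupted = corrupted, visible = visible)
}
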