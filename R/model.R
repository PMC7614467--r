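#' Construct a predictive-coding graph model
#'
#' A PC graph is a directed graph whose vertices each hold a value node x_i, a
#' prediction mu_i formed from incoming edges, and a local error
#' eps_i = x_i - mu_i. The weight `theta[a, b]` lives on the directed edge
#' a -> b and contributes `theta[a, b] * f(x_a)` to the prediction of vertex
#' b. The first `n_sensory` vertices are sensory (clamped to stimuli during
#' training); the rest are internal latent vertices. Optionally the last
#' `n_labels` sensory vertices form a 1-hot label block used by the
#' classification and generation tasks.
#'
#' @param mask Binary n x n matrix; `mask[a, b] = 1` iff the edge a -> b
#'   exists. The diagonal must be zero (no self-edges).
#' @param n_sensory Number of sensory vertices d, with 0 < d < n.
#' @param activation A [pc_activation()] (default `tanh`).
#' @param n_labels Size of the 1-hot label block at the end of the sensory
#'   range (0 for unlabelled models).
#' @param weights Optional initial n x n weight matrix (zeroed off-mask). When
#'   omitted, weights are drawn i.i.d. normal with sd `1/sqrt(n)` on masked
#'   edges.
#' @param seed Optional seed used only when `weights` is omitted.
#' @return An object of class `pc_graph`.
#' @examples
#' m <- pc_graph(build_mask(topology_spec("fully_connected", n = 6)),
#'               n_sensory = 4, seed = 1)
#' m
#' @export
pc_graph <- function(mask, n_sensory, activation = pc_activation("tanh"),
                     n_labels = 0L, weights = NULL, seed = NULL) {
  mask <- as.matrix(mask)
  n <- nrow(mask)
  if (ncol(mask) != n) stop("`mask` must be square", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary", call. = FALSE)
  if (any(diag(mask) != 0)) {
    stop("`mask` must have a zero diagonal (no self-edges)", call. = FALSE)
  }
  n_sensory <- as.integer(n_sensory)
  if (n_sensory <= 0 || n_sensory >= n) {
    stop("`n_sensory` must satisfy 0 < d < n", call. = FALSE)
  }
  n_labels <- as.integer(n_labels)
  if (n_labels < 0 || n_labels > n_sensory) {
    stop("`n_labels` must lie in [0, n_sensory]", call. = FALSE)
  }
  if (is.null(weights)) {
    if (!is.null(seed)) {
      weights <- withr::with_seed(seed, matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n))
    } else {
      weights <- matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n)
    }
  } else {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == c(n, n))) {
      stop("`weights` must be n x n", call. = FALSE)
    }
  }
  weights <- weights * mask
  structure(
    list(n_vertices = n, n_sensory = n_sensory, n_labels = n_labels,
         mask = mask, weights = weights, activation = activation),
    class = "pc_graph"
  )
}

#' @export
print.pc_graph <- function(x, ...) {
  cat(sprintf("<pc_graph> %d vertices (%d sensory%s), %d edges, activation %s\n",
              x$n_vertices, x$n_sensory,
              if (x$n_labels > 0) sprintf(" incl. %d labels", x$n_labels) else "",
              sum(x$mask), x$activation$name))
  invisible(x)
}

#' Predictions of every vertex
#'
#' Computes mu_b = sum_a theta[a, b] * f(x_a) for every vertex b: the
#' mask-respecting weighted sum of transformed value nodes over incoming
#' edges.
#'
#' @param object A [pc_graph()].
#' @param x Value-node matrix (batch x n) or vector of length n.
#' @param ... Unused.
#' @return Prediction matrix mu of the same shape as `x` (vectors are
#'   promoted to 1 x n).
#' @export
predict.pc_graph <- function(object, x, ...) {
  x <- as_state_matrix(x)
  if (ncol(x) != object$n_vertices) {
    stop(sprintf("`x` must have %d columns, got %d",
                 object$n_vertices, ncol(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  act_forward(object$activation, x) %*% object$weights
}

#' Refresh the inference state
#'
#' A state bundles per-sample value nodes `x`, predictions `mu`, errors
#' `eps = x - mu` and the current step `t`. `pc_state()` builds a consistent
#' state from value nodes.
#'
#' @param model A [pc_graph()].
#' @param x Value-node matrix (batch x n) or vector.
#' @param t Inference step counter.
#' @return A list with elements `x`, `mu`, `eps`, `t` of class `pc_state`.
#' @export
pc_state <- function(model, x, t = 0L) {
  x <- as_state_matrix(x)
  mu <- predict(model, x)
  structure(list(x = x, mu = mu, eps = x - mu, t = as.integer(t)),
            class = "pc_state")
}

#' Prediction-error energy
#'
#' The energy is half the sum of squared vertex errors,
#' `E = 1/2 * sum_i eps_i^2`, evaluated per batch row. Both inference and
#' learning are gradient descent on this quantity.
#'
#' @param model A [pc_graph()].
#' @param state A `pc_state` (or a value-node matrix, refreshed internally).
#' @return Numeric vector of per-sample energies.
#' @export
pc_energy <- function(model, state) {
  if (!inherits(state, "pc_state")) state <- pc_state(model, state)
  0.5 * rowSums(state$eps^2)
}
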