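#' Activation specifications
#'
#' An activation spec bundles a pointwise nonlinearity `f` with its derivative
#' `f'`, optionally composed with a per-cluster top-k gate: within each listed
#' cluster only the `ceiling(keep_frac * cluster_size)` vertices with the
#' highest activity keep their (transformed) value, the rest are zeroed, and
#' the derivative is gated by the same keep-mask. Vertices not covered by any
#' cluster pass through the base nonlinearity untouched.
#'
#' @param name One of `"identity"`, `"tanh"`, `"relu"`.
#' @param clusters Optional list of integer vectors of vertex indices; must be
#'   disjoint. When supplied the activation becomes top-k composed.
#' @param keep_frac Keep-fraction k in (0, 1]: the fraction of each cluster
#'   allowed to fire per step.
#' @return An object of class `pc_activation`.
#' @examples
#' act <- pc_activation("tanh")
#' act_forward(act, matrix(c(0, 1), 1))
#' @export
pc_activation <- function(name = c("identity", "tanh", "relu"),
                          clusters = NULL, keep_frac = NULL) {
  name <- match.arg(name)
  topk <- !is.null(clusters)
  if (topk) {
    if (is.null(keep_frac) || keep_frac <= 0 || keep_frac > 1) {
      stop("`keep_frac` must lie in (0, 1] for a top-k composed activation",
           call. = FALSE)
    }
    clusters <- lapply(clusters, as.integer)
    all_idx <- unlist(clusters)
    if (anyDuplicated(all_idx) > 0) {
      stop("top-k clusters must be disjoint", call. = FALSE)
    }
  }
  structure(
    list(name = name, topk = topk, clusters = clusters,
         keep_frac = keep_frac),
    class = "pc_activation"
  )
}

act_base_forward <- function(name, x) {
  switch(name,
    identity = x,
    tanh = tanh(x),
    relu = pmax(x, 0)
  )
}

act_base_deriv <- function(name, x) {
  switch(name,
    identity = array(1, dim(x)) ,
    tanh = 1 - tanh(x)^2,
    relu = (x > 0) * 1
  )
}

# keep-mask for the top-k gate, computed row-wise on the base-activated
# values; ties broken by lowest vertex index
topk_keep_mask <- function(act, fx) {
  keep <- array(1, dim(fx))
  for (cl in act$clusters) {
    m <- length(cl)
    n_keep <- ceiling(act$keep_frac * m)
    if (n_keep >= m) next
    sub <- fx[, cl, drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      ord <- order(-sub[r, ], seq_len(m))
      drop_idx <- ord[(n_keep + 1):m]
      keep[r, cl[drop_idx]] <- 0
    }
  }
  keep
}

#' Apply an activation (forward map)
#'
#' @param act A [pc_activation()].
#' @param x Numeric matrix (batch x n) or vector of value nodes.
#' @return Matrix of the same shape: `f(x)`, with the top-k gate applied when
#'   the spec carries one.
#' @export
act_forward <- function(act, x) {
  x <- as_state_matrix(x)
  fx <- act_base_forward(act$name, x)
  if (act$topk) fx <- fx * topk_keep_mask(act, fx)
  fx
}

#' Apply an activation derivative
#'
#' Pointwise derivative of [act_forward()]; for top-k composed activations the
#' base derivative is gated by the keep-mask of the current values.
#'
#' @inheritParams act_forward
#' @return Matrix of the same shape as `x`.
#' @export
act_deriv <- function(act, x) {
  x <- as_state_matrix(x)
  dx <- act_base_deriv(act$name, x)
  if (act$topk) {
    fx <- act_base_forward(act$name, x)
    dx <- dx * topk_keep_mask(act, fx)
  }
  dx
}

as_state_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' @export
print.pc_activation <- function(x, ...) {
  if (x$topk) {
    cat(sprintf("<pc_activation> %s, top-k composed (k = %g, %d clusters)\n",
                x$name, x$keep_frac, length(x$clusters)))
  } else {
    cat(sprintf("<pc_activation> %s\n", x$name))
  }
  invisible(x)
}
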