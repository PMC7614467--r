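#' Training configuration
#'
#' @param gamma Value-node (inference) step size, > 0.
#' @param alpha Weight step size, > 0.
#' @param n_iter Inference iterations T per presentation.
#' @param batch_size Samples per weight update (default: full batch).
#' @param epochs Passes over the dataset.
#' @param seed Seed controlling internal-node initialization and batch order.
#' @param tol Optional early-stop threshold on max |delta x| during inference
#'   (`NULL` disables early stopping; training uses the fixed T by default).
#' @return A list of class `pc_config`.
#' @export
pc_config <- function(gamma = 0.1, alpha = 0.01, n_iter = 32L,
                      batch_size = NULL, epochs = 100L, seed = 1L,
                      tol = NULL) {
  stopifnot(gamma >= 0, alpha >= 0, n_iter >= 1)
  structure(list(gamma = gamma, alpha = alpha, n_iter = as.integer(n_iter),
                 batch_size = batch_size, epochs = as.integer(epochs),
                 seed = as.integer(seed), tol = tol),
            class = "pc_config")
}

#' Clamp specification
#'
#' Distinguishes vertices held *fixed* for every inference step (query by
#' conditioning) from vertices merely *initialized* at t = 0 (query by
#' initialization). The two index sets must be disjoint and strictly smaller
#' than the vertex set.
#'
#' @param fixed_idx Integer vertex indices clamped for all t.
#' @param fixed_val Values for the fixed vertices: vector of length
#'   `length(fixed_idx)` or a batch x q matrix.
#' @param init_idx Vertex indices set only at t = 0.
#' @param init_val Their initial values, same shape rules as `fixed_val`.
#' @param n_vertices Total vertex count, used for validation.
#' @return A list of class `pc_clamp`.
#' @export
pc_clamp <- function(fixed_idx = integer(), fixed_val = NULL,
                     init_idx = integer(), init_val = NULL,
                     n_vertices = NULL) {
  fixed_idx <- as.integer(fixed_idx)
  init_idx <- as.integer(init_idx)
  if (length(intersect(fixed_idx, init_idx)) > 0) {
    stop("`fixed_idx` and `init_idx` must be disjoint", call. = FALSE)
  }
  if (!is.null(n_vertices) &&
      length(union(fixed_idx, init_idx)) >= n_vertices) {
    stop("clamped vertices must form a strict subset of the graph",
         call. = FALSE)
  }
  as_val <- function(v, idx, what) {
    if (length(idx) == 0) return(NULL)
    if (is.null(v)) stop(sprintf("`%s` required", what), call. = FALSE)
    if (!is.matrix(v)) v <- matrix(v, nrow = 1)
    if (ncol(v) != length(idx)) {
      stop(sprintf("`%s` must have one column per index", what),
           call. = FALSE)
    }
    v
  }
  structure(list(fixed_idx = fixed_idx,
                 fixed_val = as_val(fixed_val, fixed_idx, "fixed_val"),
                 init_idx = init_idx,
                 init_val = as_val(init_val, init_idx, "init_val")),
            class = "pc_clamp")
}

apply_fixed <- function(x, clamp) {
  if (length(clamp$fixed_idx) > 0) {
    v <- clamp$fixed_val
    if (nrow(v) == 1 && nrow(x) > 1) v <- v[rep(1, nrow(x)), , drop = FALSE]
    x[, clamp$fixed_idx] <- v
  }
  x
}

apply_init <- function(x, clamp) {
  if (length(clamp$init_idx) > 0) {
    v <- clamp$init_val
    if (nrow(v) == 1 && nrow(x) > 1) v <- v[rep(1, nrow(x)), , drop = FALSE]
    x[, clamp$init_idx] <- v
  }
  apply_fixed(x, clamp)
}

#' One inference step on the value nodes
#'
#' Gradient descent on the energy with respect to the value nodes: every
#' unclamped vertex i moves by
#' `gamma * (-eps_i + f'(x_i) * sum_k eps_k * theta[i, k])`,
#' i.e. it is pulled toward its own prediction and toward reducing the errors
#' of the vertices it predicts. Fixed vertices are bit-identical before and
#' after; `mu` and `eps` are refreshed afterwards.
#'
#' @param model A [pc_graph()].
#' @param state A `pc_state` with refreshed errors.
#' @param clamp A [pc_clamp()] (default: nothing clamped).
#' @param gamma Step size.
#' @return The updated `pc_state`.
#' @export
inference_step <- function(model, state, clamp = pc_clamp(), gamma) {
  fp <- act_deriv(model$activation, state$x)
  dx <- gamma * (-state$eps + fp * (state$eps %*% t(model$weights)))
  if (!all(is.finite(dx))) {
    stop(sprintf("inference diverged (non-finite update at gamma = %g)",
                 gamma), call. = FALSE)
  }
  x_new <- state$x + dx
  x_new <- apply_fixed(x_new, clamp)
  pc_state(model, x_new, t = state$t + 1L)
}

#' Run the inference phase
#'
#' Applies [inference_step()] for up to `n_iter` steps, optionally stopping
#' early once `max(|delta x|) < tol`. Records the total energy after every
#' step.
#'
#' @inheritParams inference_step
#' @param n_iter Maximum number of steps.
#' @param tol Optional early-stop threshold on the largest value-node change.
#' @return A list with `state` (final `pc_state`), `energy` (numeric vector,
#'   total batch energy per step, starting with the initial state), and
#'   `steps` actually taken.
#' @export
run_inference <- function(model, state, clamp = pc_clamp(), gamma,
                          n_iter, tol = NULL) {
  energy <- numeric(n_iter + 1)
  energy[1] <- sum(pc_energy(model, state))
  steps <- 0L
  for (t in seq_len(n_iter)) {
    x_prev <- state$x
    state <- inference_step(model, state, clamp, gamma)
    steps <- t
    energy[t + 1] <- sum(pc_energy(model, state))
    if (!is.null(tol) && max(abs(state$x - x_prev)) < tol) break
  }
  list(state = state, energy = energy[seq_len(steps + 1)], steps = steps)
}

#' One weight update
#'
#' After the inference phase the value nodes are frozen and every existing
#' edge a -> b takes a single local step
#' `theta[a, b] <- theta[a, b] + alpha * mean_batch(eps_b * f(x_a))`,
#' the gradient-descent step on the energy with respect to the weights.
#' Masked entries are untouched and remain exactly zero.
#'
#' @param model A [pc_graph()].
#' @param state The post-inference `pc_state`.
#' @param alpha Weight step size.
#' @return The updated `pc_graph`.
#' @export
weight_update <- function(model, state, alpha) {
  fx <- act_forward(model$activation, state$x)
  grad <- crossprod(fx, state$eps) / nrow(state$x)
  model$weights <- (model$weights + alpha * grad) * model$mask
  model
}

random_state <- function(model, batch, sd = 0.01) {
  matrix(stats::rnorm(batch * model$n_vertices, sd = sd),
         batch, model$n_vertices)
}

#' Train a predictive-coding graph
#'
#' For every batch the sensory vertices are clamped to the data rows, the
#' internal value nodes are randomly re-initialized, the inference phase runs
#' for T steps, and a single weight update follows. The per-epoch total
#' post-inference energy is logged.
#'
#' @param model A [pc_graph()].
#' @param data Numeric matrix (m x d) of training rows, d = `n_sensory`
#'   columns (including any 1-hot label block). A `pc_synth` dataset from
#'   [make_synthetic()] is also accepted.
#' @param config A [pc_config()].
#' @return An object of class `pc_fit`: list with the trained `model`, a
#'   tibble `log` (epoch, energy), and the `config`.
#' @examples
#' mask <- build_mask(topology_spec("fully_connected", n = 12))
#' mod <- pc_graph(mask, n_sensory = 4, seed = 1)
#' fit <- pc_train(mod, matrix(c(1, 0, 1, 0), 1), pc_config(epochs = 5))
#' fit$log
#' @export
pc_train <- function(model, data, config = pc_config()) {
  data <- training_matrix(data)
  d <- model$n_sensory
  if (ncol(data) != d) {
    stop(sprintf("training rows must have %d columns (= n_sensory), got %d",
                 d, ncol(data)), call. = FALSE)
  }
  m <- nrow(data)
  bs <- if (is.null(config$batch_size)) m else min(config$batch_size, m)
  set.seed(config$seed)
  log_energy <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (bs < m) sample.int(m) else seq_len(m)
    ep_energy <- 0
    for (start in seq(1, m, by = bs)) {
      rows <- ord[start:min(start + bs - 1, m)]
      x <- random_state(model, length(rows))
      clamp <- pc_clamp(fixed_idx = seq_len(d),
                        fixed_val = data[rows, , drop = FALSE])
      x <- apply_fixed(x, clamp)
      res <- run_inference(model, pc_state(model, x), clamp,
                           gamma = config$gamma, n_iter = config$n_iter,
                           tol = config$tol)
      model <- weight_update(model, res$state, config$alpha)
      ep_energy <- ep_energy + sum(pc_energy(model, res$state$x))
    }
    log_energy[ep] <- ep_energy
  }
  structure(list(model = model,
                 log = tibble::tibble(epoch = seq_len(config$epochs),
                                      energy = log_energy),
                 config = config),
            class = "pc_fit")
}

training_matrix <- function(data) {
  if (inherits(data, "pc_synth")) {
    if (is.null(data$label_block)) data$patterns
    else cbind(data$patterns, data$label_block)
  } else {
    as.matrix(data)
  }
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("<pc_fit> %d epochs, final energy %.4g\n",
              nrow(x$log), x$log$energy[nrow(x$log)]))
  print(x$model)
  invisible(x)
}

query_defaults <- function(config) {
  list(gamma = config$gamma,
       n_iter = max(config$n_iter, 5000L),
       tol = if (is.null(config$tol)) 1e-6 else config$tol)
}

#' Query a trained graph by conditioning
#'
#' All value nodes are randomly re-initialized, the `fixed_idx` vertices are
#' clamped to their values for every step, and inference runs to convergence
#' with frozen weights. The result estimates the conditional expectation of
#' the free value nodes given the clamped stimulus; clamped entries are
#' returned exactly.
#'
#' @param model A trained [pc_graph()] (weights are not modified).
#' @param clamp A [pc_clamp()] with nonempty `fixed_idx`.
#' @param config A [pc_config()]; `gamma` and `tol` are used, and the
#'   iteration budget is `max(n_iter, 5000)` with early stop at `tol`
#'   (default 1e-6).
#' @param init Optional full value-node matrix to start from instead of the
#'   random re-initialization.
#' @return Matrix (batch x n) of converged value nodes.
#' @export
query_by_conditioning <- function(model, clamp, config = pc_config(),
                                  init = NULL) {
  if (length(clamp$fixed_idx) == 0) {
    stop("query by conditioning needs a nonempty `fixed_idx`", call. = FALSE)
  }
  if (length(clamp$fixed_idx) >= model$n_vertices) {
    stop("all vertices clamped: nothing to infer", call. = FALSE)
  }
  q <- query_defaults(config)
  batch <- if (is.matrix(clamp$fixed_val)) nrow(clamp$fixed_val) else 1L
  x <- if (is.null(init)) random_state(model, batch) else as_state_matrix(init)
  x <- apply_init(x, clamp)
  res <- run_inference(model, pc_state(model, x), clamp,
                       gamma = q$gamma, n_iter = q$n_iter, tol = q$tol)
  res$state$x
}

#' Query a trained graph by initialization
#'
#' All value nodes are randomly re-initialized, the `init_idx` vertices are
#' set to their values at t = 0 only, and every vertex is free during the
#' energy minimization. The result is the minimum reached by gradient descent
#' from that initialization — the mechanism behind denoising.
#'
#' @param model A trained [pc_graph()].
#' @param clamp A [pc_clamp()] with nonempty `init_idx` and empty `fixed_idx`.
#' @inheritParams query_by_conditioning
#' @return Matrix (batch x n) of converged value nodes.
#' @export
query_by_initialization <- function(model, clamp, config = pc_config(),
                                    init = NULL) {
  if (length(clamp$init_idx) == 0) {
    stop("query by initialization needs a nonempty `init_idx`", call. = FALSE)
  }
  if (length(clamp$fixed_idx) > 0) {
    stop("query by initialization fixes no vertex; use `init_idx` only",
         call. = FALSE)
  }
  q <- query_defaults(config)
  batch <- if (is.matrix(clamp$init_val)) nrow(clamp$init_val) else 1L
  x <- if (is.null(init)) random_state(model, batch) else as_state_matrix(init)
  x <- apply_init(x, clamp)
  res <- run_inference(model, pc_state(model, x), pc_clamp(),
                       gamma = q$gamma, n_iter = q$n_iter, tol = q$tol)
  res$state$x
}
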