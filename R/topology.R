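#' Declarative topology specification
#'
#' Describes a binary adjacency mask to be realized by [build_mask()]. The
#' supported kinds mirror the architectures obtainable by pruning a fully
#' connected graph:
#'
#' * `fully_connected` — every ordered pair, no self-edges.
#' * `layered_forward` — edges from layer l to layer l+1 only (a multilayer
#'   perceptron skeleton).
#' * `layered_generative` — the transpose: edges from layer l+1 down to layer
#'   l, so the first layer (the sensory end of the hierarchy) receives
#'   top-down predictions.
#' * `layered_lateral` — `layered_forward` plus all-to-all edges within each
#'   layer.
#' * `assemblies` — ordered Erdos-Renyi neuron clusters: within each cluster,
#'   and within each listed ordered cluster pair, each ordered vertex pair is
#'   connected independently with probability `p`.
#' * `custom` — a user-supplied mask, validated only.
#'
#' @param kind Topology kind (see above).
#' @param n Vertex count (`fully_connected` / `custom`).
#' @param layer_sizes Integer vector of layer sizes (layered kinds). Layers
#'   occupy consecutive index ranges in order unless `layers` is given.
#' @param layers Optional list of integer index vectors, one per layer, for
#'   layered kinds whose layers are not contiguous in vertex order (e.g. a
#'   generative hierarchy whose top layer is a label block that must live
#'   inside the sensory index range). Overrides `layer_sizes`.
#' @param cluster_sizes Integer vector of cluster sizes (`assemblies`).
#' @param p Edge probability in \[0, 1\] (`assemblies`).
#' @param inter_cluster_edges List of ordered pairs `c(a, b)` of cluster
#'   indices to connect sparsely (`assemblies`).
#' @param mask Custom binary mask (`custom`).
#' @param seed Seed for the Erdos-Renyi draws.
#' @return A list of class `pc_topology`.
#' @export
topology_spec <- function(kind = c("fully_connected", "layered_forward",
                                   "layered_generative", "layered_lateral",
                                   "assemblies", "custom"),
                          n = NULL, layer_sizes = NULL, layers = NULL,
                          cluster_sizes = NULL,
                          p = NULL, inter_cluster_edges = list(),
                          mask = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(layers) && is.null(layer_sizes)) {
    layer_sizes <- lengths(layers)
  }
  spec <- structure(list(kind = kind, n = n,
                         layer_sizes = layer_sizes,
                         layers = if (is.null(layers)) NULL
                                  else lapply(layers, as.integer),
                         cluster_sizes = cluster_sizes, p = p,
                         inter_cluster_edges = inter_cluster_edges,
                         mask = mask, seed = seed),
                    class = "pc_topology")
  validate_topology(spec)
  spec
}

validate_topology <- function(spec) {
  switch(spec$kind,
    fully_connected = {
      if (is.null(spec$n) || spec$n < 2) {
        stop("`n` >= 2 required for fully_connected", call. = FALSE)
      }
    },
    custom = {
      if (is.null(spec$mask)) stop("`mask` required for custom", call. = FALSE)
    },
    assemblies = {
      if (is.null(spec$cluster_sizes) || any(spec$cluster_sizes < 1)) {
        stop("positive `cluster_sizes` required for assemblies", call. = FALSE)
      }
      if (is.null(spec$p) || spec$p < 0 || spec$p > 1) {
        stop("`p` must lie in [0, 1]", call. = FALSE)
      }
      m <- length(spec$cluster_sizes)
      for (e in spec$inter_cluster_edges) {
        if (length(e) != 2 || any(e < 1) || any(e > m)) {
          stop("`inter_cluster_edges` entries must be valid cluster pairs",
               call. = FALSE)
        }
      }
    },
    {
      if (is.null(spec$layer_sizes) || length(spec$layer_sizes) < 2 ||
          any(spec$layer_sizes < 1)) {
        stop("at least two positive `layer_sizes` required", call. = FALSE)
      }
    }
  )
  invisible(spec)
}

layer_index_ranges <- function(layer_sizes) {
  ends <- cumsum(layer_sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) seq.int(s, e))
}

#' Build a binary adjacency mask from a topology specification
#'
#' @param spec A [topology_spec()].
#' @return Binary n x n matrix with zero diagonal; `mask[a, b] = 1` iff edge
#'   a -> b exists.
#' @examples
#' sum(build_mask(topology_spec("layered_forward", layer_sizes = c(2, 2, 1))))
#' @export
build_mask <- function(spec) {
  validate_topology(spec)
  if (spec$kind == "fully_connected") {
    mask <- matrix(1, spec$n, spec$n)
    diag(mask) <- 0
    return(mask)
  }
  if (spec$kind == "custom") {
    mask <- as.matrix(spec$mask)
    if (nrow(mask) != ncol(mask) || !all(mask %in% c(0, 1))) {
      stop("custom `mask` must be a square binary matrix", call. = FALSE)
    }
    diag(mask) <- 0
    return(mask)
  }
  if (spec$kind == "assemblies") {
    return(assemblies_mask(spec))
  }
  sizes <- spec$layer_sizes
  n <- sum(sizes)
  ranges <- spec$layers %||% layer_index_ranges(sizes)
  mask <- matrix(0, n, n)
  for (l in seq_len(length(sizes) - 1)) {
    if (spec$kind == "layered_generative") {
      mask[ranges[[l + 1]], ranges[[l]]] <- 1
    } else {
      mask[ranges[[l]], ranges[[l + 1]]] <- 1
    }
  }
  if (spec$kind == "layered_lateral") {
    for (r in ranges) mask[r, r] <- 1
  }
  diag(mask) <- 0
  mask
}

assemblies_mask <- function(spec) {
  sizes <- spec$cluster_sizes
  n <- sum(sizes)
  ranges <- layer_index_ranges(sizes)
  blocks <- c(lapply(seq_along(sizes), function(i) c(i, i)),
              spec$inter_cluster_edges)
  draw <- function() {
    mask <- matrix(0, n, n)
    for (b in blocks) {
      ra <- ranges[[b[1]]]; rb <- ranges[[b[2]]]
      mask[ra, rb] <- (matrix(stats::runif(length(ra) * length(rb)),
                              length(ra)) < spec$p) * 1
    }
    diag(mask) <- 0
    mask
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, draw()) else draw()
}

#' Build a neuron-assemblies model
#'
#' Constructs a PC graph emulating sparsely connected brain regions: ordered
#' Erdos-Renyi clusters (each ordered vertex pair within a cluster, and
#' within each listed cluster pair, connected independently with probability
#' `p`) with a top-k composed activation in which only the
#' `ceiling(k * cluster_size)` most active vertices of each cluster fire at
#' every step.
#'
#' @param cluster_sizes Integer vector of cluster sizes, in order.
#' @param p Edge probability.
#' @param k Keep-fraction in (0, 1].
#' @param inter_cluster_edges Ordered cluster pairs to connect (for a
#'   feedforward chain of m clusters: `list(c(1,2), c(2,3), ...)`).
#' @param n_sensory Number of sensory vertices (default: the first cluster).
#' @param base Base nonlinearity composed with the top-k gate.
#' @param seed Seed for the mask draw and weight initialization.
#' @return A [pc_graph()].
#' @export
assemblies_model <- function(cluster_sizes, p, k,
                             inter_cluster_edges = list(),
                             n_sensory = cluster_sizes[1],
                             base = "tanh", seed = NULL) {
  spec <- topology_spec("assemblies", cluster_sizes = cluster_sizes, p = p,
                        inter_cluster_edges = inter_cluster_edges,
                        seed = seed)
  mask <- build_mask(spec)
  clusters <- layer_index_ranges(cluster_sizes)
  act <- pc_activation(base, clusters = clusters, keep_frac = k)
  pc_graph(mask, n_sensory = n_sensory, activation = act, seed = seed)
}

#' Export a mask as an edge list
#'
#' @param mask Binary adjacency matrix.
#' @return Tibble with columns `source`, `target`, one row per directed edge.
#' @export
mask_edge_list <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  tibble::tibble(source = as.integer(idx[, 1]),
                 target = as.integer(idx[, 2])) |>
    dplyr::arrange(.data$source, .data$target)
}

#' @export
print.pc_topology <- function(x, ...) {
  cat(sprintf("<pc_topology> %s\n", x$kind))
  invisible(x)
}
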