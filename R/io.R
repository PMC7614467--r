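PC_ARCHIVE_VERSION <- 1L

#' Save / load a model archive
#'
#' The archive is a single JSON file holding the format version, the
#' partition sizes, the activation spec, the mask (as an edge list) and the
#' dense weight matrix. The round trip is bit-exact for mask, weights,
#' partition and activation.
#'
#' @param model A [pc_graph()].
#' @param path File path to write/read.
#' @return `save_pc_graph` returns `path` invisibly; `load_pc_graph` returns
#'   the restored [pc_graph()].
#' @export
save_pc_graph <- function(model, path) {
  edges <- which(model$mask != 0, arr.ind = TRUE)
  payload <- list(
    format = "pcgraph-model",
    version = PC_ARCHIVE_VERSION,
    n_vertices = model$n_vertices,
    n_sensory = model$n_sensory,
    n_labels = model$n_labels,
    activation = list(name = model$activation$name,
                      topk = model$activation$topk,
                      keep_frac = model$activation$keep_frac,
                      clusters = model$activation$clusters),
    edges = list(source = as.integer(edges[, 1]),
                 target = as.integer(edges[, 2])),
    # serialized at full double precision, column-major
    weights = as.numeric(model$weights)
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_pc_graph
#' @export
load_pc_graph <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop(sprintf("not a readable model archive: %s", conditionMessage(e)),
           call. = FALSE)
    })
  for (field in c("format", "version", "n_vertices", "n_sensory",
                  "n_labels", "activation", "edges", "weights")) {
    if (is.null(payload[[field]])) {
      stop(sprintf("model archive is missing field '%s'", field),
           call. = FALSE)
    }
  }
  if (!identical(payload$format, "pcgraph-model")) {
    stop("file is not a pcgraph model archive", call. = FALSE)
  }
  if (payload$version != PC_ARCHIVE_VERSION) {
    stop(sprintf("incompatible archive version %s (expected %d)",
                 payload$version, PC_ARCHIVE_VERSION), call. = FALSE)
  }
  n <- payload$n_vertices
  if (length(payload$weights) != n * n) {
    stop(sprintf("model archive is corrupt: field 'weights' has %d entries, expected %d",
                 length(payload$weights), n * n), call. = FALSE)
  }
  mask <- matrix(0, n, n)
  mask[cbind(payload$edges$source, payload$edges$target)] <- 1
  act <- payload$activation
  if (is.matrix(act$clusters)) {   # equal-length clusters simplify to a matrix
    act$clusters <- lapply(seq_len(nrow(act$clusters)),
                           function(i) act$clusters[i, ])
  }
  activation <- if (isTRUE(act$topk)) {
    pc_activation(act$name, clusters = act$clusters,
                  keep_frac = act$keep_frac)
  } else {
    pc_activation(act$name)
  }
  pc_graph(mask, n_sensory = payload$n_sensory,
           activation = activation, n_labels = payload$n_labels,
           weights = matrix(payload$weights, n, n))
}

#' Read / write declarative specs
#'
#' Topology specs, train configs and experiment configs are plain YAML (or
#' JSON) mappings whose keys mirror the constructor arguments.
#'
#' @param path YAML or JSON file.
#' @return `read_topology_spec` returns a [topology_spec()];
#'   `read_train_config` a [pc_config()].
#' @export
read_topology_spec <- function(path) {
  raw <- read_config_file(path)
  topology_spec(kind = raw$kind %||% "fully_connected",
                n = raw$n, layer_sizes = raw$layer_sizes,
                cluster_sizes = raw$cluster_sizes, p = raw$p,
                inter_cluster_edges = raw$inter_cluster_edges %||% list(),
                seed = raw$seed)
}

#' @rdname read_topology_spec
#' @export
read_train_config <- function(path) {
  raw <- read_config_file(path)
  pc_config(gamma = raw$gamma %||% 0.1, alpha = raw$alpha %||% 0.01,
            n_iter = raw$n_iter %||% 32L,
            batch_size = raw$batch_size,
            epochs = raw$epochs %||% 100L, seed = raw$seed %||% 1L,
            tol = raw$tol)
}

#' Read a YAML or JSON configuration file
#'
#' @param path File path; `.json` is parsed as JSON, anything else as YAML.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a declarative experiment
#'
#' Builds the topology, generates the synthetic dataset, trains the model,
#' runs the listed tasks with frozen weights, and writes every metric as CSV
#' (plus optional PNG pattern grids) under `out_dir`. Every artifact records
#' the config hash and seed, and the whole run is reproducible from the
#' config alone.
#'
#' @param config Named list (typically from [read_config_file()]) with keys:
#'   `topology` (topology_spec arguments), `train` (pc_config arguments),
#'   `data` (make_synthetic arguments), `tasks` (subset of "classify",
#'   "generate", "reconstruct", "denoise", "memory"), `corruption`
#'   (corruption_spec arguments), `seed`, `out_dir`, and optional `plots`
#'   (logical; write PNG grids).
#' @return A list with the `fit`, a tibble `metrics`, and the paths written,
#'   invisibly contributing its CSV artifacts under `out_dir`.
#' @export
run_experiment <- function(config) {
  known_tasks <- c("classify", "generate", "reconstruct", "denoise", "memory")
  tasks <- config$tasks %||% character()
  if (length(setdiff(tasks, known_tasks)) > 0) {
    stop(sprintf("unknown task(s): %s",
                 paste(setdiff(tasks, known_tasks), collapse = ", ")),
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("`out_dir` required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  stamp <- function(df) {
    dplyr::mutate(df, config_hash = cfg_hash, seed = seed)
  }

  stage <- "data"
  result <- tryCatch({
    data_args <- config$data %||% list()
    data_args$seed <- data_args$seed %||% seed
    ds <- do.call(make_synthetic, data_args)

    stage <- "topology"
    topo_args <- config$topology %||% list(kind = "fully_connected")
    d <- ncol(ds$patterns) + if (is.null(ds$label_block)) 0 else ds$n_classes
    n_internal <- config$n_internal %||% max(32L, d)
    if (identical(topo_args$kind %||% "fully_connected", "fully_connected") &&
        is.null(topo_args$n)) {
      topo_args$n <- d + n_internal
    }
    spec <- do.call(topology_spec, topo_args)
    mask <- build_mask(spec)

    stage <- "train"
    train_args <- config$train %||% list()
    train_args$seed <- train_args$seed %||% seed
    tcfg <- do.call(pc_config, train_args)
    model <- pc_graph(mask, n_sensory = d,
                      n_labels = if (is.null(ds$label_block)) 0L
                                 else ds$n_classes,
                      seed = seed)
    fit <- pc_train(model, ds, tcfg)
    readr_write <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      path
    }
    paths <- readr_write(stamp(fit$log), "energy.csv")

    stage <- "tasks"
    metrics <- list()
    corr_args <- config$corruption %||% list(mode = "half_mask")
    corr <- do.call(corruption_spec, corr_args)
    for (task in tasks) {
      metrics[[task]] <- run_task(task, fit, ds, corr, tcfg, seed)
    }
    metrics <- dplyr::bind_rows(metrics)
    if (nrow(metrics) > 0) {
      paths <- c(paths, readr_write(stamp(metrics), "metrics.csv"))
    }
    if (isTRUE(config$plots)) {
      p <- autoplot.pc_fit(fit)
      plot_path <- file.path(out_dir, "energy.png")
      ggplot2::ggsave(plot_path, p, width = 5, height = 3.5, dpi = 120)
      paths <- c(paths, plot_path)
    }
    list(fit = fit, metrics = metrics, paths = paths)
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

run_task <- function(task, fit, ds, corr, tcfg, seed) {
  model <- fit$model
  switch(task,
    classify = {
      pred <- pc_classify(model, ds$patterns, tcfg)
      tibble::tibble(task = "classify", metric = "accuracy",
                     value = mean(pred == ds$labels))
    },
    generate = {
      cors <- purrr::map_dbl(seq_len(ds$n_classes), function(cl) {
        stats::cor(pc_generate(model, cl, tcfg), ds$prototypes[cl, ])
      })
      tibble::tibble(task = "generate",
                     metric = paste0("correlation_class_",
                                     seq_len(ds$n_classes)),
                     value = cors)
    },
    reconstruct = {
      cue <- corrupt(ds$patterns, corruption_spec("half_mask"), seed = seed)
      out <- pc_reconstruct(model, cue$corrupted, cue$visible, tcfg)
      tibble::tibble(task = "reconstruct", metric = "mse",
                     value = mse(out, ds$patterns))
    },
    denoise = {
      noisy <- corrupt(ds$patterns,
                       corruption_spec("gaussian_noise",
                                       sigma2 = corr$sigma2),
                       seed = seed)
      out <- pc_reconstruct(model, noisy$corrupted, config = tcfg,
                            mode = "initialization")
      tibble::tibble(task = "denoise",
                     metric = c("mse_input", "mse_output"),
                     value = c(mse(noisy$corrupted, ds$patterns),
                               mse(out, ds$patterns)))
    },
    memory = {
      score <- memory_retrieval_score(model, ds$patterns, corr, tcfg,
                                      seed = seed)
      tibble::tibble(task = "memory",
                     metric = c("mean_mse", "fraction_retrieved"),
                     value = c(attr(score, "mean_mse"),
                               attr(score, "fraction_retrieved")))
    }
  )
}
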