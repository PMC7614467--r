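# one small labelled model shared by the task tests: 4 glyph classes on an
# 8x8 grid, fully connected graph, trained once here
task_ds <- make_synthetic(n_classes = 4, n_per_class = 4, noise_sd = 0.02,
                          seed = 3)
task_cfg <- pc_config(gamma = 0.2, alpha = 0.1, n_iter = 24, epochs = 200,
                      seed = 3)
task_fit <- pc_train(
  pc_graph(build_mask(topology_spec("fully_connected", n = 150)),
           n_sensory = 68, n_labels = 4, seed = 3),
  task_ds, task_cfg)

test_that("label readout takes the argmax with ties to the lowest class", {
  expect_equal(pcgraph:::label_argmax(matrix(c(0.1, 0.9, 0.3), 1)), 2)
  expect_equal(pcgraph:::label_argmax(matrix(c(0.4, 0.4, 0.4), 1)), 1)
})

test_that("a trained graph classifies its training prototypes", {
  set.seed(1)
  pred <- pc_classify(task_fit$model, task_ds$prototypes, task_cfg)
  expect_equal(pred, 1:4)
  expect_error(pc_classify(task_fit$model, task_ds$prototypes[, 1:10],
                           task_cfg), "pixel columns")
  unlabelled <- pc_graph(build_mask(topology_spec("fully_connected", n = 10)),
                         n_sensory = 4, seed = 1)
  expect_error(pc_classify(unlabelled, matrix(0, 1, 4)), "label block")
})

test_that("generation from a clamped label recovers the class prototype", {
  set.seed(1)
  for (cl in 1:4) {
    g <- pc_generate(task_fit$model, cl, task_cfg)
    expect_gt(stats::cor(g, task_ds$prototypes[cl, ]), 0.9)
  }
  expect_error(pc_generate(task_fit$model, 9, task_cfg), "class_id")

  # with zero weights there is no drive: the energy minimum is all-zero
  zero <- pc_graph(task_fit$model$mask, n_sensory = 68, n_labels = 4,
                   weights = matrix(0, 150, 150))
  set.seed(1)
  expect_equal(pc_generate(zero, 1, task_cfg), rep(0, 64),
               tolerance = 1e-4)
})

test_that("conditioning-mode completion is exact on observed pixels", {
  cue <- corrupt(task_ds$prototypes, corruption_spec("half_mask"))
  set.seed(1)
  out <- pc_reconstruct(task_fit$model, cue$corrupted, cue$visible, task_cfg)
  expect_identical(out[, cue$visible], cue$corrupted[, cue$visible])
  # hidden half lands nearer the own prototype than any other class
  for (cl in 1:4) {
    d_own <- mean((out[cl, !cue$visible] -
                     task_ds$prototypes[cl, !cue$visible])^2)
    for (other in setdiff(1:4, cl)) {
      expect_lt(d_own, mean((out[cl, !cue$visible] -
                               task_ds$prototypes[other, !cue$visible])^2))
    }
  }
  expect_error(pc_reconstruct(task_fit$model, cue$corrupted,
                              rep(FALSE, 64), task_cfg), "visible")
})

test_that("an ambiguous cue resolves toward whichever label is clamped", {
  # vertical stripes (class 1) and checkerboard (class 3) share their odd
  # rows; showing only the first row makes the cue ambiguous
  proto <- task_ds$prototypes[1, ]
  visible <- rep(FALSE, 64); visible[1:8] <- TRUE
  cue <- proto * visible
  set.seed(1)
  as1 <- pc_reconstruct(task_fit$model, cue, visible, task_cfg, label = 1)
  set.seed(1)
  as3 <- pc_reconstruct(task_fit$model, cue, visible, task_cfg, label = 3)
  p1 <- task_ds$prototypes[1, !visible]
  p3 <- task_ds$prototypes[3, !visible]
  expect_lt(mean((as1[1, !visible] - p1)^2), mean((as1[1, !visible] - p3)^2))
  expect_lt(mean((as3[1, !visible] - p3)^2), mean((as3[1, !visible] - p1)^2))
  expect_false(isTRUE(all.equal(as1[1, !visible], as3[1, !visible])))
})

test_that("memory retrieval scores stored patterns and denoises", {
  ds <- make_synthetic(n_classes = 3, n_per_class = 1, size = 4,
                       noise_sd = 0, labels = FALSE, seed = 5)
  cfg <- pc_config(gamma = 0.2, alpha = 0.1, n_iter = 24, epochs = 300,
                   seed = 5)
  fit <- pc_train(
    pc_graph(build_mask(topology_spec("fully_connected", n = 60)),
             n_sensory = 16, seed = 5),
    ds, cfg)

  set.seed(2)
  sc_half <- memory_retrieval_score(fit$model, ds$patterns,
                                    corruption_spec("half_mask"), cfg)
  expect_lt(attr(sc_half, "mean_mse"), 0.05)
  expect_equal(attr(sc_half, "fraction_retrieved"), 1)

  # uncorrupted patterns sit at the stored fixed points
  set.seed(2)
  sc_none <- memory_retrieval_score(fit$model, ds$patterns,
                                    corruption_spec("gaussian_noise",
                                                    sigma2 = 0), cfg)
  expect_lt(attr(sc_none, "mean_mse"), 0.01)

  # noisy cues end up closer to the original than they started
  set.seed(2)
  sc_noise <- memory_retrieval_score(fit$model, ds$patterns,
                                     corruption_spec("gaussian_noise",
                                                     sigma2 = 0.2), cfg)
  expect_true(all(sc_noise$mse_retrieved < sc_noise$mse_corrupted))
})

test_that("retrieval improves with training epochs on the memory benchmark", {
  ds <- make_synthetic(n_classes = 3, n_per_class = 1, size = 4,
                       noise_sd = 0, labels = FALSE, seed = 6)
  model <- pc_graph(build_mask(topology_spec("fully_connected", n = 60)),
                    n_sensory = 16, seed = 6)
  mses <- sapply(c(30, 120, 480), function(ep) {
    cfg <- pc_config(gamma = 0.2, alpha = 0.1, n_iter = 24, epochs = ep,
                     seed = 6)
    fit <- pc_train(model, ds, cfg)
    set.seed(2)
    attr(memory_retrieval_score(fit$model, ds$patterns,
                                corruption_spec("half_mask"), cfg),
         "mean_mse")
  })
  expect_true(all(diff(mses) < 0))
})
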