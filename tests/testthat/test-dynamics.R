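test_that("inference step matches the hand-derived chain update", {
  m <- chain_model(theta = 1)
  st <- pc_state(m, c(1, 2))
  st1 <- inference_step(m, st, gamma = 0.1)
  # vertex 1: gamma * (-eps1 + f'(x1) * eps2 * theta12) = 0.1 * (-1 + 1) = 0
  # vertex 2: gamma * (-eps2 + 0) = -0.1
  expect_equal(st1$x - st$x, matrix(c(0, -0.1), 1))
  expect_equal(st1$t, 1L)
  expect_equal(st1$eps, st1$x - predict(m, st1$x))
})

test_that("a zero-error state is a fixed point of inference", {
  m <- chain_model(theta = 1)
  st <- pc_state(m, c(0, 0))
  st1 <- inference_step(m, st, gamma = 0.5)
  expect_equal(st1$x, st$x)
})

test_that("inference and weight updates equal the finite-difference energy gradient", {
  for (seed in 1:6) {
    act <- if (seed %% 2 == 0) "tanh" else "identity"
    m <- random_model(8, seed = seed, activation = act)
    x <- withr::with_seed(100 + seed, matrix(rnorm(16), 2, 8))
    st <- pc_state(m, x)

    dx <- inference_step(m, st, gamma = 1)$x - x
    expect_lt(max_rel_err(dx, -fd_energy_grad_x(m, x)), 1e-6)

    dth <- weight_update(m, st, alpha = 1)$weights - m$weights
    # batch mean of the per-sample gradient = 1/B of the summed gradient
    expect_lt(max_rel_err(dth, -fd_energy_grad_theta(m, x) / nrow(x)), 1e-6)
  }
})

test_that("run_inference solves a clamped DAG exactly and descends energy", {
  mask <- build_mask(topology_spec("layered_forward", layer_sizes = c(2, 3, 2)))
  m <- pc_graph(mask, n_sensory = 2, seed = 2)
  clamp <- pc_clamp(fixed_idx = 1:2, fixed_val = c(0.4, -0.2), n_vertices = 7)
  x <- matrix(0.01, 1, 7)
  x[1, 1:2] <- c(0.4, -0.2)
  res <- run_inference(m, pc_state(m, x), clamp, gamma = 0.2,
                       n_iter = 5000, tol = 1e-12)
  # the exact feedforward solution zeroes every free-vertex error; the
  # clamped sources keep their constant error x - 0
  expect_lt(sum(res$state$eps[1, 3:7]^2), 1e-8)
  expect_equal(res$state$x[1, 1:2], c(0.4, -0.2))
})

test_that("energy trajectories are non-increasing at small gamma", {
  for (seed in 1:10) {
    m <- random_model(10, seed = 200 + seed)
    x <- withr::with_seed(seed, matrix(rnorm(10, sd = 0.5), 1, 10))
    res <- run_inference(m, pc_state(m, x), gamma = 1e-3, n_iter = 200)
    expect_true(all(diff(res$energy) <= 1e-12))
  }
})

test_that("free vertex between two clamps converges to the quadratic minimizer", {
  m <- chain3_model(theta = 1)
  clamp <- pc_clamp(fixed_idx = c(1, 3), fixed_val = c(0, 1), n_vertices = 3)
  x <- matrix(0.01, 1, 3)
  x[1, c(1, 3)] <- c(0, 1)
  res <- run_inference(m, pc_state(m, x), clamp, gamma = 0.1,
                       n_iter = 5000, tol = 1e-9)
  # minimizes 0.5 * ((x2 - 0)^2 + (1 - x2)^2)  =>  x2 = 0.5
  expect_equal(res$state$x[1, 2], 0.5, tolerance = 1e-5)
})

test_that("weight update moves errors down and conserves the mask", {
  m <- chain_model(theta = 1)
  st <- pc_state(m, c(1, 2))          # eps2 = 1, f(x1) = 1
  m1 <- weight_update(m, st, alpha = 0.01)
  expect_equal(m1$weights[1, 2], 1.01)
  expect_equal(pc_state(m1, c(1, 2))$eps[1, 2], 2 - 1.01)
  expect_equal(m1$weights[m1$mask == 0], rep(0, sum(m1$mask == 0)))
})

test_that("training reduces energy, respects alpha = 0, and is deterministic", {
  ds <- withr::with_seed(3, matrix(runif(10), 1, 10))
  mask <- build_mask(topology_spec("fully_connected", n = 14))
  m <- pc_graph(mask, n_sensory = 10, seed = 4)
  cfg <- pc_config(gamma = 0.1, alpha = 0.05, n_iter = 16, epochs = 200,
                   seed = 5)
  fit <- pc_train(m, ds, cfg)
  expect_lt(fit$log$energy[200], 0.01 * fit$log$energy[1])

  frozen <- pc_train(m, ds, pc_config(alpha = 0, epochs = 3, seed = 5))
  expect_identical(frozen$model$weights, m$weights)

  fit2 <- pc_train(m, ds, cfg)
  expect_identical(fit$model$weights, fit2$model$weights)

  expect_error(pc_train(m, cbind(ds, 1), cfg), "n_sensory")
})

test_that("two orthogonal patterns are both retrievable after training", {
  # orthogonal, and both visible halves are nonzero so each cue has drive
  pats <- rbind(rep(c(1, 0), 4), rep(c(0, 1), 4))
  mask <- build_mask(topology_spec("fully_connected", n = 20))
  m <- pc_graph(mask, n_sensory = 8, seed = 6)
  cfg <- pc_config(gamma = 0.2, alpha = 0.1, n_iter = 24, epochs = 300,
                   seed = 6)
  fit <- pc_train(m, pats, cfg)
  cue <- corrupt(pats, corruption_spec("half_mask"))
  set.seed(1)
  out <- pc_reconstruct(fit$model, cue$corrupted, cue$visible, cfg)
  expect_lt(mean((out - pats)^2), 0.05)
})

test_that("query by conditioning reproduces closed-form solutions", {
  m <- chain_model(theta = 0.7)
  set.seed(1)
  x <- query_by_conditioning(m, pc_clamp(fixed_idx = 1, fixed_val = 1,
                                         n_vertices = 2),
                             pc_config(gamma = 0.1, tol = 1e-8))
  expect_equal(x[1, 1], 1)              # clamp is exact
  expect_equal(x[1, 2], 0.7, tolerance = 1e-5)

  m3 <- chain3_model(theta = 1)
  set.seed(1)
  x3 <- query_by_conditioning(m3, pc_clamp(fixed_idx = c(1, 3),
                                           fixed_val = c(0, 1),
                                           n_vertices = 3),
                              pc_config(gamma = 0.1, tol = 1e-8))
  expect_equal(x3[1, 2], 0.5, tolerance = 1e-5)
})

test_that("conditioning on a tree with identity activation matches the linear system", {
  # star 1 -> {2, 3}, 2 -> 4: clamp leaves, solve for the rest in closed form
  mask <- matrix(0, 4, 4)
  mask[1, 2] <- mask[1, 3] <- mask[2, 4] <- 1
  w <- mask * matrix(c(0, 0.8, -0.5, 0, 0, 0, 0, 0.6, rep(0, 8)), 4, 4,
                     byrow = TRUE)
  m <- pc_graph(mask, n_sensory = 2,
                activation = pc_activation("identity"), weights = w)
  clamp <- pc_clamp(fixed_idx = c(3, 4), fixed_val = c(0.3, -0.2),
                    n_vertices = 4)
  # minimize E over (x1, x2): solve grad = 0 linear system independently
  # eps: e1=x1, e2=x2-.8x1, e3=.3+.5x1, e4=-.2-.6x2
  A <- matrix(c(1 + 0.64 + 0.25, -0.8,
                -0.8, 1 + 0.36), 2, 2, byrow = TRUE)
  b <- c(-0.5 * 0.3, -0.6 * 0.2)
  want <- solve(A, b)
  set.seed(2)
  x <- query_by_conditioning(m, clamp, pc_config(gamma = 0.1, tol = 1e-8))
  expect_equal(as.numeric(x[1, 1:2]), want, tolerance = 1e-5)
})

test_that("clamped vertices stay bit-identical across all inference steps", {
  m <- random_model(9, seed = 31)
  vals <- c(0.25, -1.5)
  clamp <- pc_clamp(fixed_idx = c(2, 7), fixed_val = vals, n_vertices = 9)
  x0 <- matrix(0.1, 1, 9)
  x0[1, c(2, 7)] <- vals
  st <- pc_state(m, x0)
  for (i in 1:20) {
    st <- inference_step(m, st, clamp, gamma = 0.05)
    expect_identical(as.numeric(st$x[1, c(2, 7)]), vals)
  }
})

test_that("query by initialization relaxes freely from the cue", {
  # start at an exact fixed point: output equals input
  m <- chain_model(theta = 1)
  set.seed(1)
  out <- query_by_initialization(m, pc_clamp(init_idx = 1:2,
                                             init_val = c(0, 0)),
                                 pc_config(gamma = 0.1))
  expect_equal(out, matrix(0, 1, 2))

  # gamma ~ 0 freezes the dynamics at the initialization
  m2 <- random_model(6, seed = 12)
  init <- c(0.3, -0.2, 0.5)
  set.seed(2)
  out2 <- query_by_initialization(m2, pc_clamp(init_idx = 1:3,
                                               init_val = init),
                                  pc_config(gamma = 0, n_iter = 5))
  expect_identical(as.numeric(out2[1, 1:3]), init)
})

test_that("clamp specifications validate their invariants", {
  expect_error(pc_clamp(fixed_idx = 1, fixed_val = 1, init_idx = 1,
                        init_val = 0), "disjoint")
  expect_error(pc_clamp(fixed_idx = 1:3, fixed_val = 1:3, n_vertices = 3),
               "strict subset")
  expect_error(query_by_conditioning(chain_model(), pc_clamp()), "fixed_idx")
  expect_error(query_by_initialization(chain_model(), pc_clamp(
    fixed_idx = 1, fixed_val = 1)), "init_idx|fixes no vertex")
})

test_that("inference reports divergence instead of returning non-finite values", {
  m <- chain_model(theta = 1e4, activation = "identity")
  st <- pc_state(m, c(1e150, -1e150))
  expect_error(inference_step(m, st, gamma = 1e160), "diverged")
})
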