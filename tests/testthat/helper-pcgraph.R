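# shared fixtures: tiny graphs with hand-checkable dynamics and an
# independent finite-difference oracle for the energy gradients

chain_model <- function(theta = 1, activation = "identity") {
  mask <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  pc_graph(mask, n_sensory = 1,
           activation = pc_activation(activation),
           weights = theta * mask)
}

chain3_model <- function(theta = 1) {
  mask <- matrix(0, 3, 3)
  mask[1, 2] <- 1
  mask[2, 3] <- 1
  pc_graph(mask, n_sensory = 2,
           activation = pc_activation("identity"),
           weights = theta * mask)
}

random_model <- function(n, seed, activation = "tanh", p_edge = 0.5) {
  withr::with_seed(seed, {
    mask <- matrix(stats::rbinom(n * n, 1, p_edge), n, n)
    diag(mask) <- 0
    pc_graph(mask, n_sensory = max(1L, n %/% 3),
             activation = pc_activation(activation),
             weights = matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n))
  })
}

# independent oracle: central finite differences of the energy, computed
# straight from predict() + pc_energy() without touching the update rules
fd_energy_grad_x <- function(model, x, h = 1e-6) {
  g <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (i in seq_len(ncol(x))) {
      xp <- x; xp[r, i] <- xp[r, i] + h
      xm <- x; xm[r, i] <- xm[r, i] - h
      g[r, i] <- (sum(pc_energy(model, xp)) - sum(pc_energy(model, xm))) /
        (2 * h)
    }
  }
  g
}

fd_energy_grad_theta <- function(model, x, h = 1e-6) {
  n <- model$n_vertices
  g <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (model$mask[a, b] == 0) next
      mp <- model; mp$weights[a, b] <- mp$weights[a, b] + h
      mm <- model; mm$weights[a, b] <- mm$weights[a, b] - h
      g[a, b] <- (sum(pc_energy(mp, pc_state(mp, x))) -
                    sum(pc_energy(mm, pc_state(mm, x)))) / (2 * h)
    }
  }
  g
}

max_rel_err <- function(got, want, floor = 1e-3) {
  max(abs(got - want) / pmax(abs(want), floor))
}
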