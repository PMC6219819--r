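test_that("linear response reduces to diag(gamma) with no hidden-hidden coupling", {
  fx <- make_stable_spec(6, 3, seed = 1)
  spec <- fx$spec
  spec$weights[fx$part$hidden, fx$part$hidden] <- 0
  mf <- solve_hidden_rates(spec, fx$part)
  grid <- frequency_grid(dt = 0.05, n_time = 64)
  gop <- transfer_operator(spec, fx$part, mf, grid)
  for (i in c(1, 7, 33)) {
    expect_equal(gop$gamma_matrices[[i]], diag(mf$gains) + 0i,
                 tolerance = 1e-12)
  }
  expect_equal(gop$spectral_radius_zero, 0)
})

test_that("single hidden neuron: Gamma equals the self-loop node factor", {
  spec <- network_spec(matrix(-0.9, 1, 1), baselines = 0.95,
                       nonlinearity = nonlinearity("rectified_linear"),
                       kernels = kernel_map(self = kernel("single_exp", 1)))
  part <- partition(recorded = integer(0), hidden = 1L, n_neurons = 1)
  mf <- solve_hidden_rates(spec, part)
  grid <- frequency_grid(dt = 0.1, n_time = 32)
  gop <- transfer_operator(spec, part, mf, grid)
  for (i in seq_along(grid$omegas)) {
    jhat <- kernel_freq(kernel("single_exp", 1), -0.9, grid$omegas[i])
    expect_equal(gop$gamma_matrices[[i]][1, 1],
                 mf$gains[1] / (1 - mf$gains[1] * jhat), tolerance = 1e-12)
  }
})

test_that("two-neuron feedforward: triangular solve done by hand", {
  W <- matrix(0, 2, 2)
  W[2, 1] <- 0.7 # hidden 1 -> hidden 2
  spec <- network_spec(W, baselines = -1,
                       kernels = kernel_map(default = kernel("delta")))
  part <- partition(recorded = integer(0), hidden = 1:2, n_neurons = 2)
  mf <- solve_hidden_rates(spec, part)
  gop <- transfer_operator(spec, part, mf, NULL)
  G <- gop$gamma_matrices[[1]]
  expect_equal(G[2, 1], mf$gains[2] * (0.7 + 0i) * mf$gains[1])
  expect_equal(G[1, 2], 0 + 0i)
  expect_equal(G[1, 1], mf$gains[1] + 0i)
})

test_that("transfer operator satisfies its defining identity and Hermitian symmetry", {
  fx <- make_stable_spec(8, 3, seed = 7, sd = 0.3, sparsity = 0.7,
                         kernels = kernel_map(default = kernel("alpha", 2),
                                              self = kernel("single_exp", 1)))
  mf <- solve_hidden_rates(fx$spec, fx$part)
  grid <- frequency_grid(dt = 0.05, n_time = 64)
  gop <- transfer_operator(fx$spec, fx$part, mf, grid)
  nh <- length(fx$part$hidden)
  for (i in seq_along(grid$omegas)) {
    lhs <- (diag(1 + 0i, nh) - gop$v_matrices[[i]]) %*%
      gop$gamma_matrices[[i]]
    expect_lt(max(Mod(lhs - diag(mf$gains) + 0i)), 1e-8)
  }
  # Gamma(-omega) = Conj(Gamma(omega)): FFT index n+2-i holds -omega_i
  n <- grid$n_time
  for (i in c(2, 5, 20)) {
    expect_equal(gop$gamma_matrices[[n + 2 - i]],
                 Conj(gop$gamma_matrices[[i]]), tolerance = 1e-10)
  }
})

test_that("path series converges to the matrix inversion with the geometric bound", {
  for (seed in 1:6) {
    nh <- sample(3:6, 1)
    fx <- make_stable_spec(nh + 2, 2, seed = 100 + seed, sd = 0.3,
                           target_rho = 0.55)
    mf <- solve_hidden_rates(fx$spec, fx$part)
    gop <- transfer_operator(fx$spec, fx$part, mf, NULL)
    ps <- suppressWarnings(path_series(fx$spec, fx$part, mf, NULL,
                                       max_length = 14,
                                       max_path_count = 2000))
    err <- max(Mod(ps$gamma_approx[[1]] - gop$gamma_matrices[[1]]))
    expect_lt(err, ps$error_bound[1])
    # successive truncations shrink geometrically
    ps2 <- suppressWarnings(path_series(fx$spec, fx$part, mf, NULL,
                                        max_length = 7,
                                        max_path_count = 2000))
    err2 <- max(Mod(ps2$gamma_approx[[1]] - gop$gamma_matrices[[1]]))
    expect_lt(err, err2 + 1e-15)
  }
})

test_that("enumerated path contributions sum to the truncated matrix recursion", {
  fx <- make_stable_spec(7, 2, seed = 31, sd = 0.35, sparsity = 0.6,
                         kernels = kernel_map(default = kernel("alpha", 2),
                                              self = kernel("single_exp", 1)))
  # give one hidden neuron a self-coupling so node factors are exercised
  spec <- fx$spec
  spec$weights[5, 5] <- -0.4
  mf <- solve_hidden_rates(spec, fx$part)
  ps <- path_series(spec, fx$part, mf, NULL, max_length = 4)
  nh <- length(fx$part$hidden)
  G <- matrix(0i, nh, nh)
  for (p in ps$paths) {
    lcl <- p$local_nodes
    G[lcl[length(lcl)], lcl[1]] <- G[lcl[length(lcl)], lcl[1]] +
      p$contribution_zero
    # the closure agrees with the incrementally accumulated value
    expect_equal(p$contribution(0), p$contribution_zero, tolerance = 1e-12)
  }
  expect_equal(G, ps$gamma_approx[[1]], tolerance = 1e-10)
  expect_error(path_series(spec, fx$part, mf, NULL, max_length = 0),
               class = "hp_invalid_argument")
})

test_that("no immediate self-repeats appear in enumerated paths", {
  fx <- make_stable_spec(6, 1, seed = 41, sd = 0.3)
  spec <- fx$spec
  spec$weights[3, 3] <- -0.5 # self-loop must be factored, not walked
  mf <- solve_hidden_rates(spec, fx$part)
  ps <- path_series(spec, fx$part, mf, NULL, max_length = 3)
  for (p in ps$paths) {
    if (length(p$nodes) > 1) {
      expect_true(all(p$nodes[-1] != p$nodes[-length(p$nodes)]))
    }
  }
})

test_that("relabeling hidden indices permutes Gamma consistently", {
  fx <- make_stable_spec(7, 2, seed = 51)
  mf <- solve_hidden_rates(fx$spec, fx$part)
  G <- transfer_operator(fx$spec, fx$part, mf, NULL)$gamma_matrices[[1]]
  perm <- c(6L, 3L, 7L, 5L, 4L)
  part_p <- partition(recorded = fx$part$recorded, hidden = perm)
  mf_p <- solve_hidden_rates(fx$spec, part_p)
  G_p <- transfer_operator(fx$spec, part_p, mf_p, NULL)$gamma_matrices[[1]]
  pos <- match(perm, fx$part$hidden)
  expect_equal(G_p, G[pos, pos], tolerance = 1e-9)
})

test_that("stability report gives the closed-form small-circuit conditions", {
  circ <- ffi_circuit()
  mf <- solve_hidden_rates(circ$spec, circ$partition)
  rep1 <- stability_report(circ$spec, circ$partition, mf)
  expect_equal(rep1$one_hidden_margin, 1.9)
  expect_true(rep1$series_converges)
  c4 <- four_neuron_circuit()
  mf4 <- solve_hidden_rates(c4$spec, c4$partition)
  rep4 <- stability_report(c4$spec, c4$partition, mf4)
  expect_equal(rep4$loop_product, 0.81)
  expect_true(rep4$series_converges)
  # uncoupled hidden block: spectral radius 0
  spec0 <- network_spec(matrix(0, 3, 3), baselines = -1)
  part0 <- partition(hidden = 2:3, recorded = 1L)
  rep0 <- stability_report(spec0, part0, solve_hidden_rates(spec0, part0))
  expect_equal(rep0$spectral_radius_zero, 0)
})

test_that("a singular I - V(omega) raises the classed error", {
  # hand-built converged state with gains 1 and a unit-eigenvalue loop
  W <- matrix(c(0, 0.5, 2, 0), 2, 2)
  spec <- network_spec(W, baselines = 0,
                       kernels = kernel_map(default = kernel("delta")))
  part <- partition(hidden = 1:2, n_neurons = 2)
  mf <- structure(list(rates = c(1, 1), gains = c(1, 1), converged = TRUE,
                       iterations = 1L, residual = 0, hidden = 1:2),
                  class = "hp_meanfield")
  expect_error(transfer_operator(spec, part, mf, NULL),
               class = "hp_linear_response_singular")
})
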