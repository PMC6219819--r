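test_that("with no hidden neurons the effective model is the true recorded model", {
  fx <- make_stable_spec(5, 5, seed = 2)
  part <- partition(recorded = 1:5, hidden = integer(0), n_neurons = 5)
  grid <- frequency_grid(dt = 0.05, n_time = 128)
  em <- build_effective_model(fx$spec, part, grid)
  expect_equal(em$weights_eff, fx$spec$weights)
  expect_equal(em$baselines_eff, fx$spec$baselines)
  i0 <- which.min(abs(grid$omegas))
  expect_equal(em$filters_freq[, , i0], fx$spec$weights + 0i)
})

test_that("zero cross-blocks leave effective weights untouched; corrections scale linearly", {
  fx <- make_stable_spec(9, 3, seed = 13, sd = 0.3)
  r <- fx$part$recorded
  h <- fx$part$hidden
  mf <- solve_hidden_rates(fx$spec, fx$part)
  spec0 <- fx$spec
  spec0$weights[r, h] <- 0
  expect_equal(effective_weights(spec0, fx$part, mf),
               spec0$weights[r, r])
  # correction term is linear in J_RH and in J_HR at fixed Gamma
  base <- effective_weights(fx$spec, fx$part, mf) - fx$spec$weights[r, r]
  for (side in c("rh", "hr")) {
    spec_c <- fx$spec
    if (side == "rh") spec_c$weights[r, h] <- 3 * spec_c$weights[r, h]
    else spec_c$weights[h, r] <- 3 * spec_c$weights[h, r]
    corr <- effective_weights(spec_c, fx$part, mf) - fx$spec$weights[r, r]
    expect_equal(corr, 3 * base, tolerance = 1e-10)
  }
})

test_that("zero-frequency weights are independent of kernel shapes", {
  fx <- make_stable_spec(8, 3, seed = 17, sd = 0.3)
  mf <- solve_hidden_rates(fx$spec, fx$part)
  w_alpha <- effective_weights(fx$spec, fx$part, mf)
  spec_d <- fx$spec
  spec_d$kernels <- kernel_map(default = kernel("delta"))
  expect_equal(effective_weights(spec_d, fx$part, mf), w_alpha)
  spec_m <- fx$spec
  spec_m$kernels <- kernel_map(default = kernel("single_exp", 0.3),
                               per_neuron = list("5" = kernel("alpha", 7)))
  expect_equal(effective_weights(spec_m, fx$part, mf), w_alpha)
})

test_that("time-domain filters are real and integrate to the effective weights", {
  fx <- make_stable_spec(10, 3, seed = 19, sd = 0.25,
                         kernels = kernel_map(default = kernel("alpha", 2)))
  grid <- frequency_grid(dt = 0.02, n_time = 2048)
  em <- build_effective_model(fx$spec, fx$part, grid)
  expect_true(is.numeric(em$filters_time))
  quad <- apply(em$filters_time, c(1, 2), sum) * grid$dt
  expect_equal(quad, em$weights_eff, tolerance = 1e-6)
  mf <- solve_hidden_rates(fx$spec, fx$part)
  expect_equal(em$weights_eff, effective_weights(fx$spec, fx$part, mf),
               tolerance = 1e-10)
})

test_that("factorized frequency sweep equals the generic per-frequency solve", {
  set.seed(11)
  n <- 14
  J <- matrix(rnorm(n * n, 0, 0.15) * (runif(n * n) < 0.5), n, n)
  diag(J) <- 0
  spec <- network_spec(J, baselines = -1,
                       kernels = kernel_map(default = kernel("alpha", 10)))
  part <- partition(recorded = 1:4, hidden = 5:14)
  grid <- frequency_grid(dt = 0.02, n_time = 256)
  mf <- solve_hidden_rates(spec, part)
  em <- build_effective_model(spec, part, grid)
  gop <- transfer_operator(spec, part, mf, grid)
  ff_gen <- effective_coupling_freq(spec, part, mf, gop, grid)
  expect_lt(max(Mod(em$filters_freq - ff_gen)), 1e-12)
})

test_that("feedforward structure is preserved: no lateral or feedback effective couplings", {
  for (seed in c(3, 23)) {
    spec <- make_dag_spec(c(3, 4, 3, 2), seed = seed)
    n <- spec$n_neurons
    layer_of <- rep(1:4, c(3, 4, 3, 2))
    # record the first and last layers; middle layers hidden
    rec <- which(layer_of %in% c(1, 4))
    part <- partition(recorded = rec, n_neurons = n)
    mf <- solve_hidden_rates(spec, part)
    W <- effective_weights(spec, part, mf)
    lr <- layer_of[rec]
    for (a in seq_along(rec)) {
      for (b in seq_along(rec)) {
        # directed hidden paths exist only from layer 1 to layer 4
        if (!(lr[a] == 4 && lr[b] == 1)) {
          expect_identical(W[a, b], spec$weights[rec[a], rec[b]])
        }
      }
    }
    # layer-1 -> layer-4 entries do pick up hidden-path corrections
    expect_gt(max(abs((W - spec$weights[rec, rec])[lr == 4, lr == 1])), 0)
  }
})

test_that("recurrent random networks develop dense effective weights and self-interactions", {
  cfg <- ensemble_config(n_neurons = 250, seed = 4)
  spec <- er_mixed(cfg)
  part <- sample_partition(250, 4, seed = 9)
  mf <- solve_hidden_rates(spec, part)
  W <- effective_weights(spec, part, mf)
  J_RR <- block_weights(spec, part)$J_RR
  off <- row(W) != col(W)
  expect_lt(sum(J_RR[off] != 0), sum(off)) # the true block is sparse
  expect_identical(sum(abs(W[off]) > 1e-12), sum(off)) # the effective is not
  expect_true(all(abs(diag(W)) > 1e-12)) # emergent self-interactions
  expect_true(all(diag(J_RR) == 0))
})

test_that("the pipeline is deterministic: identical inputs give identical output", {
  fx <- make_stable_spec(8, 2, seed = 29)
  grid <- frequency_grid(dt = 0.05, n_time = 128)
  em1 <- build_effective_model(fx$spec, fx$part, grid)
  em2 <- build_effective_model(fx$spec, fx$part, grid)
  expect_identical(em1$weights_eff, em2$weights_eff)
  expect_identical(em1$filters_time, em2$filters_time)
})

test_that("to_time_domain is linear, maps zero to zero, and flags non-Hermitian input", {
  grid <- frequency_grid(dt = 0.02, n_time = 512)
  zero <- rep(0i, grid$n_time)
  expect_identical(to_time_domain(zero, grid), rep(0, grid$n_time))
  f1 <- kernel_freq(kernel("alpha", 3), 1.2, grid$omegas)
  f2 <- kernel_freq(kernel("single_exp", 2), -0.7, grid$omegas)
  lin <- to_time_domain(2 * f1 - 3 * f2, grid)
  expect_equal(lin, 2 * to_time_domain(f1, grid) - 3 * to_time_domain(f2, grid),
               tolerance = 1e-12)
  bad <- f1
  bad[5] <- bad[5] + 1 # breaks ghat(-w) = Conj(ghat(w))
  expect_warning(to_time_domain(bad, grid), class = "hp_non_hermitian")
  fixed <- suppressWarnings(to_time_domain(bad, grid))
  expect_true(is.numeric(fixed))
})

test_that("frequency grid pairs times and omegas consistently", {
  grid <- frequency_grid(dt = 0.25, n_time = 16)
  expect_equal(grid$times, seq(0, by = 0.25, length.out = 16))
  expect_equal(sort(grid$omegas)[9], 0)
  # every positive frequency has its negative partner (Nyquist excepted)
  pos <- grid$omegas[grid$omegas > 0 & abs(grid$omegas) < max(abs(grid$omegas))]
  expect_true(all(-pos %in% grid$omegas))
  expect_equal(diff(sort(grid$omegas))[1], 2 * pi / (16 * 0.25))
})

test_that("3-neuron effective coupling matches the symbolic path formula across frequency", {
  circ <- ffi_circuit()
  mf <- solve_hidden_rates(circ$spec, circ$partition)
  grid <- frequency_grid(dt = 0.1, n_time = 64)
  gop <- transfer_operator(circ$spec, circ$partition, mf, grid)
  ff <- effective_coupling_freq(circ$spec, circ$partition, mf, gop, grid)
  g3 <- mf$gains[1]
  for (i in seq_along(grid$omegas)) {
    om <- grid$omegas[i]
    j21 <- kernel_freq(kernel("alpha", 1), 1.0, om)
    j23 <- kernel_freq(kernel("alpha", 1), -2.0, om)
    j31 <- kernel_freq(kernel("alpha", 1.8), 2.0, om)
    j33 <- kernel_freq(kernel("single_exp", 1), -0.9, om)
    expect_equal(ff[2, 1, i], j21 + j23 * g3 * j31 / (1 - g3 * j33),
                 tolerance = 1e-10)
  }
})
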