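test_that("mean-field fixed points match closed-form and root-finding oracles", {
  # decoupled exponential network: nu = lambda0 exp(mu)
  spec <- network_spec(matrix(0, 3, 3), baselines = -1)
  mf <- solve_hidden_rates(spec, partition(hidden = 1:3, n_neurons = 3))
  expect_equal(mf$rates, rep(exp(-1), 3), tolerance = 1e-9)
  expect_equal(mf$gains, mf$rates) # exponential: gamma = nu exactly

  # one rectified-linear hidden neuron with refractory self-coupling:
  # nu = lambda0 mu / (1 - lambda0 J_self)
  spec_r <- network_spec(matrix(-0.9, 1, 1), baselines = 0.95,
                         nonlinearity = nonlinearity("rectified_linear"))
  mf_r <- solve_hidden_rates(spec_r, partition(hidden = 1L, n_neurons = 1))
  expect_equal(mf_r$rates, 0.95 / 1.9, tolerance = 1e-9)
  expect_equal(mf_r$gains, 1)

  # one exponential neuron with positive self-coupling: bisection oracle
  spec_e <- network_spec(matrix(0.5, 1, 1), baselines = -1)
  mf_e <- solve_hidden_rates(spec_e, partition(hidden = 1L, n_neurons = 1))
  oracle <- uniroot(function(x) x - exp(-1 + 0.5 * x), c(0, 1),
                    tol = 1e-13)$root
  expect_equal(mf_e$rates, oracle, tolerance = 1e-8)
})

test_that("converged states satisfy the fixed-point residual and ignore recorded neurons", {
  for (seed in 1:4) {
    fx <- make_stable_spec(9, 3, seed = seed, sd = 0.3)
    mf <- solve_hidden_rates(fx$spec, fx$part)
    h <- fx$part$hidden
    arg <- fx$spec$baselines[h] +
      drop(fx$spec$weights[h, h] %*% mf$rates)
    expect_lt(max(abs(mf$rates - exp(arg))), 1e-9)
    expect_true(all(mf$rates >= 0))
    # recorded block plays no role: scrambling it leaves the solution fixed
    spec2 <- fx$spec
    spec2$weights[fx$part$recorded, ] <- 99
    mf2 <- solve_hidden_rates(spec2, fx$part)
    expect_identical(mf2$rates, mf$rates)
  }
})

test_that("solver is equivariant under hidden-index reordering", {
  fx <- make_stable_spec(8, 2, seed = 11)
  mf <- solve_hidden_rates(fx$spec, fx$part)
  perm <- c(5L, 8L, 3L, 7L, 4L, 6L)
  part_p <- partition(recorded = fx$part$recorded, hidden = perm)
  mf_p <- solve_hidden_rates(fx$spec, part_p)
  expect_equal(mf_p$rates, mf$rates[match(perm, fx$part$hidden)],
               tolerance = 1e-12)
})

test_that("divergent hidden networks raise a catchable classed error", {
  spec <- network_spec(matrix(c(0, 2, 2, 0), 2, 2), baselines = 0.5)
  expect_error(solve_hidden_rates(spec, partition(hidden = 1:2, n_neurons = 2)),
               class = "hp_hidden_network_unstable")
  caught <- tryCatch(
    solve_hidden_rates(spec, partition(hidden = 1:2, n_neurons = 2)),
    hp_hidden_network_unstable = function(e) "skipped")
  expect_identical(caught, "skipped")
})

test_that("bounded sigmoid nonlinearity never diverges: rates below the ceiling", {
  set.seed(3)
  J <- matrix(abs(rnorm(36, 0, 1)), 6, 6) # strongly excitatory
  diag(J) <- 0
  spec <- network_spec(J, baselines = 1,
                       nonlinearity = nonlinearity("sigmoid", ceiling = 2))
  mf <- solve_hidden_rates(spec, partition(hidden = 1:6, n_neurons = 6))
  expect_true(mf$converged)
  expect_true(all(mf$rates <= 2 * spec$rate_scale))
})

test_that("rate-series coefficients match the printed recursion", {
  # a0 = 1 everywhere; a1 = row sums; a2 on a 2-neuron example
  J <- matrix(0, 2, 2)
  J[1, 2] <- 0.5
  J[2, 1] <- -0.3
  spec <- network_spec(J, baselines = -1.3)
  part <- partition(hidden = 1:2, n_neurons = 2)
  sr <- series_rates(spec, part, order = 2)
  expect_equal(sr$coefficients[, 1], c(1, 1))
  expect_equal(sr$coefficients[, 2], c(0.5, -0.3))
  # a2_1 = J12 J21 + 0.5 J12^2
  expect_equal(sr$coefficients[1, 3], 0.5 * (-0.3) + 0.5 * 0.25)
  expect_equal(sr$coefficients[2, 3], -0.3 * 0.5 + 0.5 * 0.09)
  expect_error(series_rates(spec, part, order = 4),
               class = "hp_invalid_argument")
  spec_r <- network_spec(J, baselines = -1,
                         nonlinearity = nonlinearity("rectified_linear"))
  expect_error(series_rates(spec_r, part),
               class = "hp_unsupported_nonlinearity")
})

test_that("series residual scales as O(eps^5): halving eps shrinks it ~32x", {
  set.seed(5)
  nh <- 8
  J <- matrix(rnorm(nh * nh, 0, 0.25), nh, nh)
  diag(J) <- 0
  J <- J * 0.9 / max(Mod(eigen(J, only.values = TRUE)$values))
  part <- partition(hidden = seq_len(nh), n_neurons = nh)
  resid <- vapply(c(-2, -2 - log(2)), function(mu0) {
    spec <- network_spec(J, baselines = mu0)
    mf <- solve_hidden_rates(spec, part)
    sr <- series_rates(spec, part, order = 3)
    max(abs(mf$rates - sr$rates))
  }, numeric(1))
  factor <- resid[1] / resid[2]
  expect_gt(factor, 16)
  expect_lt(factor, 64)
})

test_that("heterogeneous-baseline series matches the solver at second order", {
  set.seed(9)
  nh <- 5
  J <- matrix(rnorm(nh * nh, 0, 0.2), nh, nh)
  diag(J) <- 0
  part <- partition(hidden = seq_len(nh), n_neurons = nh)
  mus <- c(-3.1, -2.8, -3.4, -3.0, -2.9)
  spec <- network_spec(J, baselines = mus)
  mf <- solve_hidden_rates(spec, part)
  sr <- series_rates(spec, part, order = 2)
  expect_lt(max(abs(mf$rates - sr$rates)), 10 * max(exp(mus))^4)
  expect_error(series_rates(spec, part, order = 3),
               class = "hp_invalid_argument")
})

test_that("effective baselines shift by the net tonic hidden input", {
  fx <- make_stable_spec(7, 3, seed = 21)
  mf <- solve_hidden_rates(fx$spec, fx$part)
  r <- fx$part$recorded
  h <- fx$part$hidden
  mueff <- effective_baselines(fx$spec, fx$part, mf)
  expect_equal(mueff,
               fx$spec$baselines[r] + drop(fx$spec$weights[r, h] %*% mf$rates))
  # J_RH = 0 leaves baselines untouched
  spec0 <- fx$spec
  spec0$weights[r, h] <- 0
  expect_equal(effective_baselines(spec0, fx$part, mf),
               fx$spec$baselines[r])
  # doubling J_RH doubles the shift
  spec2 <- fx$spec
  spec2$weights[r, h] <- 2 * spec2$weights[r, h]
  expect_equal(effective_baselines(spec2, fx$part, mf) - fx$spec$baselines[r],
               2 * (mueff - fx$spec$baselines[r]))
})
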