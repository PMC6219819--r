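# Random network with a stable hidden block: weights scaled so the hidden
# transfer operator at zero frequency has spectral radius target_rho < 1.
make_stable_spec <- function(n, n_rec, seed, sd = 0.2, sparsity = 1,
                             baselines = -1, target_rho = 0.6,
                             kernels = kernel_map(default = kernel("alpha", 2)),
                             nl = nonlinearity("exponential")) {
  set.seed(seed)
  J <- matrix(rnorm(n * n, 0, sd), n, n)
  if (sparsity < 1) J <- J * (matrix(runif(n * n), n, n) < sparsity)
  diag(J) <- 0
  spec <- network_spec(J, baselines = baselines, nonlinearity = nl,
                       kernels = kernels)
  hid <- if (n_rec < n) seq(n_rec + 1, n) else integer(0)
  part <- partition(recorded = seq_len(n_rec), hidden = hid, n_neurons = n)
  if (length(hid) == 0L) return(list(spec = spec, part = part))
  mf <- solve_hidden_rates(spec, part)
  rho <- max(Mod(eigen(mf$gains * spec$weights[part$hidden, part$hidden],
                       only.values = TRUE)$values))
  if (rho > target_rho) {
    J <- J * (target_rho / rho)
    spec <- network_spec(J, baselines = baselines, nonlinearity = nl,
                         kernels = kernels)
  }
  list(spec = spec, part = part)
}

# A layered feedforward DAG spec: edges only from layer l to layer l+1.
make_dag_spec <- function(layer_sizes, seed, sd = 0.4,
                          nl = nonlinearity("exponential")) {
  set.seed(seed)
  n <- sum(layer_sizes)
  layer_of <- rep(seq_along(layer_sizes), layer_sizes)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (layer_of[i] == layer_of[j] + 1L) J[i, j] <- rnorm(1, 0, sd)
    }
  }
  network_spec(J, baselines = -1, nonlinearity = nl,
               kernels = kernel_map(default = kernel("delta")))
}
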