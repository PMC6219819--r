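#' Network ensemble configuration
#'
#' Parameter bundle for the random-network generators. Nonzero synaptic
#' weights have standard deviation \eqn{J_0/(pN)^a}: the exponent
#' \eqn{a = 1/2} is "strong" (balanced) coupling, under which hidden-path
#' corrections to effective weights stay O(1) as \eqn{N} grows, while
#' \eqn{a = 1} is classical "weak" coupling. Self-coupling weights are zero.
#'
#' Defaults reproduce the standard large-network study conditions: N = 1000
#' neurons, sparsity p = 0.2, homogeneous baselines \eqn{\mu_0 = -1}, rate
#' scale \eqn{\lambda_0 = 1}, exponential nonlinearity, coupling scale
#' \eqn{J_0 = 1}, Watts-Strogatz rewiring fraction \eqn{\beta = 0.3}.
#'
#' @param n_neurons network size N.
#' @param sparsity connection probability p in (0, 1].
#' @param coupling_scale characteristic weight scale \eqn{J_0}.
#' @param scaling_exponent 1/2 (strong) or 1 (weak).
#' @param architecture `"er_mixed"`, `"er_dale"`, or `"watts_strogatz"`.
#' @param rewiring Watts-Strogatz rewiring fraction \eqn{\beta}.
#' @param baseline homogeneous tonic drive \eqn{\mu_0}.
#' @param rate_scale \eqn{\lambda_0}.
#' @param nonlinearity a [nonlinearity()] object.
#' @param kernels a [kernel_map()] attached to generated specs; the default
#'   alpha-10 kernel matches the standard filter choice (zero-frequency
#'   statistics are kernel-independent).
#' @param seed integer RNG seed.
#' @return list of class `"hp_ensemble_config"`.
#' @export
ensemble_config <- function(n_neurons = 1000, sparsity = 0.2,
                            coupling_scale = 1.0, scaling_exponent = 1 / 2,
                            architecture = c("er_mixed", "er_dale",
                                             "watts_strogatz"),
                            rewiring = 0.3, baseline = -1, rate_scale = 1,
                            nonlinearity = hiddenpaths::nonlinearity("exponential"),
                            kernels = kernel_map(default = kernel("alpha", 10)),
                            seed = 1L) {
  architecture <- match.arg(architecture)
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity > 1) {
    stop_hp("invalid_config", "sparsity must be in [0, 1]")
  }
  if (!is.numeric(n_neurons) || n_neurons < 2) {
    stop_hp("invalid_config", "n_neurons must be >= 2")
  }
  if (!scaling_exponent %in% c(1 / 2, 1)) {
    stop_hp("invalid_config", "scaling_exponent must be 1/2 or 1")
  }
  if (rewiring < 0 || rewiring > 1) {
    stop_hp("invalid_config", "rewiring must be in [0, 1]")
  }
  structure(list(n_neurons = as.integer(n_neurons), sparsity = sparsity,
                 coupling_scale = coupling_scale,
                 scaling_exponent = scaling_exponent,
                 architecture = architecture, rewiring = rewiring,
                 baseline = baseline, rate_scale = rate_scale,
                 nonlinearity = nonlinearity, kernels = kernels,
                 seed = as.integer(seed)),
            class = "hp_ensemble_config")
}

weight_sd <- function(config) {
  if (config$sparsity == 0) return(0)
  config$coupling_scale /
    (config$sparsity * config$n_neurons)^config$scaling_exponent
}

.config_spec <- function(config, weights) {
  network_spec(weights, baselines = config$baseline,
               rate_scale = config$rate_scale,
               nonlinearity = config$nonlinearity, kernels = config$kernels)
}

#' Erdos-Renyi network with mixed synapses
#'
#' Each off-diagonal entry is independently nonzero with probability p, with
#' nonzero weights drawn Normal(0, \eqn{J_0^2/(pN)^{2a}}); no sign constraint
#' ("mixed synapses": one neuron may make both excitatory and inhibitory
#' connections). Diagonal is zero. Bit-reproducible from `config$seed`.
#'
#' @param config an [ensemble_config()].
#' @return a [network_spec()].
#' @export
er_mixed <- function(config) {
  stopifnot(inherits(config, "hp_ensemble_config"))
  n <- config$n_neurons
  sd0 <- weight_sd(config)
  W <- with_seed(config$seed, {
    mask <- matrix(stats::runif(n * n) < config$sparsity, n, n)
    vals <- matrix(stats::rnorm(n * n, 0, sd0), n, n)
    mask * vals
  })
  diag(W) <- 0
  .config_spec(config, W)
}

#' Erdos-Renyi network obeying Dale's law
#'
#' Same connectivity and weight-magnitude statistics as [er_mixed()], but
#' each neuron is labeled excitatory or inhibitory (independently, with
#' probability 1/2 each) and all its outgoing weights take the label's sign:
#' nonzero magnitudes are half-normal with scale \eqn{J_0/(pN)^a}, so the
#' overall weight distribution matches the mixed-synapse normal up to the
#' sign assignment.
#'
#' @param config an [ensemble_config()].
#' @param force_labels optional character vector of `"E"`/`"I"` labels (test
#'   hook overriding the random assignment).
#' @return a [network_spec()] with a `neuron_types` attribute.
#' @export
er_dale <- function(config, force_labels = NULL) {
  stopifnot(inherits(config, "hp_ensemble_config"))
  n <- config$n_neurons
  sd0 <- weight_sd(config)
  res <- with_seed(config$seed, {
    labels <- if (is.null(force_labels)) {
      ifelse(stats::runif(n) < 0.5, "E", "I")
    } else {
      stopifnot(length(force_labels) == n, all(force_labels %in% c("E", "I")))
      force_labels
    }
    mask <- matrix(stats::runif(n * n) < config$sparsity, n, n)
    mags <- matrix(abs(stats::rnorm(n * n, 0, sd0)), n, n)
    list(labels = labels, W = mask * mags)
  })
  signs <- ifelse(res$labels == "E", 1, -1)
  W <- sweep(res$W, 2, signs, `*`) # column sign = presynaptic type
  diag(W) <- 0
  spec <- .config_spec(config, W)
  attr(spec, "neuron_types") <- res$labels
  spec
}

#' Watts-Strogatz small-world network with mixed synapses
#'
#' Topology: a ring of N nodes each connected to its pN nearest neighbors
#' (pN/2 per side); each lattice edge is then visited once and, with
#' probability \eqn{\beta}, detached from its clockwise endpoint and
#' reattached to a uniformly random non-duplicate, non-self target (the
#' classic small-world rewiring, which preserves the edge count). Each
#' undirected edge is expanded into two directed edges carrying independent
#' Normal(0, \eqn{J_0^2/(pN)^{2a}}) weights, as in the mixed-synapse ER
#' network.
#'
#' @param config an [ensemble_config()]; `sparsity * n_neurons` must be an
#'   even integer >= 2.
#' @return a [network_spec()].
#' @export
watts_strogatz <- function(config) {
  stopifnot(inherits(config, "hp_ensemble_config"))
  n <- config$n_neurons
  k <- config$sparsity * n
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 0 || k < 2) {
    stop_hp("invalid_config",
            sprintf(paste0("sparsity * n_neurons = %g must be an even integer",
                           " >= 2 (each node links to pN/2 neighbors per side);",
                           " adjust sparsity or n_neurons"), k))
  }
  sd0 <- weight_sd(config)
  k2 <- round(k) / 2
  W <- with_seed(config$seed, {
    A <- matrix(FALSE, n, n)
    for (d in seq_len(k2)) {
      i <- seq_len(n)
      j <- (i - 1 + d) %% n + 1
      A[cbind(i, j)] <- TRUE
      A[cbind(j, i)] <- TRUE
    }
    if (config$rewiring > 0) {
      for (i in seq_len(n)) {
        for (d in seq_len(k2)) {
          j <- (i - 1 + d) %% n + 1
          if (A[i, j] && stats::runif(1) < config$rewiring) {
            candidates <- which(!A[i, ] & seq_len(n) != i)
            if (length(candidates) > 0) {
              w <- candidates[sample.int(length(candidates), 1)]
              A[i, j] <- A[j, i] <- FALSE
              A[i, w] <- A[w, i] <- TRUE
            }
          }
        }
      }
    }
    vals <- matrix(stats::rnorm(n * n, 0, sd0), n, n)
    A * vals
  })
  diag(W) <- 0
  .config_spec(config, W)
}

#' Sample a random recorded/hidden partition
#'
#' Permutes the neuron indices with the given seed and records the last
#' `n_recorded` indices of the permutation; the rest are hidden.
#'
#' @param n_neurons total neuron count.
#' @param n_recorded number of recorded neurons (0..N).
#' @param seed integer seed.
#' @return a [partition()].
#' @export
sample_partition <- function(n_neurons, n_recorded, seed) {
  if (n_recorded < 0 || n_recorded > n_neurons) {
    stop_hp("invalid_argument", "n_recorded must be in [0, n_neurons]")
  }
  perm <- with_seed(seed, sample.int(n_neurons))
  rec <- if (n_recorded > 0) {
    perm[(n_neurons - n_recorded + 1L):n_neurons]
  } else {
    integer(0)
  }
  hid <- if (n_recorded < n_neurons) perm[seq_len(n_neurons - n_recorded)]
         else integer(0)
  partition(recorded = rec, hidden = hid, n_neurons = n_neurons)
}

generate_network <- function(config) {
  switch(config$architecture,
         er_mixed = er_mixed(config),
         er_dale = er_dale(config),
         watts_strogatz = watts_strogatz(config))
}
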