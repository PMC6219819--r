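#' Discrete-time simulation of the full spiking network
#'
#' Generative Bernoulli-thinning simulation of the nonlinear Hawkes network:
#' in each bin of width `dt`, neuron i spikes independently with probability
#' \eqn{\min(\lambda_i(t)\,dt, 1)}, where
#' \eqn{\lambda_i(t) = \lambda_0\phi(\mu_i + \sum_j J_{ij}\,(g_j * \dot n_j)(t))}
#' and the convolution runs over all past spikes. Synaptic filtering is
#' implemented with exact exponential-integrator state updates (alpha kernels
#' as critically damped second-order filters, single-exponential kernels as
#' first-order filters), so the filtered input equals the kernel sampled at
#' the exact elapsed bin times; delta kernels act with a one-bin lag
#' (weight spread as `J/dt` over the following bin). Spikes in bin t affect
#' rates from bin t+1 onward; history before t = 0 is empty.
#'
#' @param spec a [network_spec()].
#' @param duration simulated time span (after which simulation stops).
#' @param dt bin width; a warning is issued if max observed
#'   \eqn{\lambda\,dt > 0.2}.
#' @param seed integer RNG seed.
#' @param burn_in initial time span whose bins are flagged for discarding in
#'   rate estimates (default 10% of duration).
#' @param forced_spikes optional 2-column matrix (neuron, time) of spikes
#'   injected deterministically (probe input for impulse-response checks).
#' @param return_rates if `TRUE`, also store the per-bin rate array (memory:
#'   neurons x bins doubles).
#' @return object of class `"hp_spike_record"`: `spikes` (neurons x bins
#'   integer 0/1 matrix), `dt`, `n_bins`, `seed`, `burn_in_bins`, `max_lambda_dt`,
#'   and optionally `rates`.
#' @export
simulate_spikes <- function(spec, duration, dt = 0.01, seed = 1L,
                            burn_in = duration * 0.1, forced_spikes = NULL,
                            return_rates = FALSE) {
  stopifnot(is_network_spec(spec), duration > 0, dt > 0)
  n <- spec$n_neurons
  n_bins <- as.integer(floor(duration / dt))
  lam0 <- spec$rate_scale
  mu <- spec$baselines
  nl <- spec$nonlinearity

  groups <- .kernel_groups(spec)
  # per-group filter state
  st <- lapply(groups, function(g) {
    switch(g$kernel$family,
      alpha = list(u = numeric(n), v = numeric(n)),
      single_exp = list(u = numeric(n)),
      delta = list(u = numeric(n)))
  })
  forced <- matrix(numeric(0), 0, 2)
  if (!is.null(forced_spikes)) {
    forced <- cbind(as.numeric(forced_spikes[, 1]),
                    floor(as.numeric(forced_spikes[, 2]) / dt))
  }

  spikes <- matrix(0L, n, n_bins)
  rates <- if (return_rates) matrix(0, n, n_bins) else NULL
  max_ldt <- 0
  overflow_run <- 0L
  set.seed(seed)
  for (t in seq_len(n_bins)) {
    input <- mu
    for (gi in seq_along(groups)) input <- input + st[[gi]]$u
    lam <- lam0 * apply_nonlinearity(nl, input)
    if (return_rates) rates[, t] <- lam
    ldt <- lam * dt
    m <- max(ldt)
    if (m > max_ldt) max_ldt <- m
    if (m > 1) {
      overflow_run <- overflow_run + 1L
      if (overflow_run > 10L) {
        stop_hp("simulation_unstable",
                sprintf("firing probability exceeded 1 persistently from t = %.4g",
                        (t - 10L) * dt),
                time = (t - 10L) * dt)
      }
    } else {
      overflow_run <- 0L
    }
    s <- as.integer(stats::runif(n) < pmin(ldt, 1))
    if (nrow(forced) > 0) {
      here <- forced[forced[, 2] == (t - 1L), 1]
      if (length(here)) s[here] <- 1L
    }
    spikes[, t] <- s
    # inject this bin's spikes at zero elapsed time, then propagate all
    # states over dt, so bin t+1 sees each kernel sampled at elapsed dt
    fired <- which(s == 1L)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      fam <- g$kernel$family
      if (fam == "alpha") {
        a <- g$kernel$rate_param
        e <- exp(-a * dt)
        if (length(fired)) {
          st[[gi]]$v <- st[[gi]]$v +
            a^2 * rowSums(g$W[, fired, drop = FALSE])
        }
        st[[gi]]$u <- e * (st[[gi]]$u + dt * st[[gi]]$v)
        st[[gi]]$v <- e * st[[gi]]$v
      } else if (fam == "single_exp") {
        b <- g$kernel$rate_param
        if (length(fired)) {
          st[[gi]]$u <- st[[gi]]$u +
            b * rowSums(g$W[, fired, drop = FALSE])
        }
        st[[gi]]$u <- exp(-b * dt) * st[[gi]]$u
      } else { # delta: active for exactly the next bin
        st[[gi]]$u <- numeric(n)
        if (length(fired)) {
          st[[gi]]$u <- rowSums(g$W[, fired, drop = FALSE]) / dt
        }
      }
    }
  }
  if (max_ldt > 0.2) {
    warn_hp("coarse_dt",
            sprintf("max lambda*dt = %.3g > 0.2; consider a smaller dt",
                    max_ldt))
  }
  structure(list(spikes = spikes, dt = dt, n_bins = n_bins,
                 seed = as.integer(seed),
                 burn_in_bins = as.integer(floor(burn_in / dt)),
                 max_lambda_dt = max_ldt, rates = rates),
            class = "hp_spike_record")
}

# Partition the weight matrix into groups sharing one resolved kernel, so the
# simulator keeps one linear filter state per kernel.
.kernel_groups <- function(spec) {
  n <- spec$n_neurons
  keys <- character(0)
  gid <- matrix(NA_integer_, n, n)
  kers <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (spec$weights[i, j] != 0) {
        k <- resolve_kernel(spec$kernels, i, j)
        key <- paste(k$family, k$rate_param)
        pos <- match(key, keys)
        if (is.na(pos)) {
          keys <- c(keys, key)
          kers[[length(keys)]] <- k
          pos <- length(keys)
        }
        gid[i, j] <- pos
      }
    }
  }
  lapply(seq_along(keys), function(p) {
    W <- spec$weights * (gid == p & !is.na(gid))
    W[is.na(W)] <- 0
    list(kernel = kers[[p]], W = W)
  })
}

#' @export
print.hp_spike_record <- function(x, ...) {
  cat(sprintf("<spike_record: %d neurons x %d bins (dt = %g), %d spikes, max lambda*dt = %.3g>\n",
              nrow(x$spikes), x$n_bins, x$dt, sum(x$spikes), x$max_lambda_dt))
  invisible(x)
}

#' Empirical firing rates from a spike record
#'
#' Rates are spike counts after burn-in divided by the effective duration;
#' the standard error is the Poisson estimate \eqn{\sqrt{\nu/T}}.
#'
#' @param record an [simulate_spikes()] result.
#' @return data frame with `neuron`, `rate`, `se`.
#' @export
empirical_rates <- function(record) {
  stopifnot(inherits(record, "hp_spike_record"))
  keep <- seq_len(record$n_bins) > record$burn_in_bins
  if (!any(keep)) {
    stop_hp("invalid_argument", "record has no bins after burn-in")
  }
  T_eff <- sum(keep) * record$dt
  counts <- rowSums(record$spikes[, keep, drop = FALSE])
  rate <- counts / T_eff
  data.frame(neuron = seq_len(nrow(record$spikes)), rate = rate,
             se = sqrt(rate / T_eff))
}
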