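#' Off-diagonal sample statistics of effective-vs-true weight differences
#'
#' Sample mean and variance of \eqn{\mathcal{J}^{\rm eff}_{r,r'} - J_{r,r'}}
#' over ordered recorded pairs \eqn{r \neq r'}; diagonal entries are excluded
#' because zero true self-couplings give them different statistics. The
#' denominators are \eqn{N_{\rm rec}(N_{\rm rec}-1)} for the mean and
#' \eqn{N_{\rm rec}(N_{\rm rec}-1) - 1} for the variance.
#'
#' @param eff_weights,true_weights square matrices over the same recorded
#'   set (dimension >= 2).
#' @return list with `mean` and `variance`.
#' @export
sample_stats <- function(eff_weights, true_weights) {
  eff_weights <- as.matrix(eff_weights)
  true_weights <- as.matrix(true_weights)
  if (!all(dim(eff_weights) == dim(true_weights)) ||
      nrow(eff_weights) != ncol(eff_weights) || nrow(eff_weights) < 2) {
    stop_hp("invalid_argument",
            "matrices must be square, same shape, dimension >= 2")
  }
  d <- eff_weights - true_weights
  off <- d[row(d) != col(d)]
  m <- sum(off) / length(off)
  v <- sum((off - m)^2) / (length(off) - 1L)
  list(mean = m, variance = v)
}

# off-diagonal sample sd
offdiag_sd <- function(m) {
  off <- m[row(m) != col(m)]
  stats::sd(off)
}

#' Ensemble deviation statistics of effective vs true synaptic weights
#'
#' The large-network subsampling experiment: for each of `n_networks` network
#' draws and each of `n_subsets` random recorded subsets per size in
#' `recorded_counts`, solve the hidden mean field, compute the
#' zero-frequency effective weights, and record the ratio
#' \eqn{\sigma[\mathcal{J}^{\rm eff} - J] / \sigma[J]} over off-diagonal
#' recorded pairs. Ratios are averaged first across subsets (their standard
#' error giving the error bar), then across network draws. Hidden
#' subnetworks whose mean field diverges (possible under Dale's law with an
#' unbounded nonlinearity) are skipped and counted.
#'
#' @param config an [ensemble_config()].
#' @param recorded_counts vector of recorded-set sizes (each in 1..N-1).
#' @param n_subsets random subsets per network draw.
#' @param n_networks independent network draws.
#' @param seed integer seed for the whole experiment (network and subset
#'   seeds are derived deterministically from it).
#' @return data frame of class `"hp_deviation_summary"` with one row per
#'   recorded count: `architecture`, `scaling_exponent`, `j0`, `n_recorded`,
#'   `f`, `ratio`, `ratio_se`, `n_used`, `n_skipped`, plus analytic overlay
#'   columns `analytic_strong` ([analytic_ratio_strong()]) and
#'   `analytic_sd_ratio` (difference form of [analytic_var_ratio()]).
#' @export
deviation_experiment <- function(config, recorded_counts, n_subsets = 10,
                                 n_networks = 3, seed = 1L) {
  stopifnot(inherits(config, "hp_ensemble_config"))
  N <- config$n_neurons
  if (any(recorded_counts < 1 | recorded_counts > N - 1)) {
    stop_hp("invalid_argument", "recorded_counts must lie in 1..N-1")
  }
  rows <- vector("list", length(recorded_counts))
  for (ci in seq_along(recorded_counts)) {
    nrec <- recorded_counts[ci]
    per_network_mean <- numeric(0)
    per_network_se <- numeric(0)
    used <- 0L
    skipped <- 0L
    for (net in seq_len(n_networks)) {
      cfg <- config
      cfg$seed <- derive_seed(seed, 101, net)
      spec <- generate_network(cfg)
      ratios <- numeric(0)
      for (sub in seq_len(n_subsets)) {
        part <- sample_partition(N, nrec, derive_seed(seed, 202, net, ci, sub))
        mf <- tryCatch(solve_hidden_rates(spec, part),
                       hp_hidden_network_unstable = function(e) NULL)
        if (is.null(mf)) {
          skipped <- skipped + 1L
          next
        }
        eff <- effective_weights(spec, part, mf)
        JRR <- block_weights(spec, part)$J_RR
        sd_true <- offdiag_sd(JRR)
        ss <- sample_stats(eff, JRR)
        if (sd_true == 0) {
          # no nonzero true weights in this subset: the ratio is 0 when the
          # hidden contribution also vanishes, otherwise undefined (skip)
          if (sqrt(ss$variance) < 1e-12) {
            ratios <- c(ratios, 0)
            used <- used + 1L
          }
          next
        }
        ratios <- c(ratios, sqrt(ss$variance) / sd_true)
        used <- used + 1L
      }
      if (length(ratios) > 0) {
        per_network_mean <- c(per_network_mean, mean(ratios))
        per_network_se <- c(per_network_se,
                            stats::sd(ratios) / sqrt(length(ratios)))
      }
    }
    f <- nrec / N
    rows[[ci]] <- data.frame(
      architecture = config$architecture,
      scaling_exponent = config$scaling_exponent,
      j0 = config$coupling_scale, n_recorded = nrec, f = f,
      ratio = if (length(per_network_mean)) mean(per_network_mean) else NA_real_,
      ratio_se = if (length(per_network_se)) mean(per_network_se) else NA_real_,
      n_used = used, n_skipped = skipped,
      analytic_strong = analytic_ratio_strong(config$coupling_scale, f,
                                              config$baseline,
                                              config$rate_scale),
      analytic_sd_ratio = sqrt(pmax(
        analytic_var_ratio(config$coupling_scale, f, config$sparsity, N,
                           config$scaling_exponent, config$baseline,
                           config$rate_scale) - 1, 0)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hp_deviation_summary", class(out))
  out
}

#' Analytic strong-coupling deviation ratio (length-3 path truncation)
#'
#' Closed-form prediction for
#' \eqn{\sigma[\mathcal{J}^{\rm eff} - J]/\sigma[J]} in strongly coupled
#' (\eqn{a = 1/2}) ER mixed-synapse networks with exponential nonlinearity,
#' truncated at hidden paths of length 3:
#' \deqn{\lambda_0 J_0 e^{\mu_0}\sqrt{1-f}\,
#'   \left(1 + \tfrac{3}{2}(\lambda_0 J_0 e^{\mu_0})^2 (1-f)\right).}
#' Depends only on the recorded fraction f, not on N: hidden-path
#' contributions survive the large-network limit under strong coupling.
#'
#' @param J0 coupling scale.
#' @param f recorded fraction in [0, 1] (vectorized).
#' @param mu0 homogeneous baseline.
#' @param lambda0 rate scale.
#' @return predicted ratio(s).
#' @export
analytic_ratio_strong <- function(J0, f, mu0 = -1, lambda0 = 1) {
  stopifnot(all(f >= 0 & f <= 1))
  x <- lambda0 * J0 * exp(mu0)
  x * sqrt(1 - f) * (1 + 1.5 * x^2 * (1 - f))
}

#' Analytic variance ratio of effective to true weights
#'
#' Finite-N prediction
#' \deqn{\frac{{\rm var}[\mathcal{J}^{\rm eff}]}{{\rm var}[J]} = 1 +
#'   N_{\rm hid}\,{\rm var}[J]\left[(\lambda_0\epsilon)^2 +
#'   (\lambda_0\epsilon)^4\left(3 - \tfrac{3}{N_{\rm hid}}\right)
#'   N_{\rm hid}\,{\rm var}[J]\right]}
#' with \eqn{\epsilon = e^{\mu_0}}, \eqn{{\rm var}[J] = p J_0^2/(pN)^{2a}}
#' and \eqn{N_{\rm hid} = (1-f)N}. At \eqn{a = 1/2} and \eqn{N \to \infty}
#' this reduces to
#' \eqn{1 + (\lambda_0 J_0\epsilon)^2(1-f) + 3(\lambda_0 J_0\epsilon)^4(1-f)^2};
#' at \eqn{a = 1} the excess over 1 scales as \eqn{1/(pN)}, so hidden paths
#' are negligible in large weakly coupled networks.
#'
#' @param J0 coupling scale.
#' @param f recorded fraction (vectorized).
#' @param p sparsity.
#' @param N network size.
#' @param a scaling exponent (1/2 or 1).
#' @param mu0 homogeneous baseline.
#' @param lambda0 rate scale.
#' @return predicted variance ratio(s) (>= 1).
#' @export
analytic_var_ratio <- function(J0, f, p, N, a = 1 / 2, mu0 = -1,
                               lambda0 = 1) {
  stopifnot(all(f >= 0 & f <= 1))
  eps <- exp(mu0)
  varJ <- p * J0^2 / (p * N)^(2 * a)
  nhid <- (1 - f) * N
  le <- lambda0 * eps
  ifelse(nhid == 0, 1,
         1 + nhid * varJ * (le^2 + le^4 * (3 - 3 / nhid) * nhid * varJ))
}
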