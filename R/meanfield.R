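#' Mean-field solver configuration
#'
#' @param tolerance max-norm fixed-point residual required for convergence.
#' @param damping step size \eqn{\eta} of the damped iteration
#'   \eqn{\nu \leftarrow (1-\eta)\nu + \eta\,\lambda_0\phi(\mu + J_{HH}\nu)};
#'   values below 1 stabilize oscillatory iterations.
#' @param max_iterations iteration cap before declaring non-convergence.
#' @param divergence_cap rates above `divergence_cap * rate_scale` abort the
#'   iteration as unstable.
#' @return list of solver settings.
#' @export
meanfield_control <- function(tolerance = 1e-10, damping = 0.5,
                              max_iterations = 10000, divergence_cap = 1e6) {
  stopifnot(tolerance > 0, damping > 0, damping <= 1, max_iterations >= 1,
            divergence_cap > 0)
  list(tolerance = tolerance, damping = damping,
       max_iterations = as.integer(max_iterations),
       divergence_cap = divergence_cap)
}

#' Steady-state mean-field rates and gains of the hidden subnetwork
#'
#' Solves the self-consistent mean-field equations
#' \deqn{\nu_h = \lambda_0 \phi(\mu_h + \sum_{h'} J_{h,h'} \nu_{h'})}
#' for the hidden neurons *in the absence of the recorded neurons* (only the
#' hidden-hidden block of the weight matrix enters; time-integrated weights
#' suffice because the steady state is time-independent). The gain of each
#' hidden neuron is \eqn{\gamma_h = \lambda_0 \phi'(\cdot)} at the same
#' operating point; for the exponential nonlinearity \eqn{\gamma_h = \nu_h}
#' exactly.
#'
#' The fixed point is found by damped iteration initialized at the
#' zero-coupling rates \eqn{\nu_h^0 = \lambda_0\phi(\mu_h)} (the leading term
#' of the small-drive series). If several fixed points exist, the one reached
#' from this initialization is reported. Divergence (rates exceeding the cap,
#' or no convergence within the iteration budget) raises a catchable
#' condition of class `"hp_hidden_network_unstable"`, so ensemble pipelines
#' can skip unstable draws.
#'
#' @param spec a [network_spec()].
#' @param part a [partition()]; only its hidden set is used.
#' @param control solver settings from [meanfield_control()].
#' @return object of class `"hp_meanfield"` with fields `rates`, `gains`
#'   (in hidden-set order), `converged`, `iterations`, `residual`,
#'   and `hidden` (the hidden index set).
#' @export
solve_hidden_rates <- function(spec, part, control = meanfield_control()) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  h <- part$hidden
  if (length(h) == 0L) {
    return(structure(list(rates = numeric(0), gains = numeric(0),
                          converged = TRUE, iterations = 0L, residual = 0,
                          hidden = integer(0)),
                     class = "hp_meanfield"))
  }
  lam0 <- spec$rate_scale
  mu <- spec$baselines[h]
  J_HH <- spec$weights[h, h, drop = FALSE]
  nl <- spec$nonlinearity
  eta <- control$damping
  cap <- control$divergence_cap * max(lam0, 1e-12)

  nu <- lam0 * apply_nonlinearity(nl, mu)
  trace_tail <- numeric(0)
  for (it in seq_len(control$max_iterations)) {
    arg <- mu + drop(J_HH %*% nu)
    target <- lam0 * apply_nonlinearity(nl, arg)
    res <- max(abs(target - nu))
    if (!all(is.finite(target)) || max(target) > cap) {
      stop_hp("hidden_network_unstable",
              sprintf("hidden mean-field rates diverged at iteration %d", it),
              iterations = it, last_rates = nu)
    }
    nu <- (1 - eta) * nu + eta * target
    if (res < control$tolerance) {
      gains <- lam0 * apply_nonlinearity(nl, mu + drop(J_HH %*% nu),
                                         deriv = TRUE)
      return(structure(list(rates = nu, gains = gains, converged = TRUE,
                            iterations = it, residual = res, hidden = h),
                       class = "hp_meanfield"))
    }
    trace_tail <- c(utils::tail(trace_tail, 9), res)
  }
  stop_hp("hidden_network_unstable",
          sprintf("hidden mean-field iteration did not converge in %d steps (residual %.3g)",
                  control$max_iterations, res),
          iterations = control$max_iterations, residual_trace = trace_tail)
}

#' @export
print.hp_meanfield <- function(x, ...) {
  cat(sprintf("<meanfield: %d hidden neurons, converged = %s (%d iterations, residual %.2e)>\n",
              length(x$rates), x$converged, x$iterations, x$residual))
  if (length(x$rates)) {
    cat(sprintf("  rates in [%.4g, %.4g]\n", min(x$rates), max(x$rates)))
  }
  invisible(x)
}

is_meanfield <- function(x) inherits(x, "hp_meanfield")

#' @export
as.data.frame.hp_meanfield <- function(x, ...) {
  data.frame(index = x$hidden, rate = x$rates, gain = x$gains)
}

check_meanfield <- function(mf) {
  if (!is_meanfield(mf) || !isTRUE(mf$converged)) {
    stop_hp("invalid_argument", "mean-field state must be converged")
  }
  invisible(mf)
}

#' Perturbative series for hidden mean-field rates (exponential nonlinearity)
#'
#' For an exponential nonlinearity and small \eqn{\epsilon_h = e^{\mu_h}},
#' the mean-field rates admit the expansion
#' \eqn{\nu_h = \lambda_0\epsilon \sum_\ell a_h^{(\ell)} (\lambda_0\epsilon)^\ell}
#' with \eqn{a_h^{(0)} = 1} and higher coefficients built recursively from
#' hidden-hidden weights. With homogeneous baselines, coefficients through
#' \eqn{a^{(3)}} are implemented (rates accurate to \eqn{O(\epsilon^4)});
#' with heterogeneous baselines, through second order.
#'
#' @inheritParams solve_hidden_rates
#' @param order series order (number of coefficient levels beyond
#'   \eqn{a^{(0)}}); at most 3 for homogeneous baselines, 2 otherwise.
#' @return list with `coefficients` (matrix, hidden neurons x orders 0..order;
#'   homogeneous case only) and `rates` (the evaluated approximation).
#' @export
series_rates <- function(spec, part, order = 3) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  if (spec$nonlinearity$kind != "exponential") {
    stop_hp("unsupported_nonlinearity",
            "rate series requires the exponential nonlinearity")
  }
  h <- part$hidden
  if (length(h) == 0L) {
    return(list(coefficients = matrix(0, 0, order + 1), rates = numeric(0)))
  }
  lam0 <- spec$rate_scale
  mu <- spec$baselines[h]
  J <- spec$weights[h, h, drop = FALSE]
  homogeneous <- length(unique(mu)) == 1L
  max_order <- if (homogeneous) 3L else 2L
  if (order < 0 || order > max_order) {
    stop_hp("invalid_argument",
            sprintf("order must be in 0..%d for %s baselines", max_order,
                    if (homogeneous) "homogeneous" else "heterogeneous"))
  }
  if (homogeneous) {
    eps <- exp(mu[1])
    r <- rowSums(J)
    coefs <- matrix(0, length(h), order + 1L)
    coefs[, 1] <- 1
    if (order >= 1) coefs[, 2] <- r
    if (order >= 2) coefs[, 3] <- drop(J %*% r) + 0.5 * r^2
    if (order >= 3) {
      J2r <- drop(J %*% drop(J %*% r))
      coefs[, 4] <- J2r + 0.5 * drop(J %*% (r^2)) +
        r * drop(J %*% r) + r^3 / 6
    }
    powers <- (lam0 * eps)^(0:order)
    rates <- lam0 * eps * drop(coefs %*% powers)
    list(coefficients = coefs, rates = rates)
  } else {
    eps <- exp(mu)
    le <- lam0 * eps
    rates <- le
    if (order >= 1) rates <- rates + le * drop(J %*% le)
    if (order >= 2) {
      quad <- drop(J %*% (le * drop(J %*% le))) + 0.5 * drop(J %*% le)^2
      rates <- rates + le * quad
    }
    list(coefficients = NULL, rates = rates)
  }
}

#' Effective baselines of the recorded neurons
#'
#' Hidden neurons modulate the recorded tonic drives by their net mean input:
#' \eqn{\mu_r^{\rm eff} = \mu_r + \sum_h J_{r,h} \nu_h}.
#'
#' @inheritParams solve_hidden_rates
#' @param mf a converged [solve_hidden_rates()] state.
#' @return numeric vector over the partition's recorded set.
#' @export
effective_baselines <- function(spec, part, mf) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  r <- part$recorded
  if (length(mf$rates) != length(part$hidden)) {
    stop_hp("invalid_argument", "mean-field state does not match partition")
  }
  J_RH <- spec$weights[r, part$hidden, drop = FALSE]
  spec$baselines[r] + drop(J_RH %*% mf$rates)
}
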