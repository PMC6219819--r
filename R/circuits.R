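# --- analytic inverse transform of causal rational spectra -----------------
#
# All circuit closed forms are rational functions of s = i*omega with poles in
# the left half-plane. The inverse Fourier transform (1/2pi) int dw e^{iwt} F
# is then, for t > 0, the sum of residues of F(s) e^{st} over the poles. For
# a pole p of multiplicity m the residue equals the coefficient of
# (s - p)^{m-1} in the Taylor series of [(s-p)^m F(s)] e^{st} about p, which
# is computed here by exact series arithmetic (polynomial shift for the
# numerator, binomial series for the remaining pole factors, exponential
# series for e^{st}). No numerical differentiation is involved.

# Taylor coefficients (orders 0..ord) of the numerator polynomial about p.
# num: coefficients ascending in s.
.shift_poly <- function(num, p, ord) {
  out <- complex(ord + 1L)
  for (k in seq_along(num)) {
    deg <- k - 1L
    for (j in 0:min(deg, ord)) {
      out[j + 1L] <- out[j + 1L] + num[k] * choose(deg, j) * p^(deg - j)
    }
  }
  out
}

# Taylor coefficients of (s - q)^(-m) about p (|p - q| > 0), orders 0..ord.
.inv_pole_series <- function(p, q, m, ord) {
  d <- p - q
  k <- 0:ord
  (-1)^k * choose(m + k - 1, k) / d^(m + k)
}

.conv_trunc <- function(a, b, ord) {
  out <- complex(ord + 1L)
  for (i in 0:ord) {
    js <- 0:i
    out[i + 1L] <- sum(a[js + 1L] * b[i - js + 1L])
  }
  out
}

# Inverse transform at times tau (>= 0) of F(s) = poly(num) / prod (s-p_i)^m_i.
# poles: complex vector; mults: integer multiplicities. Result is real for
# Hermitian-symmetric F; the real part is returned.
rational_ilt <- function(num, poles, mults, tau) {
  stopifnot(length(poles) == length(mults))
  total <- complex(length(tau))
  for (i in seq_along(poles)) {
    p <- poles[i]
    m <- mults[i]
    ord <- m - 1L
    ser <- .shift_poly(num, p, ord)
    for (j in seq_along(poles)) {
      if (j != i) {
        ser <- .conv_trunc(ser, .inv_pole_series(p, poles[j], mults[j], ord),
                           ord)
      }
    }
    # multiply by series of e^{s tau} about p and take coefficient of order m-1
    for (tt in seq_along(tau)) {
      ek <- tau[tt]^(0:ord) / factorial(0:ord)
      total[tt] <- total[tt] + exp(p * tau[tt]) * sum(ser * rev(ek))
    }
  }
  out <- Re(total)
  out[tau < 0] <- 0
  out
}

# ---------------------------------------------------------------------------

#' Feedforward-inhibition worked circuit (3 neurons)
#'
#' The classic feedforward-inhibition motif: excitatory neuron 1 projects to
#' neurons 2 and 3, inhibitory neuron 3 projects to 2 and carries a
#' refractory self-history coupling. Neurons {1, 2} are recorded, neuron 3 is
#' hidden. With the rectified-linear nonlinearity the hidden gain is exactly
#' \eqn{\gamma_3 = \lambda_0} (provided the operating point is positive), the
#' hidden rate is \eqn{\nu_3 = \lambda_0\mu_3/(1 - \lambda_0 J_{33})}, and
#' the effective 1-to-2 interaction is
#' \deqn{\hat J^{\rm eff}_{2,1}(\omega) = \hat J_{2,1}(\omega) +
#'   \frac{\hat J_{2,3}(\omega)\gamma_3\hat J_{3,1}(\omega)}
#'        {1 - \gamma_3 \hat J_{3,3}(\omega)}.}
#' The fixture carries this closed form inverse-transformed analytically
#' (partial fractions), split into `direct` and `indirect` components. The
#' self-history resummation introduces the emergent decay rate
#' \eqn{\beta_{33}(1 - \lambda_0 J_{33})}, absent from every true kernel.
#'
#' Because \eqn{\gamma_3 = \lambda_0} regardless of \eqn{\mu_3} (as long as
#' the operating point stays positive), the effective filter is independent
#' of \eqn{\mu_3}; the default 0.95 gives \eqn{\nu_3 = 0.5}.
#'
#' Defaults: \eqn{\lambda_0 = 1}, \eqn{J_{21} = 1}, \eqn{J_{23} = -2},
#' \eqn{J_{31} = 2}, \eqn{J_{33} = -0.9}, alpha kernels with
#' \eqn{\alpha_{21} = \alpha_{23} = 1}, \eqn{\alpha_{31} = 1.8}, and a
#' single-exponential self-kernel with \eqn{\beta_{33} = 1}.
#'
#' @param mu3 tonic drive of the hidden neuron (must give a positive
#'   operating point).
#' @param J21,J23,J31,J33 time-integrated weights.
#' @param alpha21,alpha23,alpha31,beta33 kernel rate constants.
#' @param lambda0 rate scale.
#' @return object of class `"hp_circuit"` with fields `spec`, `partition`,
#'   `closed_form` (function of tau for the 1-to-2 effective filter),
#'   `components` (named list of functions whose values sum to
#'   `closed_form`), and `poles` (decay structure of the closed form).
#' @export
ffi_circuit <- function(mu3 = 0.95, J21 = 1.0, J23 = -2.0, J31 = 2.0,
                        J33 = -0.9, alpha21 = 1.0, alpha23 = 1.0,
                        alpha31 = 1.8, beta33 = 1.0, lambda0 = 1.0) {
  b <- beta33 * (1 - lambda0 * J33)
  if (b <= 0) {
    stop_hp("unstable_fixture",
            "requires 1 - lambda0 * J33 > 0 for a convergent effective filter")
  }
  if (mu3 <= 0) {
    stop_hp("invalid_argument",
            "mu3 must be positive so the rectified-linear gain is lambda0")
  }
  W <- matrix(0, 3, 3)
  W[2, 1] <- J21; W[2, 3] <- J23; W[3, 1] <- J31; W[3, 3] <- J33
  km <- kernel_map(
    default = kernel("alpha", alpha21),
    per_pair = list("2,1" = kernel("alpha", alpha21),
                    "2,3" = kernel("alpha", alpha23),
                    "3,1" = kernel("alpha", alpha31)),
    self = kernel("single_exp", beta33))
  spec <- network_spec(W, baselines = c(0, 0, mu3), rate_scale = lambda0,
                       nonlinearity = nonlinearity("rectified_linear"),
                       kernels = km)
  part <- partition(recorded = c(1L, 2L), hidden = 3L)
  # operating point must sit on the linear branch
  nu3 <- lambda0 * mu3 / (1 - lambda0 * J33)
  if (mu3 + J33 * nu3 <= 0) {
    stop_hp("unstable_fixture", "hidden operating point is not positive")
  }
  gamma3 <- lambda0

  direct <- function(tau) {
    out <- J21 * alpha21^2 * tau * exp(-alpha21 * tau)
    out[tau < 0] <- 0
    out
  }
  # indirect: gamma3 J23 J31 a23^2 a31^2 (s + beta33) /
  #           ((s+a23)^2 (s+a31)^2 (s+b))
  Cind <- gamma3 * J23 * J31 * alpha23^2 * alpha31^2
  indirect <- function(tau) {
    rational_ilt(num = Cind * c(beta33, 1),
                 poles = c(-alpha23, -alpha31, -b),
                 mults = c(2L, 2L, 1L), tau = tau)
  }
  components <- list(direct = direct, indirect = indirect)
  closed_form <- function(tau) direct(tau) + indirect(tau)
  structure(list(spec = spec, partition = part, closed_form = closed_form,
                 components = components,
                 poles = c(alpha21 = alpha21, alpha23 = alpha23,
                           alpha31 = alpha31, emergent = b),
                 pair = c(post = 2L, pre = 1L)),
            class = "hp_circuit")
}

#' Degenerate 4-neuron worked circuit
#'
#' A circuit producing a nearly identical 1-to-2 effective interaction as
#' [ffi_circuit()] from a different hidden mechanism: neuron 3's self-history
#' coupling is replaced by a second hidden inhibitory neuron 4, forming a
#' reciprocal 3-4 loop. Neurons {1, 2} are recorded; {3, 4} are hidden. With
#' rectified-linear gains \eqn{\gamma_3 = \gamma_4 = \lambda_0} the frequency
#' domain correction is
#' \deqn{\frac{\hat J_{23}\gamma_3\hat J_{31} +
#'   \hat J_{23}\gamma_3\hat J_{34}\gamma_4\hat J_{41}}
#'   {1 - \gamma_3\hat J_{34}(\omega)\gamma_4\hat J_{43}(\omega)},}
#' decomposed into the four hidden paths 2<-3<-1, 2<-3<-4<-1, 2<-3<->4<-3<-1
#' (the reciprocal loop dressing the 3-step path), and 2<-3<->4<-1. The loop
#' introduces emergent oscillatory/decay structure at rates
#' \eqn{\alpha(1 \pm (|J_{34}||J_{43}|)^{1/4})}.
#'
#' Defaults: \eqn{\lambda_0 = 1}, \eqn{J_{21} = J_{31} = J_{41} = 1},
#' \eqn{J_{23} = -3}, \eqn{J_{34} = J_{43} = -0.9}; alpha kernels with
#' \eqn{\alpha_{21} = 1} for the direct interaction and \eqn{\alpha = 1.294}
#' elsewhere.
#'
#' @param mu3,mu4 hidden tonic drives (positive operating point required).
#' @param J21,J31,J41,J23,J34,J43 time-integrated weights.
#' @param alpha21,alpha kernel rate constants.
#' @param lambda0 rate scale.
#' @return object of class `"hp_circuit"`; `components` holds the four path
#'   contributions plus `direct`.
#' @export
four_neuron_circuit <- function(mu3 = 0.95, mu4 = 0.95, J21 = 1.0, J31 = 1.0,
                                J41 = 1.0, J23 = -3.0, J34 = -0.9, J43 = -0.9,
                                alpha21 = 1.0, alpha = 1.294, lambda0 = 1.0) {
  if (abs(J34) * abs(J43) >= 1) {
    stop_hp("unstable_fixture",
            "requires |J34||J43| < 1 for a convergent effective filter")
  }
  W <- matrix(0, 4, 4)
  W[2, 1] <- J21; W[3, 1] <- J31; W[4, 1] <- J41
  W[2, 3] <- J23; W[3, 4] <- J34; W[4, 3] <- J43
  km <- kernel_map(default = kernel("alpha", alpha),
                   per_pair = list("2,1" = kernel("alpha", alpha21)),
                   self = kernel("single_exp", 1))
  spec <- network_spec(W, baselines = c(0, 0, mu3, mu4),
                       rate_scale = lambda0,
                       nonlinearity = nonlinearity("rectified_linear"),
                       kernels = km)
  part <- partition(recorded = c(1L, 2L), hidden = c(3L, 4L))
  # hidden fixed point: nu3 = mu3 + J34 nu4, nu4 = mu4 + J43 nu3 (lambda0 = 1
  # units); both arguments must be positive for gamma = lambda0
  det <- 1 - lambda0^2 * J34 * J43
  nu3 <- lambda0 * (mu3 + lambda0 * J34 * mu4) / det
  nu4 <- lambda0 * (mu4 + lambda0 * J43 * mu3) / det
  if (nu3 <= 0 || nu4 <= 0) {
    stop_hp("unstable_fixture", "hidden operating point is not positive")
  }
  g <- lambda0 # gamma_3 = gamma_4

  direct <- function(tau) {
    out <- J21 * alpha21^2 * tau * exp(-alpha21 * tau)
    out[tau < 0] <- 0
    out
  }
  # loop denominator 1 - g^2 J34 J43 ghat^2 = ((s+a)^4 - c)/(s+a)^4,
  # c = g^2 J34 J43 a^4; quartic-root poles s = -a + c^{1/4} i^k
  c4 <- g^2 * J34 * J43 * alpha^4
  root <- (abs(c4))^(1 / 4) * exp(1i * (Arg(complex(real = c4)) / 4))
  loop_poles <- -alpha + root * exp(1i * pi / 2 * (0:3))
  p231 <- function(tau) { # g J23 J31 ghat^2, no loop
    out <- g * J23 * J31 * alpha^4 * tau^3 * exp(-alpha * tau) / 6
    out[tau < 0] <- 0
    out
  }
  p2341 <- function(tau) { # g^2 J23 J34 J41 ghat^3
    out <- g^2 * J23 * J34 * J41 * alpha^6 * tau^5 * exp(-alpha * tau) / 120
    out[tau < 0] <- 0
    out
  }
  p23431 <- function(tau) { # g J23 J31 ghat^2 * c4/((s+a)^4 - c4)
    if (c4 == 0) return(rep(0, length(tau)))
    rational_ilt(num = g * J23 * J31 * alpha^4 * c4,
                 poles = c(-alpha, loop_poles),
                 mults = c(4L, rep(1L, 4)), tau = tau)
  }
  p23441 <- function(tau) { # g^2 J23 J34 J41 ghat^3 * c4/((s+a)^4 - c4)
    if (c4 == 0) return(rep(0, length(tau)))
    rational_ilt(num = g^2 * J23 * J34 * J41 * alpha^6 * c4,
                 poles = c(-alpha, loop_poles),
                 mults = c(6L, rep(1L, 4)), tau = tau)
  }
  components <- list(direct = direct, "2<-3<-1" = p231, "2<-3<-4<-1" = p2341,
                     "2<-3<->4<-3<-1" = p23431, "2<-3<->4<-1" = p23441)
  closed_form <- function(tau) {
    Reduce(`+`, lapply(components, function(f) f(tau)))
  }
  structure(list(spec = spec, partition = part, closed_form = closed_form,
                 components = components,
                 poles = c(alpha21 = alpha21, alpha = alpha,
                           loop = alpha * (1 - Mod(root) / alpha)),
                 pair = c(post = 2L, pre = 1L)),
            class = "hp_circuit")
}

#' @export
print.hp_circuit <- function(x, ...) {
  cat(sprintf("<circuit fixture: %d neurons, recorded {%s}, hidden {%s}>\n",
              x$spec$n_neurons, paste(x$partition$recorded, collapse = ","),
              paste(x$partition$hidden, collapse = ",")))
  cat(sprintf("  closed-form effective interaction %d <- %d; components: %s\n",
              x$pair["post"], x$pair["pre"],
              paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' Discrepancy between two circuit closed forms
#'
#' Evaluates both fixtures' closed-form effective interactions on a shared
#' time grid and reports the maximum absolute difference and the integrated
#' absolute difference. Symmetric in its arguments.
#'
#' @param a,b `"hp_circuit"` fixtures.
#' @param tau_max,dt evaluation grid.
#' @return list with `max_abs` and `integrated_abs`.
#' @export
fixture_similarity <- function(a, b, tau_max = 10, dt = 0.001) {
  stopifnot(inherits(a, "hp_circuit"), inherits(b, "hp_circuit"))
  tau <- seq(0, tau_max, by = dt)
  d <- a$closed_form(tau) - b$closed_form(tau)
  list(max_abs = max(abs(d)), integrated_abs = sum(abs(d)) * dt)
}
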