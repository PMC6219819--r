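#' Synaptic temporal kernel
#'
#' Constructs a normalized causal synaptic waveform \eqn{g(\tau)}. Three
#' families are supported:
#' \describe{
#'   \item{`alpha`}{\eqn{g(\tau) = \alpha^2 \tau e^{-\alpha\tau}}, the usual
#'     alpha synapse with rise and decay governed by a single rate
#'     `rate_param` \eqn{= \alpha} (units 1/time).}
#'   \item{`single_exp`}{\eqn{g(\tau) = \beta e^{-\beta\tau}}, used for
#'     self-history couplings such as refractoriness.}
#'   \item{`delta`}{\eqn{g(\tau) = \delta(\tau)}; its transform is 1 at every
#'     frequency, so it lets zero-frequency-only computations bypass temporal
#'     structure entirely.}
#' }
#' All families integrate to one over \eqn{[0, \infty)}, so a coupling filter
#' \eqn{J_{ij}(\tau) = J_{ij} g_j(\tau)} has time-integrated weight
#' \eqn{J_{ij}} (units of time) and frequency-domain value
#' \eqn{\hat J_{ij}(0) = J_{ij}}.
#'
#' @param family one of `"alpha"`, `"single_exp"`, `"delta"`.
#' @param rate_param inverse-time rate constant (\eqn{\alpha} or \eqn{\beta});
#'   ignored for the delta family.
#' @return an object of class `"hp_kernel"`.
#' @examples
#' k <- kernel("alpha", 10)
#' kernel_time(k, weight = 1, tau = 0.1)
#' kernel_freq(k, weight = 1, omega = 0) # = 1, normalization
#' @export
kernel <- function(family = c("alpha", "single_exp", "delta"),
                   rate_param = NULL) {
  family <- match.arg(family)
  if (family != "delta") {
    if (is.null(rate_param) || !is.numeric(rate_param) ||
        length(rate_param) != 1L || !is.finite(rate_param) ||
        rate_param <= 0) {
      stop_hp("invalid_kernel",
              sprintf("kernel family '%s' requires a positive finite rate_param",
                      family))
    }
  } else {
    rate_param <- NA_real_
  }
  structure(list(family = family, rate_param = as.numeric(rate_param)),
            class = "hp_kernel")
}

#' @export
print.hp_kernel <- function(x, ...) {
  if (x$family == "delta") {
    cat("<kernel: delta>\n")
  } else {
    cat(sprintf("<kernel: %s, rate = %g>\n", x$family, x$rate_param))
  }
  invisible(x)
}

is_kernel <- function(x) inherits(x, "hp_kernel")

#' Evaluate a coupling filter in the time domain
#'
#' Returns \eqn{J g(\tau)} for a kernel's waveform \eqn{g}. Causality is
#' enforced: the value is 0 for \eqn{\tau < 0}. The delta family returns 0
#' for every \eqn{\tau \neq 0} and signals an error at \eqn{\tau = 0}, where
#' the density is not finite.
#'
#' @param kernel a [kernel()] object.
#' @param weight time-integrated synaptic weight \eqn{J} (units of time).
#' @param tau time lag(s); vectorized.
#' @return numeric vector of interaction values.
#' @export
kernel_time <- function(kernel, weight, tau) {
  check_kernel(kernel)
  stopifnot(is.numeric(tau), all(is.finite(tau)))
  a <- kernel$rate_param
  out <- switch(kernel$family,
    alpha = weight * a^2 * tau * exp(-a * tau),
    single_exp = weight * a * exp(-a * tau),
    delta = {
      if (any(tau == 0)) {
        stop_hp("invalid_argument",
                "delta kernel has no finite time-domain density at tau = 0")
      }
      rep(0, length(tau))
    })
  out[tau < 0] <- 0
  out
}

#' Evaluate a coupling filter in the frequency domain
#'
#' Closed-form Fourier transforms under the convention
#' \eqn{\hat f(\omega) = \int dt\, e^{-i\omega t} f(t)}:
#' alpha \eqn{J\alpha^2/(\alpha + i\omega)^2}, single-exponential
#' \eqn{J\beta/(\beta + i\omega)}, delta \eqn{J}. At \eqn{\omega = 0} every
#' family returns exactly `weight` (normalized waveforms).
#'
#' @inheritParams kernel_time
#' @param omega angular frequency (real, vectorized).
#' @return complex vector.
#' @export
kernel_freq <- function(kernel, weight, omega) {
  check_kernel(kernel)
  stopifnot(is.numeric(omega), all(is.finite(omega)))
  a <- kernel$rate_param
  switch(kernel$family,
    alpha = weight * a^2 / (a + 1i * omega)^2,
    single_exp = weight * a / (a + 1i * omega),
    delta = rep(complex(real = weight), length(omega)))
}

check_kernel <- function(k) {
  if (!is_kernel(k)) stop_hp("invalid_kernel", "not a kernel object")
  if (k$family != "delta" &&
      (!is.finite(k$rate_param) || k$rate_param <= 0)) {
    stop_hp("invalid_kernel", "kernel rate_param must be positive")
  }
  invisible(k)
}

#' Rate nonlinearity
#'
#' The nonnegative function \eqn{\phi(x)} mapping summed synaptic input to an
#' instantaneous rate factor, \eqn{\lambda = \lambda_0 \phi(x)}. Supported
#' kinds: `"exponential"` \eqn{e^x} (the canonical GLM choice),
#' `"rectified_linear"` \eqn{\max(x, 0)} with derivative the Heaviside step
#' \eqn{\Theta(x)} (zero at \eqn{x = 0}), and `"sigmoid"`
#' \eqn{c/(1 + e^{-x})}, whose ceiling \eqn{c} bounds the rate and
#' guarantees non-divergent mean-field solutions.
#'
#' @param kind one of `"exponential"`, `"rectified_linear"`, `"sigmoid"`.
#' @param ceiling saturation level \eqn{c} (sigmoid only, default 2).
#' @return an object of class `"hp_nonlinearity"`.
#' @export
nonlinearity <- function(kind = c("exponential", "rectified_linear", "sigmoid"),
                         ceiling = 2) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(ceiling), length(ceiling) == 1L, is.finite(ceiling),
            ceiling > 0)
  structure(list(kind = kind,
                 ceiling = if (kind == "sigmoid") as.numeric(ceiling)
                           else NA_real_),
            class = "hp_nonlinearity")
}

#' @export
print.hp_nonlinearity <- function(x, ...) {
  if (x$kind == "sigmoid") {
    cat(sprintf("<nonlinearity: sigmoid, ceiling = %g>\n", x$ceiling))
  } else {
    cat(sprintf("<nonlinearity: %s>\n", x$kind))
  }
  invisible(x)
}

is_nonlinearity <- function(x) inherits(x, "hp_nonlinearity")

#' Apply a rate nonlinearity or its derivative
#'
#' @param nl a [nonlinearity()] object.
#' @param x input (vectorized, finite).
#' @param deriv if `TRUE` return \eqn{\phi'(x)} instead of \eqn{\phi(x)}.
#' @return numeric vector; \eqn{\phi(x) \ge 0} always.
#' @export
apply_nonlinearity <- function(nl, x, deriv = FALSE) {
  stopifnot(is_nonlinearity(nl), is.numeric(x), all(is.finite(x)))
  switch(nl$kind,
    exponential = exp(x),
    rectified_linear = if (deriv) as.numeric(x > 0) else pmax(x, 0),
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      if (deriv) nl$ceiling * s * (1 - s) else nl$ceiling * s
    })
}
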