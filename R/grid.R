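#' Paired time/frequency sampling grid
#'
#' Uniform time bins \eqn{t_k = k\,\Delta t}, \eqn{k = 0, \dots, n-1}, and
#' the conjugate FFT grid of angular frequencies
#' \eqn{\omega_j = 2\pi j / (n \Delta t)} (stored in FFT order, negative
#' frequencies in the upper half), under the transform convention
#' \eqn{\hat f(\omega) = \int dt\, e^{-i\omega t} f(t)}. The inverse
#' transform is the Riemann sum
#' \eqn{f(t_k) = \frac{1}{2\pi}\sum_j \hat f(\omega_j) e^{i\omega_j t_k}
#' \Delta\omega} with the frequency step
#' \eqn{\Delta\omega = 2\pi/(n\Delta t)} in the quadrature weight, which is
#' the dimensionally consistent discretization and reduces to a standard
#' inverse FFT.
#'
#' The default resolution \eqn{\Delta t = 0.1/\alpha_{\max}} resolves the
#' fastest synaptic kernel; `n_time = 4096` bins then cover the slowest
#' emergent timescales of the worked examples.
#'
#' @param dt time step.
#' @param n_time number of time bins.
#' @return object of class `"hp_grid"` with fields `dt`, `n_time`, `times`,
#'   `omegas` (FFT order; `omegas[1] == 0`).
#' @export
frequency_grid <- function(dt = 0.01, n_time = 4096) {
  stopifnot(is.numeric(dt), dt > 0, n_time >= 2)
  n_time <- as.integer(n_time)
  j <- 0:(n_time - 1L)
  j[j >= n_time / 2] <- j[j >= n_time / 2] - n_time
  structure(list(dt = dt, n_time = n_time,
                 times = (0:(n_time - 1L)) * dt,
                 omegas = 2 * pi * j / (n_time * dt)),
            class = "hp_grid")
}

#' @export
print.hp_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid: dt = %g, %d bins, t in [0, %g), |omega| <= %g>\n",
              x$dt, x$n_time, x$n_time * x$dt, max(abs(x$omegas))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "hp_grid")

#' Inverse-transform frequency-domain filters to the time domain
#'
#' Accepts a complex vector (one filter) or a 3-d array
#' (recorded x recorded x frequency) sampled on the grid's omega points, and
#' returns the real time-domain filter(s) on the grid's time bins. Input that
#' violates Hermitian symmetry (so that the inverse transform has an
#' imaginary residue above `1e-8` of the peak amplitude) triggers a warning
#' and is symmetrized. The operation is linear in its input.
#'
#' @param filters_freq complex vector of length `grid$n_time`, or array with
#'   last dimension `grid$n_time`, in the grid's FFT frequency order.
#' @param grid a [frequency_grid()].
#' @return real vector or array matching the input shape, last dimension now
#'   indexing time bins.
#' @export
to_time_domain <- function(filters_freq, grid) {
  stopifnot(is_grid(grid))
  # For even n the unpaired Nyquist coefficient of a real signal's DFT is
  # necessarily real; project it before inverting.
  nyq <- if (grid$n_time %% 2L == 0L) grid$n_time / 2L + 1L else 0L
  inv1 <- function(z) {
    if (nyq > 0L) z[nyq] <- Re(z[nyq])
    stats::fft(z, inverse = TRUE) / (grid$n_time * grid$dt)
  }
  if (is.null(dim(filters_freq))) {
    stopifnot(length(filters_freq) == grid$n_time)
    z <- inv1(filters_freq)
    scale <- max(Mod(z), .Machine$double.xmin)
    if (max(abs(Im(z))) > 1e-8 * scale) {
      warn_hp("non_hermitian",
              "frequency-domain input is not Hermitian-consistent; symmetrizing")
      sym <- hermitian_symmetrize(filters_freq, grid)
      z <- inv1(sym)
    }
    return(Re(z))
  }
  d <- dim(filters_freq)
  stopifnot(d[length(d)] == grid$n_time)
  out <- array(0, dim = d)
  nr <- d[1]; nc <- d[2]
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      out[a, b, ] <- to_time_domain(filters_freq[a, b, ], grid)
    }
  }
  out
}

# Enforce fhat(-omega) = Conj(fhat(omega)) on an FFT-ordered vector.
hermitian_symmetrize <- function(z, grid) {
  n <- grid$n_time
  idx_neg <- c(1L, seq(n, 2L, by = -1L)) # index of -omega_j for each j
  (z + Conj(z[idx_neg])) / 2
}
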