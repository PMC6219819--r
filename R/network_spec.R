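#' Kernel assignment map
#'
#' Resolves the temporal waveform used by every ordered pair (post, pre) of a
#' network. Precedence: per-pair assignment, then (for diagonal entries) the
#' dedicated self-history kernel, then per-presynaptic-neuron assignment,
#' then the global default. This reproduces the common setup of alpha-kernel
#' inter-neuron couplings mixed with single-exponential self-history terms
#' without enumerating every pair.
#'
#' @param default [kernel()] used when nothing more specific applies.
#' @param per_neuron optional list mapping presynaptic neuron index (as list
#'   name, e.g. `"3"`) to a kernel.
#' @param per_pair optional list mapping `"post,pre"` strings (1-based,
#'   e.g. `"2,1"`) to a kernel.
#' @param self optional kernel for diagonal (self-history) entries.
#' @return object of class `"hp_kernel_map"`.
#' @export
kernel_map <- function(default = kernel("alpha", 1),
                       per_neuron = NULL, per_pair = NULL, self = NULL) {
  check_kernel(default)
  if (!is.null(self)) check_kernel(self)
  for (k in per_neuron) check_kernel(k)
  for (k in per_pair) check_kernel(k)
  structure(list(default = default, per_neuron = per_neuron,
                 per_pair = per_pair, self = self),
            class = "hp_kernel_map")
}

#' Resolve the kernel for an ordered neuron pair
#'
#' @param km a [kernel_map()].
#' @param post,pre postsynaptic and presynaptic neuron indices (1-based).
#' @return a [kernel()] object.
#' @export
resolve_kernel <- function(km, post, pre) {
  stopifnot(inherits(km, "hp_kernel_map"))
  key <- paste0(post, ",", pre)
  if (!is.null(km$per_pair) && !is.null(km$per_pair[[key]])) {
    return(km$per_pair[[key]])
  }
  if (post == pre && !is.null(km$self)) return(km$self)
  nk <- km$per_neuron[[as.character(pre)]]
  if (!is.null(nk)) return(nk)
  km$default
}

#' Ground-truth network specification
#'
#' Container for a fully specified nonlinear Hawkes network: the rate scale
#' \eqn{\lambda_0}, per-neuron tonic drives \eqn{\mu_i}, the matrix of
#' time-integrated synaptic weights \eqn{J_{ij}} (row = postsynaptic i,
#' column = presynaptic j, i.e. entry (i, j) is the weight *from* j *to* i),
#' the kernel assignment giving each ordered pair its temporal waveform, and
#' the rate nonlinearity. Diagonal entries are self-history terms
#' (refractoriness when negative, burstiness when positive), not autapses.
#'
#' @param weights square numeric matrix of time-integrated weights.
#' @param baselines numeric vector of tonic drives, recycled if scalar.
#' @param rate_scale characteristic rate \eqn{\lambda_0} (default 1; time is
#'   then measured in units of \eqn{1/\lambda_0}).
#' @param nonlinearity a [nonlinearity()] object.
#' @param kernels a [kernel_map()].
#' @return object of class `"hp_network_spec"`.
#' @export
network_spec <- function(weights, baselines, rate_scale = 1,
                         nonlinearity = hiddenpaths::nonlinearity("exponential"),
                         kernels = kernel_map()) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop_hp("invalid_argument", "weights matrix must be square")
  }
  if (!all(is.finite(weights))) {
    stop_hp("invalid_argument", "weights matrix must be finite-valued")
  }
  n <- nrow(weights)
  if (length(baselines) == 1L) baselines <- rep(baselines, n)
  stopifnot(length(baselines) == n, all(is.finite(baselines)),
            is.numeric(rate_scale), length(rate_scale) == 1L, rate_scale >= 0,
            is_nonlinearity(nonlinearity), inherits(kernels, "hp_kernel_map"))
  dimnames(weights) <- NULL
  structure(list(n_neurons = n, rate_scale = as.numeric(rate_scale),
                 baselines = as.numeric(baselines), weights = weights,
                 kernels = kernels, nonlinearity = nonlinearity),
            class = "hp_network_spec")
}

#' @export
print.hp_network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: %d neurons, lambda0 = %g, %s nonlinearity>\n",
              x$n_neurons, x$rate_scale, x$nonlinearity$kind))
  cat(sprintf("  nonzero weights: %d of %d off-diagonal, %d self\n",
              sum(x$weights != 0) - sum(diag(x$weights) != 0),
              x$n_neurons * (x$n_neurons - 1L),
              sum(diag(x$weights) != 0)))
  invisible(x)
}

is_network_spec <- function(x) inherits(x, "hp_network_spec")

#' Recorded/hidden partition
#'
#' Splits neuron indices into an ordered recorded set and an ordered hidden
#' set. The orderings are preserved so the weight blocks J_RR, J_RH, J_HR,
#' J_HH are reproducible.
#'
#' @param recorded integer vector of recorded neuron indices (1-based).
#' @param hidden integer vector of hidden neuron indices.
#' @param n_neurons total neuron count; if one of `recorded`/`hidden` is
#'   missing it is filled with the complement in original index order.
#' @return object of class `"hp_partition"`.
#' @export
partition <- function(recorded = NULL, hidden = NULL, n_neurons = NULL) {
  if (is.null(recorded) && is.null(hidden)) {
    stop_hp("invalid_partition", "supply recorded and/or hidden indices")
  }
  if (is.null(n_neurons)) {
    n_neurons <- length(recorded) + length(hidden)
  }
  if (is.null(recorded)) recorded <- setdiff(seq_len(n_neurons), hidden)
  if (is.null(hidden)) hidden <- setdiff(seq_len(n_neurons), recorded)
  recorded <- as.integer(recorded)
  hidden <- as.integer(hidden)
  all_idx <- c(recorded, hidden)
  if (anyDuplicated(all_idx) ||
      !setequal(all_idx, seq_len(n_neurons)) ||
      length(all_idx) != n_neurons) {
    stop_hp("invalid_partition",
            "recorded and hidden must be disjoint and cover 1..n_neurons")
  }
  structure(list(recorded = recorded, hidden = hidden,
                 n_neurons = as.integer(n_neurons)),
            class = "hp_partition")
}

#' @export
print.hp_partition <- function(x, ...) {
  cat(sprintf("<partition: %d recorded, %d hidden of %d>\n",
              length(x$recorded), length(x$hidden), x$n_neurons))
  invisible(x)
}

is_partition <- function(x) inherits(x, "hp_partition")

check_partition <- function(spec, part) {
  if (!is_partition(part)) stop_hp("invalid_partition", "not a partition")
  if (part$n_neurons != spec$n_neurons) {
    stop_hp("invalid_partition",
            sprintf("partition is over %d neurons but network has %d",
                    part$n_neurons, spec$n_neurons))
  }
  invisible(part)
}

#' Partition a weight matrix into recorded/hidden blocks
#'
#' Returns the four blocks J_RR, J_RH, J_HR, J_HH of the time-integrated
#' weight matrix, indexed in the partition's recorded/hidden order.
#' Reassembling the blocks at the partition indices recovers the original
#' matrix exactly.
#'
#' @param spec a [network_spec()].
#' @param part a [partition()] over the same neurons.
#' @return list with elements `J_RR`, `J_RH`, `J_HR`, `J_HH`.
#' @export
block_weights <- function(spec, part) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  r <- part$recorded
  h <- part$hidden
  J <- spec$weights
  list(J_RR = J[r, r, drop = FALSE], J_RH = J[r, h, drop = FALSE],
       J_HR = J[h, r, drop = FALSE], J_HH = J[h, h, drop = FALSE])
}

# Frequency-domain weight block: matrix of Jhat_{ij}(omega) = J_ij ghat_ij(omega)
# for one scalar omega, rows/cols taken from the given index vectors.
block_freq <- function(spec, rows, cols, omega) {
  out <- matrix(0i, length(rows), length(cols))
  for (a in seq_along(rows)) {
    for (b in seq_along(cols)) {
      w <- spec$weights[rows[a], cols[b]]
      if (w != 0) {
        k <- resolve_kernel(spec$kernels, rows[a], cols[b])
        out[a, b] <- kernel_freq(k, w, omega)
      }
    }
  }
  out
}

# TRUE when every nonzero ordered pair among the given indices resolves to
# one identical kernel; basis for the uniform-kernel fast path.
uniform_kernel <- function(spec, rows, cols) {
  km <- spec$kernels
  # common fast case: nothing but a global default can apply
  if (is.null(km$per_pair) && is.null(km$per_neuron) &&
      (is.null(km$self) || !any(rows %in% cols) ||
       all(diag(spec$weights)[intersect(rows, cols)] == 0))) {
    return(km$default)
  }
  k0 <- NULL
  for (a in rows) {
    for (b in cols) {
      if (spec$weights[a, b] != 0) {
        k <- resolve_kernel(spec$kernels, a, b)
        if (is.null(k0)) {
          k0 <- k
        } else if (!identical(k, k0)) {
          return(NULL)
        }
      }
    }
  }
  k0 # NULL if no nonzero entries: caller treats as compatible with anything
}
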