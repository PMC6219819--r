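#' Hidden-network linear response over a frequency grid
#'
#' Computes, at every grid frequency, the transfer matrix
#' \eqn{\hat V_{h,h'}(\omega) = \gamma_h \hat J_{h,h'}(\omega)} and the
#' linear-response matrix of the hidden subnetwork
#' \eqn{\hat\Gamma(\omega) = [I - \hat V(\omega)]^{-1}\,\mathrm{diag}(\gamma)},
#' obtained by a dense linear solve (never an explicit inverse). The spectral
#' radius of \eqn{\hat V(0)} is recorded as the sharp stability/convergence
#' diagnostic.
#'
#' When every nonzero hidden-hidden pair shares one identical kernel, a fast
#' path diagonalizes \eqn{\mathrm{diag}(\gamma) J_{HH}} once and evaluates
#' all frequencies from the eigendecomposition; otherwise each frequency is
#' solved independently.
#'
#' @param spec a [network_spec()].
#' @param part a [partition()] with nonempty hidden set.
#' @param mf converged mean-field state from [solve_hidden_rates()].
#' @param grid a [frequency_grid()], or `NULL` for the zero-frequency-only
#'   operator.
#' @return object of class `"hp_transfer"` with fields `grid`, `omegas`,
#'   `v_matrices` and `gamma_matrices` (lists of complex matrices, one per
#'   frequency), and `spectral_radius_zero`.
#' @export
transfer_operator <- function(spec, part, mf, grid = NULL) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  h <- part$hidden
  if (length(h) == 0L) {
    stop_hp("invalid_argument", "transfer operator requires hidden neurons")
  }
  omegas <- if (is.null(grid)) 0 else grid$omegas
  gam <- mf$gains
  nh <- length(h)
  mem_gb <- as.numeric(nh)^2 * length(omegas) * 16 / 2^30
  if (mem_gb > 4) {
    stop_hp("invalid_argument",
            sprintf(paste0("materializing %d x %d response matrices at %d ",
                           "frequencies needs ~%.0f GiB; use ",
                           "build_effective_model() (factorized path) or a ",
                           "zero-frequency operator (grid = NULL)"),
                    nh, nh, length(omegas), mem_gb))
  }
  D <- diag(gam, nh)

  v_mats <- vector("list", length(omegas))
  g_mats <- vector("list", length(omegas))
  uk <- uniform_kernel(spec, h, h)
  J_HH <- spec$weights[h, h, drop = FALSE]

  fast <- !is.null(uk) || all(J_HH == 0)
  if (fast) {
    # single shared kernel: Vhat(omega) = ghat(omega) * diag(gamma) J_HH;
    # one eigendecomposition serves every frequency. Guard against a
    # defective decomposition by checking the omega = 0 residual.
    V0 <- gam * J_HH
    ghat <- if (all(J_HH == 0)) rep(1 + 0i, length(omegas))
            else kernel_freq(uk, 1, omegas)
    eig <- eigen(V0)
    P <- eig$vectors
    B <- tryCatch(solve(P, D), error = function(e) NULL) # P^-1 D
    if (is.null(B)) {
      fast <- FALSE
    } else if (all(Mod(1 - eig$values) > 1e-12)) {
      G0 <- P %*% ((1 / (1 - eig$values)) * B)
      resid <- max(Mod((diag(1 + 0i, nh) - V0) %*% G0 - D))
      if (resid > 1e-8 * max(1, max(abs(gam)))) fast <- FALSE
    }
  }
  if (fast) {
    for (i in seq_along(omegas)) {
      v_mats[[i]] <- ghat[i] * V0
      denom <- 1 - ghat[i] * eig$values
      if (any(Mod(denom) < 1e-12)) {
        stop_hp("linear_response_singular",
                sprintf("I - V(omega) singular at omega = %g", omegas[i]),
                omega = omegas[i])
      }
      g_mats[[i]] <- P %*% ((1 / denom) * B)
    }
  } else {
    for (i in seq_along(omegas)) {
      Jhat <- block_freq(spec, h, h, omegas[i])
      V <- gam * Jhat
      v_mats[[i]] <- V
      A <- diag(1 + 0i, nh) - V
      G <- tryCatch(solve(A, D + 0i), error = function(e) NULL)
      if (is.null(G)) {
        stop_hp("linear_response_singular",
                sprintf("I - V(omega) singular at omega = %g", omegas[i]),
                omega = omegas[i])
      }
      g_mats[[i]] <- G
    }
  }
  i0 <- which.min(abs(omegas))
  structure(list(grid = grid, omegas = omegas, hidden = h,
                 gains = gam, v_matrices = v_mats, gamma_matrices = g_mats,
                 spectral_radius_zero = spectral_radius(v_mats[[i0]])),
            class = "hp_transfer")
}

#' @export
print.hp_transfer <- function(x, ...) {
  cat(sprintf("<transfer_operator: %d hidden neurons, %d frequencies, rho(V(0)) = %.4g>\n",
              length(x$hidden), length(x$omegas), x$spectral_radius_zero))
  invisible(x)
}

is_transfer <- function(x) inherits(x, "hp_transfer")

#' Path-series expansion of the hidden-network linear response
#'
#' Expands \eqn{\hat\Gamma(\omega)} as a sum over directed paths through the
#' hidden network. Self-loops are factored into node factors: each hidden
#' node \eqn{h} on a path contributes
#' \eqn{\gamma_h / (1 - \gamma_h \hat J_{h,h}(\omega))} and each edge
#' \eqn{h_i \to h_j} contributes \eqn{\hat J_{h_j,h_i}(\omega)}; consecutive
#' path nodes are distinct. A length-0 path is a single node.
#'
#' Explicit paths are enumerated depth-first up to `max_path_count` (beyond
#' which a truncation warning is attached and enumeration stops). The
#' truncated \eqn{\hat\Gamma} approximation itself is accumulated through the
#' equivalent matrix recursion \eqn{\sum_{\ell \le L} (D \hat J_{\rm off})^\ell D}
#' with \eqn{D = \mathrm{diag}(\gamma_h/(1-\gamma_h \hat J_{h,h}))}, which is
#' exact for the full set of paths regardless of the enumeration cap.
#'
#' @inheritParams transfer_operator
#' @param max_length maximum number of edges per path (>= 1).
#' @param max_path_count cap on explicitly enumerated paths.
#' @return list with `paths` (list of `hp_hidden_path` objects, each with
#'   `nodes` in signal order source -> sink, `contribution_zero`, and a
#'   `contribution(omega)` function), `gamma_approx` (list of per-frequency
#'   truncated matrices), `error_bound` (per-frequency rigorous geometric
#'   tail bound, entrywise valid when the factored series converges),
#'   `converges` flag and `truncated_enumeration` flag.
#' @export
path_series <- function(spec, part, mf, grid = NULL, max_length = 3,
                        max_path_count = 1e6) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  if (max_length < 1) stop_hp("invalid_argument", "max_length must be >= 1")
  h <- part$hidden
  nh <- length(h)
  omegas <- if (is.null(grid)) 0 else grid$omegas
  gam <- mf$gains
  J_HH <- spec$weights[h, h, drop = FALSE]

  rho0 <- spectral_radius(gam * J_HH)
  if (rho0 >= 1) {
    warn_hp("series_divergent",
            sprintf("spectral radius of V(0) is %.4g >= 1; path series may diverge",
                    rho0))
  }

  # node and edge factor builders (local hidden indexing)
  node_factor <- function(a, omega) {
    jhh <- J_HH[a, a]
    if (jhh == 0) return(rep(complex(real = gam[a]), length(omega)))
    k <- resolve_kernel(spec$kernels, h[a], h[a])
    gam[a] / (1 - gam[a] * kernel_freq(k, jhh, omega))
  }
  edge_factor <- function(to, from, omega) {
    k <- resolve_kernel(spec$kernels, h[to], h[from])
    kernel_freq(k, J_HH[to, from], omega)
  }

  # depth-first enumeration of paths (source -> sink) without immediate
  # self-repeats, following existing (nonzero) edges only; zero-frequency
  # contributions are accumulated incrementally from precomputed factors
  truncated <- FALSE
  succ <- lapply(seq_len(nh), function(a) which(J_HH[, a] != 0 & seq_len(nh) != a))
  nf0 <- vapply(seq_len(nh), function(a) node_factor(a, 0), complex(1))
  J0 <- block_freq(spec, h, h, 0)
  diag(J0) <- 0i
  new_path <- function(nodes, value) {
    structure(list(nodes = h[nodes], local_nodes = nodes,
                   contribution = function(omega) {
                     val <- node_factor(nodes[1], omega)
                     for (s in seq_len(length(nodes) - 1L)) {
                       val <- val * edge_factor(nodes[s + 1L], nodes[s], omega) *
                         node_factor(nodes[s + 1L], omega)
                     }
                     val
                   },
                   contribution_zero = value),
              class = "hp_hidden_path")
  }
  paths <- vector("list", 1024L)
  np <- 0L
  stack <- vector("list", 256L)
  ns <- 0L
  for (a in rev(seq_len(nh))) {
    ns <- ns + 1L
    stack[[ns]] <- list(a, nf0[a])
  }
  while (ns > 0L) {
    cur <- stack[[ns]]
    ns <- ns - 1L
    if (np >= max_path_count) {
      truncated <- TRUE
      break
    }
    nodes <- cur[[1]]
    np <- np + 1L
    if (np > length(paths)) paths <- c(paths, vector("list", length(paths)))
    paths[[np]] <- new_path(nodes, cur[[2]])
    if (length(nodes) - 1L < max_length) {
      tip <- nodes[length(nodes)]
      for (nxt in succ[[tip]]) {
        ns <- ns + 1L
        if (ns > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[ns]] <- list(c(nodes, nxt),
                            cur[[2]] * J0[nxt, tip] * nf0[nxt])
      }
    }
  }
  paths <- paths[seq_len(np)]
  if (truncated) {
    warn_hp("path_enumeration_truncated",
            sprintf("path enumeration capped at %g paths", max_path_count))
  }

  # truncated Gamma via matrix recursion, plus rigorous tail bound
  gamma_approx <- vector("list", length(omegas))
  error_bound <- numeric(length(omegas))
  for (i in seq_along(omegas)) {
    om <- omegas[i]
    Dvec <- vapply(seq_len(nh), function(a) node_factor(a, om), complex(1))
    Joff <- block_freq(spec, h, h, om)
    diag(Joff) <- 0i
    Dm <- diag(Dvec, nh)
    W <- Dvec * Joff # D %*% Joff
    total <- Dm
    term <- Dm
    for (l in seq_len(max_length)) {
      term <- W %*% term
      total <- total + term
    }
    gamma_approx[[i]] <- total
    M <- op_norm2(W)
    error_bound[i] <- if (M < 1) {
      M^(max_length + 1) / (1 - M) * op_norm2(Dm)
    } else {
      Inf
    }
  }
  list(paths = paths, gamma_approx = gamma_approx, omegas = omegas,
       error_bound = error_bound, converges = rho0 < 1,
       truncated_enumeration = truncated)
}

#' @export
print.hp_hidden_path <- function(x, ...) {
  cat(sprintf("<hidden path: %s (contribution at omega=0: %.4g)>\n",
              paste(x$nodes, collapse = " -> "), Re(x$contribution_zero)))
  invisible(x)
}

#' Tabulate enumerated hidden paths
#'
#' Flattens a [path_series()] result into a data frame (one row per path)
#' suitable for CSV export: the node sequence in signal order, the real part
#' of the zero-frequency contribution, and its cumulative sum in enumeration
#' order.
#'
#' @param ps a [path_series()] result.
#' @return data frame with columns `path`, `length`, `contribution_zero`,
#'   `cumulative`.
#' @export
path_series_table <- function(ps) {
  stopifnot(is.list(ps), !is.null(ps$paths))
  contrib <- vapply(ps$paths, function(p) Re(p$contribution_zero), numeric(1))
  data.frame(
    path = vapply(ps$paths, function(p) paste(p$nodes, collapse = "->"),
                  character(1)),
    length = vapply(ps$paths, function(p) length(p$nodes) - 1L, integer(1)),
    contribution_zero = contrib,
    cumulative = cumsum(contrib))
}

#' Stability diagnostics of the hidden subnetwork
#'
#' Reports the spectral radius of \eqn{\hat V(0) = \mathrm{diag}(\gamma)
#' J_{HH}} (the sharp convergence criterion for the path series) plus, for
#' the two smallest topologies, the closed-form conditions: a single hidden
#' neuron requires \eqn{1 - \gamma_h J_{h,h} > 0}; a two-neuron loop without
#' self-couplings requires \eqn{|\gamma_3 J_{34}\,\gamma_4 J_{43}| < 1}.
#'
#' @inheritParams transfer_operator
#' @return list with `spectral_radius_zero`, `series_converges`, and (when
#'   applicable) `one_hidden_margin` (\eqn{1 - \gamma J_{hh}}) or
#'   `loop_product` (\eqn{\gamma_1 J_{12} \gamma_2 J_{21}}).
#' @export
stability_report <- function(spec, part, mf) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  h <- part$hidden
  J_HH <- spec$weights[h, h, drop = FALSE]
  rho <- spectral_radius(mf$gains * J_HH)
  out <- list(spectral_radius_zero = rho, series_converges = rho < 1)
  if (length(h) == 1L) {
    out$one_hidden_margin <- 1 - mf$gains[1] * J_HH[1, 1]
  } else if (length(h) == 2L && all(diag(J_HH) == 0)) {
    out$loop_product <- mf$gains[1] * J_HH[1, 2] * mf$gains[2] * J_HH[2, 1]
  }
  out
}
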