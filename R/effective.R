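#' Effective coupling filters in the frequency domain
#'
#' Assembles, at every grid frequency, the effective interaction matrix
#' among recorded neurons
#' \deqn{\hat J^{\rm eff}(\omega) = \hat J_{RR}(\omega) +
#'   \hat J_{RH}(\omega)\,\hat\Gamma(\omega)\,\hat J_{HR}(\omega),}
#' the true recorded-block filters plus corrections from all signal paths
#' through the hidden subnetwork. Blocks use the closed-form kernel
#' transforms.
#'
#' @inheritParams transfer_operator
#' @param gammas a transfer operator from [transfer_operator()] computed on
#'   the same grid.
#' @param grid a [frequency_grid()] (or `NULL` for zero frequency only);
#'   must match `gammas$grid`.
#' @return 3-d complex array, recorded x recorded x frequency.
#' @export
effective_coupling_freq <- function(spec, part, mf, gammas, grid = NULL) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  stopifnot(is_transfer(gammas))
  omegas <- if (is.null(grid)) 0 else grid$omegas
  if (!isTRUE(all.equal(omegas, gammas$omegas))) {
    stop_hp("invalid_argument", "transfer operator grid does not match")
  }
  r <- part$recorded
  h <- part$hidden
  nr <- length(r)
  out <- array(0i, dim = c(nr, nr, length(omegas)))

  if (length(h) == 0L) {
    for (i in seq_along(omegas)) {
      out[, , i] <- block_freq(spec, r, r, omegas[i])
    }
    return(out)
  }

  # fast path: one shared kernel for all cross-block and recorded-block pairs
  uk_rr <- uniform_kernel(spec, r, r)
  uk_rh <- uniform_kernel(spec, r, h)
  uk_hr <- uniform_kernel(spec, h, r)
  uks <- Filter(Negate(is.null), list(uk_rr, uk_rh, uk_hr))
  uniform <- length(uks) == 0L ||
    all(vapply(uks, identical, logical(1), y = uks[[1]]))
  if (uniform) {
    ghat <- if (length(uks)) kernel_freq(uks[[1]], 1, omegas)
            else rep(1 + 0i, length(omegas))
    bw <- block_weights(spec, part)
    for (i in seq_along(omegas)) {
      corr <- bw$J_RH %*% gammas$gamma_matrices[[i]] %*% bw$J_HR
      out[, , i] <- ghat[i] * bw$J_RR + ghat[i]^2 * corr
    }
  } else {
    for (i in seq_along(omegas)) {
      om <- omegas[i]
      out[, , i] <- block_freq(spec, r, r, om) +
        block_freq(spec, r, h, om) %*% gammas$gamma_matrices[[i]] %*%
          block_freq(spec, h, r, om)
    }
  }
  out
}

#' Zero-frequency effective synaptic weights
#'
#' The time-integrated effective weights
#' \eqn{\mathcal{J}^{\rm eff}_{r,r'} = \hat J^{\rm eff}_{r,r'}(0) =
#' J_{RR} + J_{RH} [I - \mathrm{diag}(\gamma) J_{HH}]^{-1}
#' \mathrm{diag}(\gamma) J_{HR}}, computed with a single real linear solve.
#' Because all kernels are normalized (\eqn{\hat g(0) = 1}), the result
#' depends only on the time-integrated weights, not on kernel shapes.
#'
#' @inheritParams transfer_operator
#' @return real matrix over recorded pairs (partition order).
#' @export
effective_weights <- function(spec, part, mf) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  check_meanfield(mf)
  bw <- block_weights(spec, part)
  if (length(part$hidden) == 0L) return(bw$J_RR)
  gam <- mf$gains
  A <- diag(length(gam)) - gam * bw$J_HH
  rhs <- gam * bw$J_HR
  Y <- tryCatch(solve(A, rhs), error = function(e) {
    stop_hp("linear_response_singular",
            "I - V(0) is singular; hidden network at a critical point")
  })
  bw$J_RR + bw$J_RH %*% Y
}

#' Full effective model of the recorded subnetwork
#'
#' One-call pipeline: solves the hidden mean field, builds the linear
#' response over a frequency grid, assembles the effective coupling filters,
#' inverse-transforms them to the time domain, and collects the effective
#' baselines and zero-frequency effective weights.
#'
#' @inheritParams transfer_operator
#' @param grid a [frequency_grid()]; default resolves an alpha-10 kernel.
#' @param control mean-field solver settings.
#' @return object of class `"hp_effective_model"` with fields `partition`,
#'   `baselines_eff`, `filters_freq` (recorded x recorded x frequency),
#'   `filters_time` (recorded x recorded x time), `weights_eff`, `grid`,
#'   `meanfield`, and `spectral_radius_zero`.
#' @export
build_effective_model <- function(spec, part, grid = frequency_grid(),
                                  control = meanfield_control()) {
  stopifnot(is_network_spec(spec))
  check_partition(spec, part)
  mf <- solve_hidden_rates(spec, part, control)
  nh <- length(part$hidden)
  fast <- nh > 0L && !is.null(.shared_kernel(spec, part))
  if (fast) {
    res <- .effective_freq_factorized(spec, part, mf, grid)
    ff <- res$filters_freq
    rho0 <- res$spectral_radius_zero
    if (is.null(ff)) fast <- FALSE # defective eigendecomposition fallback
  }
  if (!fast) {
    if (nh > 0L) {
      gam_op <- transfer_operator(spec, part, mf, grid)
      ff <- effective_coupling_freq(spec, part, mf, gam_op, grid)
      rho0 <- gam_op$spectral_radius_zero
    } else {
      ff <- effective_coupling_freq(spec, part, mf,
                                    empty_transfer(grid), grid)
      rho0 <- 0
    }
  }
  ft <- to_time_domain(ff, grid)
  weights_eff <- Re(ff[, , which.min(abs(grid$omegas)), drop = FALSE])
  dim(weights_eff) <- dim(ff)[1:2]
  structure(list(partition = part,
                 baselines_eff = effective_baselines(spec, part, mf),
                 filters_freq = ff, filters_time = ft,
                 weights_eff = weights_eff, grid = grid, meanfield = mf,
                 spectral_radius_zero = rho0),
            class = "hp_effective_model")
}

# One kernel shared by every nonzero pair across all four blocks, or NULL.
.shared_kernel <- function(spec, part) {
  r <- part$recorded
  h <- part$hidden
  uks <- list(uniform_kernel(spec, r, r), uniform_kernel(spec, r, h),
              uniform_kernel(spec, h, r), uniform_kernel(spec, h, h))
  found <- Filter(Negate(is.null), uks)
  if (length(found) == 0L) return(kernel("delta"))
  for (k in found) if (!identical(k, found[[1]])) return(NULL)
  found[[1]]
}

# Factorized frequency sweep: Jeff(w) = ghat(w) J_RR +
# ghat(w)^2 J_RH P diag(1/(1 - ghat(w) d_i)) P^-1 diag(gamma) J_HR, from one
# eigendecomposition of diag(gamma) J_HH. Memory stays O(nr^2 * n_freq).
.effective_freq_factorized <- function(spec, part, mf, grid) {
  bw <- block_weights(spec, part)
  gam <- mf$gains
  uk <- .shared_kernel(spec, part)
  omegas <- if (is.null(grid)) 0 else grid$omegas
  ghat <- kernel_freq(uk, 1, omegas)
  V0 <- gam * bw$J_HH
  eig <- eigen(V0)
  P <- eig$vectors
  B <- tryCatch(solve(P, (gam * bw$J_HR) + 0i), error = function(e) NULL)
  if (is.null(B)) {
    return(list(filters_freq = NULL,
                spectral_radius_zero = spectral_radius(V0)))
  }
  A <- bw$J_RH %*% P
  # guard against defective P: check omega = 0 correction vs direct solve
  corr0 <- Re(A %*% ((1 / (1 - eig$values)) * B))
  direct0 <- tryCatch(
    bw$J_RH %*% solve(diag(length(gam)) - V0, gam * bw$J_HR),
    error = function(e) {
      stop_hp("linear_response_singular",
              "I - V(0) is singular; hidden network at a critical point")
    })
  if (max(abs(corr0 - direct0)) >
      1e-8 * max(1, max(abs(direct0)))) {
    return(list(filters_freq = NULL,
                spectral_radius_zero = spectral_radius(V0)))
  }
  nr <- length(part$recorded)
  ff <- array(0i, dim = c(nr, nr, length(omegas)))
  for (i in seq_along(omegas)) {
    denom <- 1 - ghat[i] * eig$values
    if (any(Mod(denom) < 1e-12)) {
      stop_hp("linear_response_singular",
              sprintf("I - V(omega) singular at omega = %g", omegas[i]),
              omega = omegas[i])
    }
    ff[, , i] <- ghat[i] * bw$J_RR + ghat[i]^2 * (A %*% ((1 / denom) * B))
  }
  list(filters_freq = ff, spectral_radius_zero = spectral_radius(V0))
}

# placeholder transfer operator for hidden = empty (never indexed)
empty_transfer <- function(grid) {
  structure(list(grid = grid,
                 omegas = if (is.null(grid)) 0 else grid$omegas,
                 hidden = integer(0), gains = numeric(0),
                 v_matrices = list(), gamma_matrices = list(),
                 spectral_radius_zero = 0),
            class = "hp_transfer")
}

#' @export
print.hp_effective_model <- function(x, ...) {
  nr <- length(x$partition$recorded)
  cat(sprintf("<effective_model: %d recorded, %d hidden; rho(V(0)) = %.4g>\n",
              nr, length(x$partition$hidden), x$spectral_radius_zero))
  cat("  effective weights (zero-frequency):\n")
  print(round(x$weights_eff, 5))
  invisible(x)
}
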