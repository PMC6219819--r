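# Classed conditions so callers (ensemble pipelines in particular) can catch
# specific failure modes with tryCatch(..., hp_hidden_network_unstable = ...).
stop_hp <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    c(list(message = message, call = sys.call(-1)), extra),
    class = c(paste0("hp_", class), "hp_error", "error", "condition"))
  stop(cond)
}

warn_hp <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    c(list(message = message, call = sys.call(-1)), extra),
    class = c(paste0("hp_", class), "hp_warning", "warning", "condition"))
  warning(cond)
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministically derive a child seed from a parent seed and stream labels;
# keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}

spectral_radius <- function(m) {
  if (length(m) == 0L) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

op_norm2 <- function(m) {
  if (length(m) == 0L) return(0)
  # largest singular value; works for complex matrices
  sqrt(max(abs(eigen(Conj(t(m)) %*% m, only.values = TRUE)$values)))
}
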