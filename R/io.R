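#' Read a network specification from JSON
#'
#' Schema (1-based neuron indices throughout):
#' \preformatted{
#' {
#'   "n_neurons": 3,
#'   "rate_scale": 1.0,
#'   "baselines": [0, 0, 0.95],
#'   "nonlinearity": {"kind": "rectified_linear", "ceiling": null},
#'   "weights": [[0,0,0],[1,0,-2],[2,0,-0.9]]        // dense rows, or
#'   "weights": {"triplets": [[2,1,1.0], ...]}        // sparse (post,pre,J)
#'   "kernels": {
#'     "default":   {"family": "alpha", "rate_param": 1.0},
#'     "per_neuron": {"3": {"family": "alpha", "rate_param": 1.8}},
#'     "per_pair":  {"2,3": {"family": "alpha", "rate_param": 1.0}},
#'     "self":      {"family": "single_exp", "rate_param": 1.0}
#'   }
#' }
#' }
#'
#' @param path JSON file path.
#' @return a [network_spec()].
#' @export
load_spec <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_hp("parse_error",
                            sprintf("cannot parse '%s': %s", path,
                                    conditionMessage(e)))
                  })
  need <- function(field) {
    if (is.null(raw[[field]])) {
      stop_hp("parse_error",
              sprintf("network spec is missing required field '%s'", field))
    }
    raw[[field]]
  }
  n <- as.integer(need("n_neurons"))
  w <- need("weights")
  if (!is.null(w$triplets)) {
    W <- matrix(0, n, n)
    for (tr in w$triplets) {
      tr <- unlist(tr)
      W[tr[1], tr[2]] <- tr[3]
    }
  } else {
    W <- do.call(rbind, lapply(w, unlist))
    if (!is.numeric(W) || any(dim(W) != n)) {
      stop_hp("parse_error", "field 'weights' is not an n x n numeric matrix")
    }
  }
  nlr <- need("nonlinearity")
  nl <- nonlinearity(nlr$kind,
                     ceiling = if (is.null(nlr$ceiling)) 2 else nlr$ceiling)
  km <- .parse_kernel_map(raw$kernels)
  network_spec(W, baselines = unlist(need("baselines")),
               rate_scale = need("rate_scale"), nonlinearity = nl,
               kernels = km)
}

.parse_kernel <- function(x) {
  if (is.null(x$family)) {
    stop_hp("parse_error", "kernel entry is missing field 'family'")
  }
  kernel(x$family, rate_param = x$rate_param)
}

.parse_kernel_map <- function(k) {
  if (is.null(k)) return(kernel_map())
  kernel_map(
    default = if (is.null(k$default)) kernel("alpha", 1)
              else .parse_kernel(k$default),
    per_neuron = if (is.null(k$per_neuron)) NULL
                 else lapply(k$per_neuron, .parse_kernel),
    per_pair = if (is.null(k$per_pair)) NULL
               else lapply(k$per_pair, .parse_kernel),
    self = if (is.null(k$self)) NULL else .parse_kernel(k$self))
}

#' Write a network specification to JSON
#'
#' Inverse of [load_spec()]; weights are stored as a sparse triplet list
#' when fewer than a quarter of the entries are nonzero.
#'
#' @param spec a [network_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_spec <- function(spec, path) {
  stopifnot(is_network_spec(spec))
  km <- spec$kernels
  ser_k <- function(k) {
    if (is.null(k)) return(NULL)
    list(family = k$family,
         rate_param = if (is.na(k$rate_param)) NULL else k$rate_param)
  }
  nz <- which(spec$weights != 0, arr.ind = TRUE)
  w <- if (nrow(nz) < spec$n_neurons^2 / 4) {
    list(triplets = lapply(seq_len(nrow(nz)), function(i) {
      c(nz[i, 1], nz[i, 2], spec$weights[nz[i, 1], nz[i, 2]])
    }))
  } else {
    apply(spec$weights, 1, identity, simplify = FALSE)
  }
  out <- list(
    n_neurons = spec$n_neurons,
    rate_scale = spec$rate_scale,
    baselines = spec$baselines,
    nonlinearity = list(kind = spec$nonlinearity$kind,
                        ceiling = if (is.na(spec$nonlinearity$ceiling)) NULL
                                  else spec$nonlinearity$ceiling),
    weights = w,
    kernels = list(default = ser_k(km$default),
                   per_neuron = if (is.null(km$per_neuron)) NULL
                                else lapply(km$per_neuron, ser_k),
                   per_pair = if (is.null(km$per_pair)) NULL
                              else lapply(km$per_pair, ser_k),
                   self = ser_k(km$self)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import / export weight matrices as headerless CSV
#'
#' @param path CSV file path.
#' @return `read_weights_csv`: numeric matrix.
#' @export
read_weights_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname read_weights_csv
#' @param weights square numeric matrix.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.table(weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Write a manifest describing a CLI run for bit-identical reproduction.
write_manifest <- function(out_dir, command, params) {
  manifest <- list(
    package = "hiddenpaths",
    version = as.character(utils::packageVersion("hiddenpaths")),
    command = command, parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
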