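#' Dense feedforward network with sigmoid activations
#'
#' Minimal from-scratch multilayer perceptron: every layer is an
#' affine transform followed by the logistic sigmoid, including the
#' output layer, so a single output unit yields a probability-like
#' score in (0,1). All parameters live in one flat weight vector so a
#' swarm optimizer can treat training as box-constrained continuous
#' optimization.
#'
#' @name neural_net
NULL

#' Network architecture specification
#'
#' @param layer_sizes Integer vector, input size first, output size
#'   last, e.g. `c(26, 16, 16, 1)`. All sizes >= 1.
#' @return A `network_spec` with `layer_sizes` and `weight_count`
#'   (`sum (fan_in + 1) * fan_out` over consecutive layer pairs).
#' @export
network_spec <- function(layer_sizes) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  wc <- sum((layer_sizes[-length(layer_sizes)] + 1L) * layer_sizes[-1L])
  structure(list(layer_sizes = layer_sizes, weight_count = wc),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec %s: %d trainable parameters>\n",
              paste(x$layer_sizes, collapse = "-"), x$weight_count))
  invisible(x)
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, computed in a form that avoids overflow for
#' large negative inputs.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1), monotone increasing in `x`.
#' @export
nn_sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Unpack a flat weight vector into per-layer matrices
#'
#' Layout is layer-major: for each consecutive layer pair, the weight
#' matrix (fan_in x fan_out, column-major) followed by the fan_out
#' biases.
#'
#' @param w Numeric vector of length `spec$weight_count`.
#' @param spec A `network_spec`.
#' @return List of layers, each `list(W, b)`.
#' @export
unflatten_weights <- function(w, spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(w) != spec$weight_count) {
    stop(sprintf("weight vector length %d != expected %d",
                 length(w), spec$weight_count), call. = FALSE)
  }
  ls <- spec$layer_sizes
  layers <- vector("list", length(ls) - 1L)
  off <- 0L
  for (l in seq_len(length(ls) - 1L)) {
    nin <- ls[l]; nout <- ls[l + 1L]
    W <- matrix(w[off + seq_len(nin * nout)], nin, nout)
    off <- off + nin * nout
    b <- w[off + seq_len(nout)]
    off <- off + nout
    layers[[l]] <- list(W = W, b = b)
  }
  layers
}

#' Flatten per-layer weights into a single vector
#'
#' Inverse of [unflatten_weights()].
#'
#' @param layers List of `list(W, b)` layers.
#' @return Flat numeric vector.
#' @export
flatten_weights <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

#' Forward pass
#'
#' @param spec A `network_spec`.
#' @param w Flat weight vector (or a layer list from
#'   [unflatten_weights()]).
#' @param X Numeric matrix, one row per sample, `spec$layer_sizes[1]`
#'   columns.
#' @return Output matrix (rows = samples, columns = output units),
#'   every entry in (0, 1).
#' @export
nn_forward <- function(spec, w, X) {
  X <- as.matrix(X)
  if (ncol(X) != spec$layer_sizes[1]) {
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(X), spec$layer_sizes[1]), call. = FALSE)
  }
  layers <- if (is.list(w)) w else unflatten_weights(w, spec)
  A <- X
  for (l in layers) {
    A <- nn_sigmoid(sweep(A %*% l$W, 2, l$b, "+"))
  }
  A
}

#' Mean squared error
#'
#' `(1/m) * sum((predicted - actual)^2)` over all `m` samples (and
#' output units).
#'
#' @param predicted,actual Equal-shaped numeric vectors or matrices.
#' @return Non-negative scalar, 0 iff the inputs are identical.
#' @export
nn_mse <- function(predicted, actual) {
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual))) {
    stop("shape mismatch between predicted and actual", call. = FALSE)
  }
  m <- nrow(predicted)
  if (m == 0) stop("empty input to mse", call. = FALSE)
  sum((predicted - actual)^2) / m
}

#' Serialize / restore a weight checkpoint
#'
#' JSON checkpoint carrying the layer sizes and the flat weight
#' vector.
#'
#' @param spec A `network_spec`.
#' @param w Flat weight vector.
#' @param path File path.
#' @return `save_weights` invisibly returns `path`; `load_weights`
#'   returns `list(spec, w)`.
#' @export
save_weights <- function(spec, w, path) {
  jsonlite::write_json(list(layer_sizes = spec$layer_sizes,
                            weights = w),
                       path, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(obj$layer_sizes)
  w <- as.numeric(obj$weights)
  if (length(w) != spec$weight_count) {
    stop("checkpoint weight length does not match its layer sizes",
         call. = FALSE)
  }
  list(spec = spec, w = w)
}
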