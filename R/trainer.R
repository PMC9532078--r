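#' Metaheuristic weight training
#'
#' Trains the feedforward network by global swarm search over the flat
#' weight vector (training MSE as fitness), optionally followed by a
#' local Adam gradient refinement. The improved optimizer with the
#' iterative chaotic map is the default search engine.
#'
#' @name trainer
NULL

#' Trainer configuration
#'
#' @param spec A `network_spec`.
#' @param N Population size (default 30).
#' @param T Optimizer iterations (default 1000).
#' @param lb,ub Per-weight search box (default \[-5, 5\]; sigmoid
#'   pre-activations on standardized features rarely benefit from
#'   larger weights).
#' @param map Chaotic map for the improved optimizer; `NULL` runs the
#'   baseline algorithm.
#' @param refine_epochs Adam refinement epochs after the swarm search
#'   (0 disables refinement).
#' @param lr Adam learning rate (default 0.001).
#' @param seed RNG seed for the run.
#' @return A `trainer_config` list.
#' @export
trainer_config <- function(spec, N = 30, T = 1000, lb = -5, ub = 5,
                           map = chaotic_map("iterative"),
                           refine_epochs = 0, lr = 0.001, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"), T >= 1, lb < ub,
            refine_epochs >= 0, lr > 0)
  structure(list(spec = spec, N = N, T = T, lb = lb, ub = ub, map = map,
                 refine_epochs = as.integer(refine_epochs), lr = lr,
                 seed = seed),
            class = "trainer_config")
}

#' Training-set fitness of a weight vector
#'
#' @param w Flat weight vector.
#' @param spec A `network_spec`.
#' @param X Feature matrix (rows = samples).
#' @param y Target vector/matrix in \[0, 1\].
#' @return Mean squared error of the forward pass against `y`.
#' @export
nn_fitness <- function(w, spec, X, y) {
  nn_mse(nn_forward(spec, w, X), y)
}

# forward with cached activations, then backprop of the MSE gradient
.nn_gradient <- function(layers, X, y) {
  m <- nrow(X)
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    acts[[l + 1]] <- nn_sigmoid(sweep(acts[[l]] %*% layers[[l]]$W, 2,
                                      layers[[l]]$b, "+"))
  }
  grads <- vector("list", length(layers))
  dA <- 2 * (acts[[length(acts)]] - y) / m
  for (l in rev(seq_along(layers))) {
    A <- acts[[l + 1]]
    dZ <- dA * A * (1 - A)
    grads[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    if (l > 1) dA <- dZ %*% t(layers[[l]]$W)
  }
  grads
}

#' Adam gradient refinement of a weight vector
#'
#' Full-batch Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) on the MSE
#' objective using analytic backpropagation gradients. Training MSE is
#' monitored each epoch; the best-seen weights are returned, so the
#' refined MSE never exceeds the incoming one.
#'
#' @param w Flat starting weight vector.
#' @param spec A `network_spec`.
#' @param X,y Training features and targets.
#' @param lr Learning rate.
#' @param epochs Number of full-batch epochs (0 returns `w` unchanged).
#' @return Refined flat weight vector.
#' @export
adam_refine <- function(w, spec, X, y, lr = 0.001, epochs = 100) {
  stopifnot(lr > 0, epochs >= 0)
  if (epochs == 0) return(w)
  X <- as.matrix(X); y <- as.matrix(y)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mvec <- numeric(length(w)); vvec <- numeric(length(w))
  best_w <- w
  best_f <- nn_fitness(w, spec, X, y)
  for (t in seq_len(epochs)) {
    layers <- unflatten_weights(w, spec)
    g <- flatten_weights(.nn_gradient(layers, X, y))
    mvec <- beta1 * mvec + (1 - beta1) * g
    vvec <- beta2 * vvec + (1 - beta2) * g^2
    mhat <- mvec / (1 - beta1^t)
    vhat <- vvec / (1 - beta2^t)
    w <- w - lr * mhat / (sqrt(vhat) + eps)
    f <- nn_fitness(w, spec, X, y)
    if (f < best_f) { best_f <- f; best_w <- w }
  }
  best_w
}

#' Train the network by swarm search (plus optional Adam refinement)
#'
#' The number of network weights sets the dimensionality of the swarm
#' search; each sparrow is a candidate flat weight vector and the
#' fitness is the training MSE. The global search runs first; Adam
#' then refines the returned weights locally when `refine_epochs > 0`.
#'
#' @param X Feature matrix (rows = samples), already standardized by
#'   the caller (see [cross_validate()]).
#' @param y Binary target vector (0/1).
#' @param config A `trainer_config`.
#' @return List with `w` (trained flat weights), `spec`, `trace`
#'   (best training MSE per optimizer iteration, non-increasing) and
#'   `train_mse`.
#' @export
train_network <- function(X, y, config) {
  stopifnot(inherits(config, "trainer_config"))
  X <- as.matrix(X); y <- as.matrix(as.numeric(y))
  spec <- config$spec
  if (ncol(X) != spec$layer_sizes[1]) {
    stop("feature count does not match the network input size",
         call. = FALSE)
  }
  objective <- function(w) nn_fitness(w, spec, X, y)
  cfg <- sparrow_config(D = spec$weight_count, lb = config$lb,
                        ub = config$ub, N = config$N, T = config$T,
                        map = config$map, seed = config$seed)
  res <- if (is.null(config$map)) run_ssa(objective, cfg)
         else run_cgssa(objective, cfg)
  w <- res$best_x
  if (config$refine_epochs > 0) {
    w <- adam_refine(w, spec, X, y, lr = config$lr,
                     epochs = config$refine_epochs)
  }
  list(w = w, spec = spec, trace = res$trace,
       train_mse = nn_fitness(w, spec, X, y))
}

#' Score samples with a trained model
#'
#' @param model List returned by [train_network()].
#' @param X Feature matrix on the same standardized scale as training.
#' @return Numeric vector of scores in (0, 1); class = score >= 0.5.
#' @export
predict_scores <- function(model, X) {
  as.numeric(nn_forward(model$spec, model$w, X))
}
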