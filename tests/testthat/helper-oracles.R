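# independent oracles used across tests

# brute-force pairwise concordance AUC (ties count 1/2)
concordance_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# numeric gradient of the training MSE w.r.t. the flat weight vector
numeric_nn_gradient <- function(w, spec, X, y, h = 1e-6) {
  vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (nn_fitness(wp, spec, X, y) - nn_fitness(wm, spec, X, y)) / (2 * h)
  }, 0)
}

# a tiny linearly separable 2-feature toy problem
toy_separable <- function(n = 20, seed = 5) {
  set.seed(seed)
  x1 <- c(stats::runif(n / 2, -2, -0.5), stats::runif(n / 2, 0.5, 2))
  x2 <- stats::runif(n, -1, 1)
  list(X = cbind(x1, x2), y = as.numeric(x1 > 0))
}
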