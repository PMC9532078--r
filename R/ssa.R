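#' Sparrow search optimization
#'
#' Population metaheuristic in which three roles share the search:
#' discoverers (best-ranked individuals, wide exploration), followers
#' (track the best discoverer) and scouts (randomly chosen individuals
#' performing anti-predation moves). The improved variant (CGSSA) adds
#' chaotic-map initialization, Gaussian mutation of better-than-average
#' individuals and chaotic perturbation of the rest, both under greedy
#' acceptance.
#'
#' @name sparrow
NULL

#' Optimizer configuration
#'
#' @param N Population size (>= 2). Default 30.
#' @param T Maximum iterations (>= 1). Default 500.
#' @param D Dimensionality of the search space.
#' @param lb,ub Box bounds, scalars or length-`D` vectors, `lb < ub`.
#' @param Pa Discoverer fraction, in (0, 1). Default 0.2.
#' @param Sa Scout fraction, in (0, 1). Default 0.2.
#' @param ST Safety value in \[0.5, 1\] switching the discoverer update
#'   between multiplicative decay (safe) and Gaussian drift (alarmed).
#'   Default 0.8.
#' @param epsilon Small constant guarding the scout denominator.
#' @param map A `chaotic_map`, or `NULL` for the baseline algorithm
#'   (uniform initialization, no mutation or perturbation).
#' @param seed Integer RNG seed; one seeded generator drives every
#'   stochastic draw of a run so results are reproducible.
#' @return A `sparrow_config` list.
#' @export
sparrow_config <- function(D, lb, ub, N = 30, T = 500, Pa = 0.2, Sa = 0.2,
                           ST = 0.8, epsilon = 1e-50, map = NULL,
                           seed = NULL) {
  stopifnot(N >= 2, T >= 1, D >= 1, Pa > 0, Pa < 1, Sa > 0, Sa < 1,
            ST >= 0.5, ST <= 1, all(lb < ub))
  if (!is.null(map)) stopifnot(inherits(map, "chaotic_map"))
  structure(list(N = as.integer(N), T = as.integer(T), D = as.integer(D),
                 lb = rep_len(lb, D), ub = rep_len(ub, D),
                 Pa = Pa, Sa = Sa, ST = ST, epsilon = epsilon,
                 map = map, seed = seed),
            class = "sparrow_config")
}

.clamp <- function(X, lb, ub) {
  # hard clamp each coordinate to the violated bound
  X <- pmax(X, matrix(lb, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(ub, nrow(X), ncol(X), byrow = TRUE))
}

.eval_pop <- function(objective, X) {
  f <- apply(X, 1, objective)
  f[!is.finite(f)] <- Inf
  f
}

# --- pure update kernels (explicit draws, for unit testing) -----------

# discoverers ranked i = 1..nd (best first); X is nd x D
.discoverer_step <- function(X, T, R2, ST, alpha, Q) {
  nd <- nrow(X)
  if (R2 < ST) {
    X * exp(-(seq_len(nd)) / (alpha * T))
  } else {
    X + Q
  }
}

# followers ranked i = 1..nf within their group; N is population size;
# A is an nf x D matrix of +-1, Q a length-nf normal vector
.follower_step <- function(X, ranks, N, xb, xw, A, Q) {
  hungry <- ranks > N / 2
  if (any(hungry)) {
    Xh <- X[hungry, , drop = FALSE]
    decay <- exp(sweep(-Xh, 2, xw, "+") / ranks[hungry]^2)
    X[hungry, ] <- Q[hungry] * decay
  }
  if (any(!hungry)) {
    Xn <- X[!hungry, , drop = FALSE]
    An <- A[!hungry, , drop = FALSE]
    # s = |x - xb| %*% A+ with A+ = t(A) / D, then broadcast over dims
    s <- rowSums(abs(sweep(Xn, 2, xb, "-")) * An) / ncol(X)
    X[!hungry, ] <- matrix(xb, sum(!hungry), ncol(X), byrow = TRUE) + s
  }
  X
}

# scouts: X is ns x D, f the scouts' fitness, fg/fw global best/worst
.scout_step <- function(X, f, fg, fw, xb, xw, beta, K, epsilon) {
  at_best <- f == fg   # exact equality: the branch targets the best one
  if (any(!at_best)) {
    Xo <- X[!at_best, , drop = FALSE]
    X[!at_best, ] <- matrix(xb, sum(!at_best), ncol(X), byrow = TRUE) +
      beta[!at_best] * abs(sweep(Xo, 2, xb, "-"))
  }
  if (any(at_best)) {
    Xb <- X[at_best, , drop = FALSE]
    step <- abs(sweep(Xb, 2, xw, "-")) / ((f[at_best] - fw) + epsilon)
    X[at_best, ] <- Xb + K[at_best] * step
  }
  X
}

# --- exported single-phase operations ---------------------------------

#' Discoverer position update
#'
#' When the warning value `R2` is below the safety value `ST`, the
#' i-th ranked discoverer decays multiplicatively,
#' `x * exp(-i / (alpha * T))` with `alpha ~ U(0, 1]` per sparrow;
#' otherwise each discoverer drifts by a standard-normal scalar added
#' to every coordinate. Positions are clamped to the box.
#'
#' @param X `nd x D` matrix of discoverer positions, best rank first.
#' @param config A `sparrow_config`.
#' @param R2 The per-iteration warning draw in \[0, 1\].
#' @return Updated position matrix.
#' @export
update_discoverers <- function(X, config, R2 = stats::runif(1)) {
  nd <- nrow(X)
  alpha <- 1 - stats::runif(nd)           # U(0, 1]
  Q <- stats::rnorm(nd)
  .clamp(.discoverer_step(X, config$T, R2, config$ST, alpha, Q),
         config$lb, config$ub)
}

#' Follower position update
#'
#' Followers ranked worse than half the population jump towards food
#' (`Q * exp((xw - x) / i^2)`); the rest move next to the best position
#' via the pseudo-inverse of a random sign vector.
#'
#' @param X `nf x D` matrix of follower positions, best rank first.
#' @param config A `sparrow_config`.
#' @param xb Current best position (after the discoverer update).
#' @param xw Current worst position.
#' @return Updated position matrix.
#' @export
update_followers <- function(X, config, xb, xw) {
  nf <- nrow(X)
  A <- matrix(sample(c(-1, 1), nf * config$D, replace = TRUE), nf, config$D)
  Q <- stats::rnorm(nf)
  .clamp(.follower_step(X, seq_len(nf), config$N, xb, xw, A, Q),
         config$lb, config$ub)
}

#' Scout (anti-predation) position update
#'
#' Scouts away from the population best move towards it with a normal
#' step on `|x - xb|`; the scout at the best position steps away from
#' the worst, scaled by its fitness gap.
#'
#' @param X `ns x D` matrix of scout positions.
#' @param f Fitness of each scout.
#' @param config A `sparrow_config`.
#' @param xb,xw Best and worst positions.
#' @param fg,fw Best and worst fitness values.
#' @return Updated position matrix.
#' @export
update_scouts <- function(X, f, config, xb, xw, fg, fw) {
  ns <- nrow(X)
  beta <- stats::rnorm(ns)
  K <- stats::runif(ns, -1, 1)
  .clamp(.scout_step(X, f, fg, fw, xb, xw, beta, K, config$epsilon),
         config$lb, config$ub)
}

#' Gaussian mutation
#'
#' Per-dimension multiplicative mutation `x * (1 + G)` with independent
#' standard-normal `G`, clamped to the box.
#'
#' @param x Position vector.
#' @param config A `sparrow_config` (for the box bounds).
#' @param G Optional fixed normal draws (length of `x`), for testing.
#' @return Mutated position.
#' @export
gaussian_mutate <- function(x, config, G = stats::rnorm(length(x))) {
  pmin(pmax(x * (1 + G), config$lb), config$ub)
}

# --- full optimization loops ------------------------------------------

.run_sparrow <- function(objective, config, improved) {
  N <- config$N; D <- config$D; T <- config$T
  lb <- config$lb; ub <- config$ub
  if (!is.null(config$seed)) set.seed(config$seed)

  if (improved) {
    stream <- chaos_stream(config$map)
    X <- chaos_to_domain(
      matrix(chaotic_sequence(stream, N * D), N, D, byrow = TRUE),
      matrix(lb, N, D, byrow = TRUE), matrix(ub, N, D, byrow = TRUE))
  } else {
    X <- matrix(stats::runif(N * D), N, D)
    X <- sweep(sweep(X, 2, ub - lb, "*"), 2, lb, "+")
  }
  f <- .eval_pop(objective, X)

  # per-sparrow greedy memory: a sparrow whose proposed move worsens its
  # fitness reverts at the end of the iteration. This memory is what
  # lets the multiplicative discoverer decay compound across hundreds
  # of iterations and drive near-underflow collapse on unimodal
  # problems.
  pX <- X; pf <- f
  best_i <- which.min(pf)
  best_x <- pX[best_i, ]; best_f <- pf[best_i]
  trace <- numeric(T)
  nd <- max(1L, round(config$Pa * N))
  ns <- max(1L, round(config$Sa * N))

  for (t in seq_len(T)) {
    ord <- order(pf)
    disc <- ord[seq_len(nd)]
    foll <- ord[seq.int(nd + 1L, N)]
    xw <- pX[ord[N], ]
    X <- pX; f <- pf

    R2 <- stats::runif(1)
    X[disc, ] <- update_discoverers(X[disc, , drop = FALSE], config, R2)
    fd <- .eval_pop(objective, X[disc, , drop = FALSE])
    f[disc] <- fd
    xb_new <- X[disc[which.min(fd)], ]   # best updated discoverer

    X[foll, ] <- update_followers(X[foll, , drop = FALSE], config,
                                  xb_new, xw)
    f[foll] <- .eval_pop(objective, X[foll, , drop = FALSE])

    fg <- min(f); fw <- max(f)
    xb <- X[which.min(f), ]; xw2 <- X[which.max(f), ]
    scouts <- sample.int(N, ns)
    X[scouts, ] <- update_scouts(X[scouts, , drop = FALSE], f[scouts],
                                 config, xb, xw2, fg, fw)
    f[scouts] <- .eval_pop(objective, X[scouts, , drop = FALSE])

    if (improved) {
      fa <- mean(f[is.finite(f)])
      if (!is.finite(fa)) fa <- Inf
      cand <- X
      mut <- f < fa
      if (any(mut)) {
        Xm <- X[mut, , drop = FALSE]
        G <- matrix(stats::rnorm(length(Xm)), nrow(Xm), ncol(Xm))
        cand[mut, ] <- .clamp(Xm * (1 + G), lb, ub)
      }
      if (any(!mut)) {
        idx <- which(!mut)
        for (i in idx) {
          xn <- chaos_to_domain(chaotic_sequence(stream, D), lb, ub)
          cand[i, ] <- pmin(pmax(chaos_perturb(X[i, ], xn), lb), ub)
        }
      }
      fc <- .eval_pop(objective, cand)
      acc <- fc < f                      # greedy acceptance
      if (any(acc)) {
        X[acc, ] <- cand[acc, , drop = FALSE]
        f[acc] <- fc[acc]
      }
    }

    imp <- f < pf
    if (any(imp)) {
      pX[imp, ] <- X[imp, , drop = FALSE]
      pf[imp] <- f[imp]
    }
    it_best <- which.min(pf)
    if (pf[it_best] < best_f) {
      best_f <- pf[it_best]
      best_x <- pX[it_best, ]
    }
    trace[t] <- best_f
  }

  list(best_x = best_x, best_f = best_f, trace = trace,
       config = config, improved = improved)
}

#' Run the baseline sparrow search algorithm
#'
#' Uniform random initialization in the box, then per iteration: rank
#' by fitness, update discoverers, followers and scouts, and track the
#' best-ever solution.
#'
#' @param objective Function mapping a length-`D` numeric vector to a
#'   scalar; non-finite values are treated as `+Inf`.
#' @param config A `sparrow_config` with `map = NULL`.
#' @return List with `best_x`, `best_f` and `trace` (best-ever fitness
#'   per iteration, non-increasing).
#' @export
run_ssa <- function(objective, config) {
  if (!is.null(config$map)) {
    stop("baseline run_ssa requires config$map = NULL; use run_cgssa",
         call. = FALSE)
  }
  .run_sparrow(objective, config, improved = FALSE)
}

#' Run the chaos + Gaussian improved sparrow search (CGSSA)
#'
#' Chaotic-map initialization, the three baseline role updates, then
#' per iteration each better-than-average individual undergoes
#' Gaussian mutation and each worse-than-average individual undergoes
#' chaotic perturbation (averaging with a fresh chaos-derived point in
#' the box), both kept only on improvement. With the iterative map
#' this is the IIGSSA variant.
#'
#' @inheritParams run_ssa
#' @param config A `sparrow_config` with a `chaotic_map` set.
#' @return As [run_ssa()].
#' @export
run_cgssa <- function(objective, config) {
  if (is.null(config$map)) {
    stop("run_cgssa requires a chaotic map in the config", call. = FALSE)
  }
  .run_sparrow(objective, config, improved = TRUE)
}
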