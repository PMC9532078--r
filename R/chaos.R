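#' Chaotic maps for population initialization and perturbation
#'
#' Nine one-dimensional chaotic recurrences used as ergodic,
#' deterministic pseudo-random sources: tent, Chebyshev, circle,
#' iterative, sine, singer, sinusoidal, logistic and cubic. Raw
#' iterates live either in \[0,1\] or \[-1,1\] depending on the map;
#' normalized sequences are rescaled to \[0,1\] and mapped affinely
#' into a search box.
#'
#' @name chaos
NULL

.chaos_defaults <- list(
  tent       = list(beta = 0.7),
  chebyshev  = list(phi = 4),
  circle     = list(),            # constants 0.2 and 0.5/(2*pi) are fixed
  iterative  = list(a = 0.7),
  sine       = list(a = 4),
  singer     = list(mu = 1.07),
  sinusoidal = list(a = 2.3),
  logistic   = list(mu = 4),
  cubic      = list(rho = 2.595)
)

# native range of the raw iterates; maps on [-1,1] are rescaled by
# (z+1)/2 when a normalized value is requested
.chaos_ranges <- list(
  tent = c(0, 1), chebyshev = c(-1, 1), circle = c(0, 1),
  iterative = c(-1, 1), sine = c(0, 1), singer = c(0, 1),
  sinusoidal = c(0, 1), logistic = c(0, 1), cubic = c(0, 1)
)

#' Construct a chaotic map
#'
#' @param name One of `"tent"`, `"chebyshev"`, `"circle"`, `"iterative"`,
#'   `"sine"`, `"singer"`, `"sinusoidal"`, `"logistic"`, `"cubic"`.
#' @param ... Named parameter overrides (e.g. `mu = 3.99` for logistic).
#' @return A `chaotic_map` object with `name`, `params`, `native_range`.
#' @details Defaults: tent beta = 0.7; Chebyshev order phi = 4;
#'   iterative a = 0.7; sine a = 4; singer mu = 1.07; sinusoidal
#'   a = 2.3; logistic mu = 4; cubic rho = 2.595. The cubic map is
#'   only chaotic for rho near 2.595; a rho below 1 is accepted but
#'   collapses to the fixed point 0 and triggers a warning.
#' @export
chaotic_map <- function(name, ...) {
  name <- match.arg(tolower(name), names(.chaos_defaults))
  params <- utils::modifyList(.chaos_defaults[[name]], list(...))
  if (name == "cubic" && params$rho < 1) {
    warning("cubic map with rho < 1 is not chaotic (collapses to 0)",
            call. = FALSE)
  }
  if (name == "logistic" && (params$mu < 0 || params$mu > 4)) {
    stop("logistic mu must lie in [0, 4]", call. = FALSE)
  }
  if (name == "singer" && (params$mu <= 0.9 || params$mu >= 1.08)) {
    stop("singer mu must lie in (0.9, 1.08)", call. = FALSE)
  }
  structure(list(name = name, params = params,
                 native_range = .chaos_ranges[[name]]),
            class = "chaotic_map")
}

#' @export
print.chaotic_map <- function(x, ...) {
  p <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "fixed constants"
  cat(sprintf("<chaotic_map %s (%s), native range [%g, %g]>\n",
              x$name, p, x$native_range[1], x$native_range[2]))
  invisible(x)
}

#' One application of a chaotic recurrence
#'
#' @param map A `chaotic_map`.
#' @param z Current state, inside the map's native range (nonzero for
#'   the iterative map).
#' @return The next raw state.
#' @export
iterate_map <- function(map, z) {
  stopifnot(inherits(map, "chaotic_map"))
  r <- map$native_range
  if (!is.finite(z) || z < r[1] || z > r[2]) {
    stop(sprintf("state %g outside native range [%g, %g] of %s map",
                 z, r[1], r[2], map$name), call. = FALSE)
  }
  p <- map$params
  switch(map$name,
    tent = if (z < p$beta) z / p$beta else (1 - z) / (1 - p$beta),
    chebyshev = cos(p$phi * acos(z)),
    circle = (z + 0.2 - (0.5 / (2 * pi)) * sin(2 * pi * z)) %% 1,
    iterative = {
      if (z == 0) stop("iterative map undefined at z = 0", call. = FALSE)
      sin(p$a * pi / z)
    },
    sine = (p$a / 4) * sin(pi * z),
    singer = p$mu * (7.86 * z - 23.31 * z^2 + 28.75 * z^3 -
                       13.302875 * z^4),
    sinusoidal = p$a * z^2 * sin(pi * z),
    logistic = p$mu * z * (1 - z),
    cubic = p$rho * z * (1 - z^2)
  )
}

.chaos_normalize <- function(map, z) {
  if (map$native_range[1] < 0) (z + 1) / 2 else z
}

# admissible fresh state drawn from the ongoing RNG stream, avoiding
# fixed points / absorbing states (0, 1 and band edges)
.chaos_seed_state <- function(map) {
  z <- stats::runif(1, 0.01, 0.99)
  # logistic fixed point 1 - 1/mu, tent fixed point 0; a uniform draw
  # hits these with probability zero, but re-draw if degenerate anyway
  for (k in 1:100) {
    z2 <- iterate_map(map, z)
    if (is.finite(z2) && abs(z2 - z) > 1e-12) return(z)
    z <- stats::runif(1, 0.01, 0.99)
  }
  z
}

#' Create a resumable chaotic stream
#'
#' @param map A `chaotic_map`.
#' @param z0 Initial raw state; when `NULL`, drawn uniformly from
#'   (0.01, 0.99) using the current RNG stream.
#' @return A `chaos_stream` environment holding the map and state.
#' @export
chaos_stream <- function(map, z0 = NULL) {
  stopifnot(inherits(map, "chaotic_map"))
  e <- new.env(parent = emptyenv())
  e$map <- map
  e$z <- if (is.null(z0)) .chaos_seed_state(map) else z0
  class(e) <- "chaos_stream"
  e
}

#' Draw normalized chaotic values from a stream
#'
#' Advances the stream by `n` iterations and returns the normalized
#' (\[0,1\]) iterates. Degenerate absorbing states (e.g. logistic at
#' exactly 0 or 1) are escaped by re-seeding from the RNG stream.
#'
#' @param stream A `chaos_stream`.
#' @param n Number of values, at least 1.
#' @return Numeric vector of length `n` with values in \[0, 1\].
#' @export
chaotic_sequence <- function(stream, n) {
  stopifnot(inherits(stream, "chaos_stream"), n >= 1)
  map <- stream$map
  r <- map$native_range
  out <- numeric(n)
  z <- stream$z
  for (k in seq_len(n)) {
    if (map$name == "iterative" && abs(z) < 1e-300) z <- .chaos_seed_state(map)
    z <- iterate_map(map, z)
    if (!is.finite(z)) {
      z <- .chaos_seed_state(map)
      z <- iterate_map(map, z)
    }
    if (z < r[1] || z > r[2]) {
      # e.g. the singer polynomial dips marginally below 0 near z = 1:
      # clamp the emitted value and restart from a fresh RNG state
      out[k] <- .chaos_normalize(map, min(max(z, r[1]), r[2]))
      z <- .chaos_seed_state(map)
      next
    }
    out[k] <- .chaos_normalize(map, z)
    # absorbing fixed points (logistic/cubic/sine at exactly 0) would
    # freeze the stream; escape via the RNG
    if (z == 0 && map$name %in% c("logistic", "cubic", "sine", "sinusoidal",
                                  "tent")) {
      z <- .chaos_seed_state(map)
    }
  }
  stream$z <- z
  out
}

#' Map a normalized chaotic value into a search interval
#'
#' Affine placement of `c` in \[0,1\] onto \[`m_min`, `m_max`\].
#'
#' @param c Value(s) in \[0, 1\].
#' @param m_min,m_max Interval bounds, `m_min <= m_max`. Either scalars
#'   or vectors recycled against `c`.
#' @return `m_min + c * (m_max - m_min)`.
#' @export
chaos_to_domain <- function(c, m_min, m_max) {
  if (any(c < 0 | c > 1)) stop("chaotic value outside [0, 1]", call. = FALSE)
  if (any(m_min > m_max)) stop("m_min must not exceed m_max", call. = FALSE)
  m_min + c * (m_max - m_min)
}

#' Chaotic perturbation of a solution
#'
#' Averages a solution with a chaos-derived point mapped into the box:
#' elementwise `(x_prime + x_n) / 2`.
#'
#' @param x_prime The individual being perturbed.
#' @param x_n The chaos-derived perturbation point.
#' @return Numeric vector of the same length.
#' @export
chaos_perturb <- function(x_prime, x_n) {
  if (length(x_prime) != length(x_n)) {
    stop("length mismatch in chaotic perturbation", call. = FALSE)
  }
  (x_prime + x_n) / 2
}

#' Chaotic population initialization
#'
#' Draws an initial state from the RNG, iterates the map `N * D` times,
#' normalizes the iterates to \[0,1\] and maps them affinely into the
#' box, filling the population row by row.
#'
#' @param map A `chaotic_map`.
#' @param N Population size.
#' @param D Dimensionality.
#' @param lb,ub Box bounds (scalars or length-`D` vectors).
#' @param seed Optional integer; when given, `set.seed(seed)` is called.
#' @return `N x D` numeric matrix with every entry inside the box.
#' @export
chaotic_init_population <- function(map, N, D, lb, ub, seed = NULL) {
  stopifnot(N >= 1, D >= 1, all(lb < ub))
  if (!is.null(seed)) set.seed(seed)
  stream <- chaos_stream(map)
  vals <- chaotic_sequence(stream, N * D)
  X <- matrix(vals, nrow = N, ncol = D, byrow = TRUE)
  lo <- rep_len(lb, D); hi <- rep_len(ub, D)
  sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
}
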