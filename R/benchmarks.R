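#' Benchmark objective functions
#'
#' A fixed suite of fourteen classical box-constrained minimization
#' problems (Sphere, Schwefel 2.21/2.22, Rosenbrock, Step, Quartic,
#' Alpine, Rastrigin, Sum squares, Ackley, Matyas, Levi N.13, Booth,
#' Three-Hump camel) used to compare optimizer variants. All have
#' known minimum value 0.
#'
#' @name benchmarks
NULL

# evaluator bodies; each takes a numeric vector and returns a scalar.
# Quartic additionally takes `noise`, a scalar drawn by the caller.
.bench_evals <- list(
  sphere = function(x) sum(x^2),
  schwefel221 = function(x) max(abs(x)),
  schwefel222 = function(x) sum(abs(x)) + prod(abs(x)),
  rosenbrock = function(x) {
    d <- length(x)
    sum(100 * (x[-1] - x[-d]^2)^2 + (x[-d] - 1)^2)
  },
  step = function(x) sum(floor(x + 0.5)^2),
  quartic = function(x, noise = 0) sum(seq_along(x) * x^4) + noise,
  alpine = function(x) sum(abs(x * sin(x) + 0.1 * x)),
  rastrigin = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
  sumsquares = function(x) sum(seq_along(x) * x^2),
  ackley = function(x) {
    d <- length(x)
    -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
      20 + exp(1)
  },
  matyas = function(x) 0.26 * (x[1]^2 + x[2]^2) - 0.48 * x[1] * x[2],
  levi = function(x) {
    sin(3 * pi * x[1])^2 +
      (x[1] - 1)^2 * (1 + sin(3 * pi * x[2])^2) +
      (x[2] - 1)^2 * (1 + sin(2 * pi * x[2])^2)
  },
  booth = function(x) (x[1] + 2 * x[2] - 7)^2 + (2 * x[1] + x[2] - 5)^2,
  threehump = function(x) {
    2 * x[1]^2 - 1.05 * x[1]^4 + x[1]^6 / 6 + x[1] * x[2] + x[2]^2
  }
)

.bench_table <- data.frame(
  id = paste0("F", 1:14),
  name = c("Sphere", "Schwefel 2.21", "Schwefel 2.22", "Rosenbrock",
           "Step", "Quartic", "Alpine", "Rastrigin", "Sum squares",
           "Ackley", "Matyas", "Levi", "Booth", "Three-Hump"),
  key = c("sphere", "schwefel221", "schwefel222", "rosenbrock", "step",
          "quartic", "alpine", "rastrigin", "sumsquares", "ackley",
          "matyas", "levi", "booth", "threehump"),
  dimension = c(rep(30L, 10L), rep(2L, 4L)),
  lower = c(-100, -100, -10, -30, -100, -1.28, -10, -5.12, -10, -100,
            -10, -10, -10, -10),
  upper = c(100, 100, 10, 30, 100, 1.28, 10, 5.12, 10, 100,
            10, 10, 10, 10),
  optimum = rep(0, 14L),
  stochastic = c(rep(FALSE, 5L), TRUE, rep(FALSE, 8L)),
  stringsAsFactors = FALSE
)

# textbook minimizers (NULL where a closed-form single point is not used)
.bench_minimizers <- list(
  sphere = function(d) rep(0, d),
  schwefel221 = function(d) rep(0, d),
  schwefel222 = function(d) rep(0, d),
  rosenbrock = function(d) rep(1, d),
  step = function(d) rep(0, d),
  quartic = function(d) rep(0, d),
  alpine = function(d) rep(0, d),
  rastrigin = function(d) rep(0, d),
  sumsquares = function(d) rep(0, d),
  ackley = function(d) rep(0, d),
  matyas = function(d) c(0, 0),
  levi = function(d) c(1, 1),
  booth = function(d) c(1, 3),
  threehump = function(d) c(0, 0)
)

#' Look up one benchmark function
#'
#' @param id Function id `"F1"`..`"F14"`, or a name such as `"Ackley"`
#'   (case-insensitive).
#' @return An object of class `benchmark_fn`: a list with `id`, `name`,
#'   `dimension`, `lower`, `upper`, `optimum`, `stochastic`,
#'   `known_minimizer` and the evaluator `fn`.
#' @examples
#' f <- benchmark_fn("F10")
#' evaluate_benchmark(f, rep(0, 30))
#' @export
benchmark_fn <- function(id) {
  tab <- .bench_table
  i <- match(tolower(id), tolower(tab$id))
  if (is.na(i)) i <- match(tolower(id), tolower(tab$name))
  if (is.na(i)) stop("unknown benchmark function: ", id, call. = FALSE)
  key <- tab$key[i]
  structure(list(
    id = tab$id[i], name = tab$name[i], dimension = tab$dimension[i],
    lower = tab$lower[i], upper = tab$upper[i], optimum = tab$optimum[i],
    stochastic = tab$stochastic[i],
    known_minimizer = .bench_minimizers[[key]](tab$dimension[i]),
    fn = .bench_evals[[key]]
  ), class = "benchmark_fn")
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf("<benchmark_fn %s: %s, d=%d, box [%g, %g], optimum %g>\n",
              x$id, x$name, x$dimension, x$lower, x$upper, x$optimum))
  invisible(x)
}

#' Evaluate a benchmark function at a point
#'
#' @param fn A `benchmark_fn`.
#' @param x Numeric vector of length `fn$dimension`.
#' @param noise For the stochastic Quartic function, whether to add the
#'   uniform \[0,1) noise term. Ignored for deterministic functions.
#' @return Scalar function value. When `noise = TRUE` the current RNG
#'   state is consumed by one `runif()` draw.
#' @export
evaluate_benchmark <- function(fn, x, noise = TRUE) {
  stopifnot(inherits(fn, "benchmark_fn"))
  if (length(x) != fn$dimension) {
    stop(sprintf("dimension mismatch: expected %d, got %d",
                 fn$dimension, length(x)), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite input coordinates", call. = FALSE)
  if (fn$stochastic) {
    fn$fn(x, noise = if (noise) stats::runif(1) else 0)
  } else {
    fn$fn(x)
  }
}

#' The full benchmark registry
#'
#' @return List of 14 `benchmark_fn` objects in suite order F1..F14:
#'   ten 30-dimensional problems followed by four 2-dimensional ones.
#' @export
benchmark_registry <- function() {
  lapply(.bench_table$id, benchmark_fn)
}

#' Export the registry as JSON
#'
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON description of each function's id, name, dimension, bounds and
#'   optimum (invisibly when written to file).
#' @keywords internal
registry_json <- function(path = NULL) {
  tab <- .bench_table[, c("id", "name", "dimension", "lower", "upper",
                          "optimum")]
  if (is.null(path)) {
    jsonlite::toJSON(tab, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
  }
}

#' Objective closure for the optimizer
#'
#' Wraps a benchmark function as `f(x) -> value` for [run_ssa()] /
#' [run_cgssa()]; the Quartic noise term is drawn from the run's RNG
#' stream.
#'
#' @inheritParams evaluate_benchmark
#' @return A function of one numeric vector.
#' @export
benchmark_objective <- function(fn, noise = TRUE) {
  force(fn); force(noise)
  function(x) evaluate_benchmark(fn, x, noise = noise)
}
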