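#' Benchmark experiment harness
#'
#' Runs the 10-variant x 14-function x 20-repeat comparison: the
#' baseline algorithm plus nine chaotic-map-improved variants, with
#' paired seeds across variants, and summarizes best/mean/sd of the
#' final fitness per cell.
#'
#' @name harness
NULL

.variant_names <- c("ssa", "tent", "chebyshev", "circle", "iterative",
                    "sine", "singer", "sinusoidal", "logistic", "cubic")

#' Run one (function, variant) experiment cell
#'
#' @param fn A `benchmark_fn` or an id accepted by [benchmark_fn()].
#' @param variant `"ssa"` for the baseline, or a chaotic-map name for
#'   the improved algorithm.
#' @param repeats Number of independent runs (default 20). Repeat `r`
#'   uses seed `base_seed + r - 1`, so variants sharing a base seed are
#'   paired.
#' @param base_seed First seed of the run sequence.
#' @param N,T,Pa,Sa,ST Optimizer settings (defaults: population 30,
#'   500 iterations, discoverer and scout fractions 0.2).
#' @param sd_population Use the population standard deviation
#'   (divisor n) as in the summary convention; `FALSE` gives the
#'   sample sd.
#' @return A `run_summary` list: `function_id`, `variant`, `repeats`,
#'   `best_value`, `mean_value`, `std_value`, per-run `finals` and the
#'   list of convergence `traces`.
#' @export
run_experiment <- function(fn, variant, repeats = 20, base_seed = 1,
                           N = 30, T = 500, Pa = 0.2, Sa = 0.2, ST = 0.8,
                           sd_population = TRUE) {
  if (!inherits(fn, "benchmark_fn")) fn <- benchmark_fn(fn)
  variant <- match.arg(tolower(variant), .variant_names)
  stopifnot(repeats >= 1)
  map <- if (variant == "ssa") NULL else chaotic_map(variant)
  finals <- numeric(repeats)
  traces <- vector("list", repeats)
  obj <- benchmark_objective(fn)
  for (r in seq_len(repeats)) {
    cfg <- sparrow_config(D = fn$dimension, lb = fn$lower, ub = fn$upper,
                          N = N, T = T, Pa = Pa, Sa = Sa, ST = ST,
                          map = map, seed = base_seed + r - 1L)
    res <- if (is.null(map)) run_ssa(obj, cfg) else run_cgssa(obj, cfg)
    finals[r] <- res$best_f
    traces[[r]] <- res$trace
  }
  sdv <- if (repeats == 1) 0 else {
    if (sd_population) sqrt(mean((finals - mean(finals))^2))
    else stats::sd(finals)
  }
  structure(list(function_id = fn$id, function_name = fn$name,
                 variant = variant, repeats = repeats,
                 best_value = min(finals), mean_value = mean(finals),
                 std_value = sdv, finals = finals, traces = traces),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary %s/%s: %d repeats, best %.4g, mean %.4g, sd %.4g>\n",
              x$function_id, x$variant, x$repeats, x$best_value,
              x$mean_value, x$std_value))
  invisible(x)
}

#' Compare optimizer variants over benchmark functions
#'
#' @param functions Character vector of function ids (default all 14).
#' @param variants Character vector of variant names (default all 10).
#' @param repeats Runs per cell.
#' @param base_seed Shared base seed so comparisons are paired.
#' @param ... Further settings passed to [run_experiment()].
#' @return A data frame with one row per (function, variant):
#'   best/mean/sd of final fitness plus `is_best`, flagging the
#'   per-function minimum of each statistic column.
#' @export
compare_variants <- function(functions = .bench_table$id,
                             variants = .variant_names,
                             repeats = 20, base_seed = 1, ...) {
  stopifnot(length(functions) >= 1, length(variants) >= 1)
  rows <- list()
  for (fid in functions) {
    for (v in variants) {
      s <- run_experiment(fid, v, repeats = repeats, base_seed = base_seed,
                          ...)
      rows[[length(rows) + 1L]] <- data.frame(
        function_id = s$function_id, variant = s$variant,
        repeats = s$repeats, best_value = s$best_value,
        mean_value = s$mean_value, std_value = s$std_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$is_best <- stats::ave(out$best_value, out$function_id,
                            FUN = function(v) v == min(v)) > 0
  out
}

#' Format a results table in scientific notation
#'
#' Renders best/mean/sd to 4 significant digits (e.g. `4.441E-16`),
#' the usual presentation style for benchmark tables.
#'
#' @param results Data frame from [compare_variants()].
#' @return Data frame of formatted strings.
#' @export
format_results <- function(results) {
  fmt <- function(v) ifelse(v == 0, "0", toupper(sprintf("%.3E", v)))
  data.frame(function_id = results$function_id, variant = results$variant,
             best_value = fmt(results$best_value),
             mean_value = fmt(results$mean_value),
             std_value = fmt(results$std_value),
             is_best = results$is_best, stringsAsFactors = FALSE)
}

#' Write convergence traces to CSV files
#'
#' @param summary A `run_summary`.
#' @param dir Output directory; files are named
#'   `<function>_<variant>_<rep>.csv` with columns iteration,
#'   best_fitness.
#' @return Invisibly, the written paths.
#' @export
export_traces <- function(summary, dir) {
  stopifnot(inherits(summary, "run_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(summary$repeats)
  for (r in seq_len(summary$repeats)) {
    tr <- summary$traces[[r]]
    paths[r] <- file.path(dir, sprintf("%s_%s_%d.csv", summary$function_id,
                                       summary$variant, r))
    utils::write.csv(data.frame(iteration = seq_along(tr),
                                best_fitness = tr),
                     paths[r], row.names = FALSE)
  }
  invisible(paths)
}
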