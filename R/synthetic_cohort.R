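#' Synthetic esophageal-cancer-like cohort
#'
#' Generates cohorts that reproduce the marginal summaries of a
#' 398-patient esophageal-cancer feature schema: 21 continuous
#' features (17 blood indicators, tumor length/width/thickness, age)
#' drawn from range-truncated normals, 5 categorical features drawn at
#' the published proportions, and a binary survival outcome with a
#' configurable feature-to-outcome signal. The real cohort is private;
#' these synthetic cohorts make the full training/evaluation pipeline
#' testable, but carry no clinical claims. The feature correlation
#' structure defaults to independence.
#'
#' @name synthetic_cohort
NULL

# continuous feature summaries: mean, variance, admissible range.
# The published summary lists sixteen named blood indicators while
# stating there are seventeen; "HCT" below is a synthetic stand-in for
# the unnamed seventeenth (hematocrit-like, fraction of blood volume).
.cont_specs <- local({
  m <- rbind(
    tumor_length    = c(4.112,    3.208,    1,      11),
    tumor_width     = c(2.649,    1.148,    0.3,    9),
    tumor_thickness = c(1.1776,   0.471,    0.1,    8),
    WBC             = c(6.5366,   3.6958,   2.5,    13.6),
    LY              = c(1.7622,   0.3652,   0,      4),
    MONO            = c(0.3899,   0.06661,  0,      1.4),
    NEUT            = c(4.0011,   2.8097,   0,      9.8),
    EOS             = c(0.1238,   0.0198,   0,      0.9),
    BASO            = c(0.04163,  0.005549, 0,      5),
    RBC             = c(4.43,     0.2289,   2.73,   5.75),
    HB              = c(137.4347, 223.7577, 64,     169),
    PLT             = c(236.8518, 52.606,   100,    448),
    TP              = c(71.0377,  54.4092,  50,     92),
    ALB             = c(42.0201,  25.1281,  26,     59),
    GLB             = c(29.1533,  28.8656,  16,     45),
    PT              = c(10.2271,  2.4610,   7,      16.6),
    APTT            = c(35.9095,  52.9934,  15.4,   62.2),
    TT              = c(15.3420,  2.9607,   10.9,   21.3),
    FIB             = c(387.3433, 985.7021, 167.613, 774.433),
    HCT             = c(0.41,     0.0016,   0.20,   0.55),
    age             = c(60,       70.099,   38,     82)
  )
  colnames(m) <- c("mean", "variance", "min", "max")
  m
})

.cat_specs <- list(
  gender = c(Male = 247, Female = 151),
  differentiation = c(Poorly = 158, Moderately = 217, Highly = 23),
  tumor_site = c(Lower = 78, Mid = 267, Upper = 53),
  transfer = c(Negative = 200, Positive = 198),
  tnm_stage = c(I = 39, II = 172, III = 166, IV = 21)
)

.status_counts <- c(live = 101, dead = 297)

#' Default cohort schema
#'
#' @return A `cohort_schema`: list of per-feature specs (26 features)
#'   plus the two outcome specs (survival status at the 25/75
#'   live/dead split; survival time, integer years 0-11).
#' @export
default_schema <- function() {
  feats <- c(
    lapply(rownames(.cont_specs), function(nm) {
      v <- .cont_specs[nm, ]
      list(name = nm, kind = "continuous", mean = v[["mean"]],
           variance = v[["variance"]], min = v[["min"]], max = v[["max"]])
    }),
    lapply(names(.cat_specs), function(nm) {
      cnt <- .cat_specs[[nm]]
      list(name = nm, kind = "categorical", labels = names(cnt),
           counts = unname(cnt), probs = unname(cnt) / sum(cnt))
    })
  )
  names(feats) <- vapply(feats, `[[`, "", "name")
  structure(list(
    features = feats,
    outcomes = list(
      survival_status = list(labels = names(.status_counts),
                             counts = unname(.status_counts),
                             probs = unname(.status_counts) / 398),
      survival_time = list(min = 0L, max = 11L)
    )
  ), class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat(sprintf("<cohort_schema: %d features (%d continuous, %d categorical) + 2 outcomes>\n",
              length(x$features), sum(kinds == "continuous"),
              sum(kinds == "categorical")))
  invisible(x)
}

# inverse-CDF sampling from a range-truncated normal, parameterized by
# the parent (untruncated) mean/variance
.rtruncnorm <- function(n, mean, variance, lo, hi) {
  sd <- sqrt(variance)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(q, lo), hi)   # guard qnorm round-off at the edges
}

#' Default feature-to-outcome signal
#'
#' Positive death-log-odds on TNM stage, transfer-positive status and
#' tumor length, applied to standardized (ordinal-coded) features.
#' Directions were chosen for face validity; magnitudes are sized so
#' the Bayes-optimal linear score has AUC near 0.9 against the
#' latent logistic noise (sd(eta) close to 3 vs noise sd pi/sqrt(3)),
#' i.e. a strong, learnable signal clearly separable from a
#' label-permuted control. They are not claims about the real cohort.
#'
#' @return Named numeric vector of logistic coefficients.
#' @export
default_signal <- function() {
  c(tnm_stage = 2.0, transfer = 1.5, tumor_length = 1.5)
}

# ordinal-code a cohort column: factor levels in schema order -> 1..k
.feature_numeric <- function(col) {
  if (is.factor(col)) as.numeric(col) else as.numeric(col)
}

#' Generate a synthetic cohort
#'
#' Continuous features are drawn from truncated normals matching the
#' schema's mean/variance/range; categorical features follow the
#' schema proportions (or the exact published counts when
#' `exact_counts` and `n = 398`). Survival status follows a logistic
#' model on standardized features with the supplied coefficients;
#' all-zero coefficients reduce to the marginal 25/75 live/dead split.
#' Survival time is drawn consistently with status (dead implies
#' shorter time).
#'
#' @param schema A `cohort_schema` (default [default_schema()]).
#' @param n Number of records (>= 10).
#' @param seed Integer seed; when given, `set.seed(seed)` is called.
#' @param signal Named coefficient vector (death log-odds per standard
#'   deviation of the named feature); default [default_signal()]. Use
#'   `signal = c()` or zeros for a null cohort.
#' @param exact_counts When `TRUE` (requires `n = 398`), every
#'   categorical count and the 101/297 live/dead split are matched
#'   exactly; the signal then determines *which* records die via the
#'   latent ordering.
#' @return A data.frame of class `clinical_cohort` with 26 feature
#'   columns plus `survival_time` (integer years) and
#'   `survival_status` (factor live/dead).
#' @export
generate_cohort <- function(schema = default_schema(), n = 398,
                            seed = NULL, signal = default_signal(),
                            exact_counts = FALSE) {
  stopifnot(inherits(schema, "cohort_schema"), n >= 10)
  if (exact_counts && n != 398) {
    stop("exact_counts requires n = 398 (the published cohort size)",
         call. = FALSE)
  }
  if (length(signal)) {
    bad <- setdiff(names(signal), names(schema$features))
    if (length(bad)) {
      stop("unknown signal coefficient name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  cols <- list()
  for (fs in schema$features) {
    if (fs$kind == "continuous") {
      cols[[fs$name]] <- .rtruncnorm(n, fs$mean, fs$variance, fs$min,
                                     fs$max)
    } else {
      v <- if (exact_counts) {
        sample(rep(fs$labels, fs$counts))
      } else {
        sample(fs$labels, n, replace = TRUE, prob = fs$probs)
      }
      cols[[fs$name]] <- factor(v, levels = fs$labels)
    }
  }

  # latent death score: logistic intercept at the marginal split plus
  # the configured signal on standardized feature codes
  eta <- rep(stats::qlogis(schema$outcomes$survival_status$probs[
    schema$outcomes$survival_status$labels == "dead"]), n)
  for (nm in names(signal)) {
    x <- .feature_numeric(cols[[nm]])
    s <- stats::sd(x)
    if (s > 0) eta <- eta + signal[[nm]] * (x - mean(x)) / s
  }
  latent <- eta + stats::qlogis(stats::runif(n))
  dead <- if (exact_counts) {
    rank(-latent, ties.method = "first") <= .status_counts[["dead"]]
  } else {
    latent > 0
  }
  status <- factor(ifelse(dead, "dead", "live"), levels = c("live", "dead"))
  stime <- integer(n)
  stime[dead] <- sample(0:4, sum(dead), replace = TRUE)
  stime[!dead] <- sample(5:11, sum(!dead), replace = TRUE)

  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  out$survival_time <- stime
  out$survival_status <- status
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' Numeric feature matrix for model input
#'
#' Encodes the 26 feature columns as a numeric matrix (categorical
#' features as ordinal level codes 1..k), dropping the outcome
#' columns.
#'
#' @param cohort A `clinical_cohort` data.frame.
#' @return Numeric matrix, one column per feature.
#' @export
cohort_features <- function(cohort) {
  feat_cols <- setdiff(names(cohort), c("survival_time", "survival_status"))
  as.matrix(as.data.frame(lapply(cohort[feat_cols], .feature_numeric)))
}

#' Binary outcome vector
#'
#' @param cohort A `clinical_cohort`.
#' @return Numeric 0/1 vector with death (the majority class) coded 1.
#' @export
cohort_labels <- function(cohort) {
  as.numeric(cohort$survival_status == "dead")
}

#' Summarize a cohort against its schema
#'
#' @param cohort A `clinical_cohort` (or any data.frame with the same
#'   columns).
#' @return List with `continuous` (mean, median, min, max, variance
#'   per numeric feature) and `categorical` (counts and percentages
#'   per level).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  num_cols <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  cont <- do.call(rbind, lapply(num_cols, function(nm) {
    x <- cohort[[nm]]
    data.frame(feature = nm, mean = mean(x), median = stats::median(x),
               min = min(x), max = max(x), variance = stats::var(x),
               stringsAsFactors = FALSE)
  }))
  fac_cols <- names(cohort)[vapply(cohort, is.factor, TRUE)]
  cat_ <- do.call(rbind, lapply(fac_cols, function(nm) {
    tab <- table(cohort[[nm]])
    data.frame(feature = nm, level = names(tab), count = as.integer(tab),
               percent = round(100 * as.integer(tab) / nrow(cohort)),
               stringsAsFactors = FALSE)
  }))
  list(continuous = cont, categorical = cat_)
}

#' Write / read a cohort CSV
#'
#' @param cohort A `clinical_cohort`.
#' @param path CSV file path.
#' @return `write_cohort` invisibly returns `path`; `read_cohort`
#'   returns a `clinical_cohort` with categorical columns restored as
#'   factors in schema level order.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(names(.cat_specs), "survival_status")
  miss <- setdiff(c(rownames(.cont_specs), need, "survival_time"),
                  names(df))
  if (length(miss)) {
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(.cat_specs)) {
    df[[nm]] <- factor(df[[nm]], levels = names(.cat_specs[[nm]]))
  }
  df$survival_status <- factor(df$survival_status,
                               levels = c("live", "dead"))
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' Export the schema as JSON
#'
#' @param schema A `cohort_schema`.
#' @param path Optional output file.
#' @return JSON string, or (invisibly) `path` when written.
#' @export
schema_json <- function(schema = default_schema(), path = NULL) {
  if (is.null(path)) {
    jsonlite::toJSON(unclass(schema), auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
  }
}
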