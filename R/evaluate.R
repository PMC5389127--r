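# Pairwise comparison of two annotation sets and the benchmark statistics
# sensitivity, precision and F1.

#' Comparison counts between a test and a reference annotation set
#'
#' @param tp,fp,fn Non-negative integer counts: hits found by both methods
#'   (true positives), found only by the method under test (false
#'   positives), and found only by the reference (false negatives).
#' @param mode Optional label of the hit-key granularity.
#' @return An `annotation_comparison` object.
#' @examples
#' comparison_counts(tp = 1546, fp = 296, fn = 220) |> glance()
#' @export
comparison_counts <- function(tp, fp, fn, mode = "protein") {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  structure(
    list(tp = tp, fp = fp, fn = fn, mode = mode,
         n_test = tp + fp, n_reference = tp + fn),
    class = "annotation_comparison"
  )
}

#' Compare two annotation sets
#'
#' Computes true positives (hit keys found by both methods), false
#' positives (found only by the test method) and false negatives (found
#' only by the reference). The default hit key is the protein accession;
#' `mode = "protein_family"` keys on (accession, family) pairs for finer
#' audits.
#'
#' @param test,reference Annotation sets: a `hotpep_annotations` object, a
#'   data frame with an `accession` (and for family mode `family`) column,
#'   or a character vector of keys.
#' @param mode `"protein"` (default) or `"protein_family"`.
#' @return An `annotation_comparison` object.
#' @examples
#' compare_annotations(c("a", "b", "c"), c("b", "c", "d")) |> tidy()
#' @export
compare_annotations <- function(test, reference,
                                mode = c("protein", "protein_family")) {
  mode <- match.arg(mode)
  t_keys <- hit_keys(test, mode)
  r_keys <- hit_keys(reference, mode)
  comparison_counts(
    tp = length(intersect(t_keys, r_keys)),
    fp = length(setdiff(t_keys, r_keys)),
    fn = length(setdiff(r_keys, t_keys)),
    mode = mode
  )
}

hit_keys <- function(x, mode) {
  if (inherits(x, "hotpep_annotations")) x <- x$hits
  if (is.character(x)) return(unique(x))
  if (!is.data.frame(x) || !"accession" %in% names(x)) {
    abort("annotation set must be a character vector or have an `accession` column")
  }
  if (mode == "protein") {
    unique(x$accession)
  } else {
    if (!"family" %in% names(x)) {
      abort("`mode = \"protein_family\"` needs a `family` column")
    }
    unique(paste(x$accession, x$family, sep = "\t"))
  }
}

#' Annotation benchmark statistics
#'
#' `sensitivity()` is TP/(TP+FN), `precision()` is TP/(TP+FP) (positive
#' predictive value), and `f1()` is 2TP/(2TP+FP+FN), the harmonic mean of
#' sensitivity and precision. Each errors when its denominator is zero.
#'
#' @param x An `annotation_comparison` (from [compare_annotations()] or
#'   [comparison_counts()]).
#' @return A single number in `[0, 1]`.
#' @examples
#' x <- comparison_counts(tp = 1546, fp = 296, fn = 220)
#' round_half_up(sensitivity(x), 2)  # 0.88
#' round_half_up(precision(x), 2)    # 0.84
#' round_half_up(f1(x), 2)           # 0.86
#' @export
sensitivity <- function(x) {
  stopifnot(inherits(x, "annotation_comparison"))
  if (x$tp + x$fn == 0) abort("sensitivity undefined: TP + FN = 0")
  x$tp / (x$tp + x$fn)
}

#' @rdname sensitivity
#' @export
precision <- function(x) {
  stopifnot(inherits(x, "annotation_comparison"))
  if (x$tp + x$fp == 0) abort("precision undefined: TP + FP = 0")
  x$tp / (x$tp + x$fp)
}

#' @rdname sensitivity
#' @export
f1 <- function(x) {
  stopifnot(inherits(x, "annotation_comparison"))
  if (2 * x$tp + x$fp + x$fn == 0) abort("F1 undefined: all counts zero")
  2 * x$tp / (2 * x$tp + x$fp + x$fn)
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (0.845 -> 0.85 at 2 digits),
#' matching how the benchmark tables are printed; R's own `round()` rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.annotation_comparison <- function(x, ...) {
  cat(sprintf("<annotation_comparison> (%s keys) TP %d, FP %d, FN %d\n",
              x$mode, x$tp, x$fp, x$fn))
  cat(sprintf("  sensitivity %.2f  precision %.2f  F1 %.2f\n",
              round_half_up(sensitivity(x), 2),
              round_half_up(precision(x), 2),
              round_half_up(f1(x), 2)))
  invisible(x)
}

#' @rdname sensitivity
#' @param ... Unused.
#' @method tidy annotation_comparison
#' @export
tidy.annotation_comparison <- function(x, ...) {
  tibble(
    metric = c("true_positives", "false_positives", "false_negatives",
               "sensitivity", "precision", "f1"),
    value = c(x$tp, x$fp, x$fn, sensitivity(x), precision(x), f1(x))
  )
}

#' @rdname sensitivity
#' @method glance annotation_comparison
#' @export
glance.annotation_comparison <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    n_test = x$n_test, n_reference = x$n_reference,
    sensitivity = sensitivity(x), precision = precision(x), f1 = f1(x)
  )
}

#' @rdname sensitivity
#' @param object An `annotation_comparison`.
#' @method autoplot annotation_comparison
#' @export
autoplot.annotation_comparison <- function(object, ...) {
  df <- tibble(
    metric = factor(c("sensitivity", "precision", "F1"),
                    levels = c("sensitivity", "precision", "F1")),
    value = c(sensitivity(object), precision(object), f1(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Annotation agreement")
}

#' Combine comparisons across datasets
#'
#' Two combining rules are computed and both reported, since neither is
#' canonical: `pooled` sums the raw counts before computing F1;
#' `mean` averages the per-dataset F1 values.
#'
#' @param comparisons A list of `annotation_comparison` objects.
#' @return A one-row tibble with `f1_pooled` and `f1_mean`.
#' @export
combine_comparisons <- function(comparisons) {
  stopifnot(length(comparisons) > 0,
            all(vapply(comparisons, inherits, logical(1),
                       "annotation_comparison")))
  pooled <- comparison_counts(
    tp = sum(vapply(comparisons, `[[`, integer(1), "tp")),
    fp = sum(vapply(comparisons, `[[`, integer(1), "fp")),
    fn = sum(vapply(comparisons, `[[`, integer(1), "fn"))
  )
  tibble(
    f1_pooled = f1(pooled),
    f1_mean = mean(vapply(comparisons, f1, numeric(1)))
  )
}

#' Benchmark-table layout for several methods
#'
#' Lays out several comparisons side by side in the conventional benchmark
#' shape: rows are annotated-protein count, TP, FP, FN, sensitivity,
#' precision and F1; one column per method. Statistics are rounded to two
#' decimals, half up.
#'
#' @param comparisons A named list of `annotation_comparison` objects.
#' @return A tibble with a `statistic` column and one column per method.
#' @export
comparison_table <- function(comparisons) {
  stopifnot(length(comparisons) > 0, !is.null(names(comparisons)))
  cols <- map(comparisons, function(x) {
    c(x$n_test, x$tp, x$fp, x$fn,
      round_half_up(sensitivity(x), 2),
      round_half_up(precision(x), 2),
      round_half_up(f1(x), 2))
  })
  bind_cols(
    tibble(statistic = c("annotated", "true_positives", "false_positives",
                         "false_negatives", "sensitivity", "precision",
                         "f1")),
    as_tibble(cols)
  )
}
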