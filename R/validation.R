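#' Gold-standard validation 2x2 table
#'
#' Cross-classification of subjects in a validation sub-study by their true
#' event status (gold standard) and the event status assigned by the record
#' linkage. The four cells are: `tp` true positives (event, linked), `fp`
#' false positives (no event, linked), `fn` false negatives (event, missed)
#' and `tn` true negatives (no event, not linked).
#'
#' Both margins must be populated: `tp + fn > 0` (some true events) and
#' `tn + fp > 0` (some true non-events), otherwise sensitivity or
#' specificity is undefined.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `validation_table`.
#' @examples
#' # NSW prisoner mortality validation sub-study
#' validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
#' @export
validation_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("validation table cells must be non-negative integers", call. = FALSE)
  }
  if (tp + fn <= 0) stop("no true events (tp + fn = 0): sensitivity undefined",
                         call. = FALSE)
  if (tn + fp <= 0) stop("no true non-events (tn + fp = 0): specificity undefined",
                         call. = FALSE)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "validation_table")
}

#' @export
print.validation_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(`linked` = c("yes", "no"),
                              `true event` = c("yes", "no")))
  cat("Validation 2x2 table (rows: linked, cols: true event)\n")
  print(m)
  acc <- estimate_accuracy(x)
  cat(sprintf("  sensitivity = %d/%d = %.4f\n",
              as.integer(x$tp), as.integer(x$tp + x$fn), acc$sensitivity))
  cat(sprintf("  specificity = %d/%d = %.4f\n",
              as.integer(x$tn), as.integer(x$tn + x$fp), acc$specificity))
  invisible(x)
}

#' Estimate linkage sensitivity and specificity from a validation table
#'
#' Point estimates are the usual binomial proportions:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP).
#'
#' @param table A [validation_table()].
#' @return A [linkage_accuracy()] object.
#' @examples
#' tab <- validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
#' estimate_accuracy(tab) # SE 0.884, SP 0.997
#' @export
estimate_accuracy <- function(table) {
  stopifnot(inherits(table, "validation_table"))
  linkage_accuracy(table$tp / (table$tp + table$fn),
                   table$tn / (table$tn + table$fp))
}

#' Confidence intervals for linkage sensitivity and specificity
#'
#' Exact Clopper-Pearson intervals (the default) guarantee at least nominal
#' coverage, which matters for the small event margins typical of validation
#' sub-studies; Wilson score intervals are available as a shorter
#' alternative.
#'
#' @param table A [validation_table()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (exact, via [stats::binom.test()]) or
#'   `"wilson"` (score, via [stats::prop.test()] without continuity
#'   correction).
#' @return A list with elements `sensitivity` and `specificity`, each a named
#'   numeric vector `c(estimate, lower, upper)`, plus `level` and `method`.
#' @examples
#' tab <- validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
#' accuracy_ci(tab)
#' @export
accuracy_ci <- function(table, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(table, "validation_table"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  method <- match.arg(method)
  one_margin <- function(x, n) {
    ci <- switch(method,
      "clopper-pearson" = stats::binom.test(x, n, conf.level = level)$conf.int,
      "wilson" = stats::prop.test(x, n, conf.level = level,
                                  correct = FALSE)$conf.int)
    c(estimate = x / n, lower = ci[1], upper = ci[2])
  }
  list(sensitivity = one_margin(table$tp, table$tp + table$fn),
       specificity = one_margin(table$tn, table$tn + table$fp),
       level = level, method = method)
}
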