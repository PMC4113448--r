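#' Linkage accuracy: sensitivity and specificity of a record linkage
#'
#' Bundles the two error probabilities of a linkage process treated as a
#' diagnostic test for the outcome: the *sensitivity* SE (probability that a
#' true event is detected by the linkage) and the *specificity* SP
#' (probability that a person with no event is not falsely linked to one).
#'
#' Both values are proportions in (0, 1]. The identifiability condition
#' SE + SP > 1, required by the inverse adjustment ([adjust_events()]), is
#' deliberately *not* enforced at construction: the forward model is well
#' defined without it. Use [is_identifiable()] to check it.
#'
#' @param sensitivity Probability of detecting a true event; in (0, 1].
#'   May be given as a percent string such as `"88.4%"`.
#' @param specificity Probability of not detecting an absent event; in (0, 1].
#'   Same notation accepted.
#' @return An object of class `linkage_accuracy`: a list with numeric
#'   elements `sensitivity` and `specificity`.
#' @seealso [estimate_accuracy()] to estimate these from a validation table,
#'   [parse_accuracy_value()] for the accepted notations.
#' @examples
#' linkage_accuracy(0.884, 0.997)
#' linkage_accuracy("88.4%", "99.7%")
#' @export
linkage_accuracy <- function(sensitivity, specificity) {
  se <- parse_accuracy_value(sensitivity, what = "sensitivity")
  sp <- parse_accuracy_value(specificity, what = "specificity")
  structure(list(sensitivity = se, specificity = sp),
            class = "linkage_accuracy")
}

#' Parse a sensitivity/specificity value
#'
#' Accepts a proportion in (0, 1] or a percent string (`"88.4%"`). Bare
#' numbers greater than 1 are rejected with a hint rather than silently
#' divided by 100, because the two conventions are easy to confuse.
#'
#' @param x A single numeric proportion or a character scalar, optionally
#'   with a trailing `%`.
#' @param what Label used in error messages.
#' @return A numeric proportion in (0, 1].
#' @examples
#' parse_accuracy_value("99.7%")
#' parse_accuracy_value(0.997)
#' @export
parse_accuracy_value <- function(x, what = "accuracy value") {
  if (length(x) != 1L || is.na(x)) {
    stop(what, " must be a single non-missing value", call. = FALSE)
  }
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("%$", x)) {
      val <- suppressWarnings(as.numeric(sub("%$", "", x))) / 100
    } else {
      val <- suppressWarnings(as.numeric(x))
    }
    if (is.na(val)) stop("cannot parse ", what, " from '", x, "'", call. = FALSE)
    x <- val
  }
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (x > 1) {
    stop(what, " = ", x, " is greater than 1; proportions are expected. ",
         "If you meant a percentage, write it as \"", x, "%\"", call. = FALSE)
  }
  if (x <= 0) {
    stop(what, " must be in (0, 1], got ", x, call. = FALSE)
  }
  as.numeric(x)
}

#' Is an accuracy pair identifiable for inverse adjustment?
#'
#' The inverse adjustment divides by SE + SP - 1; the estimated true count is
#' only identifiable when that denominator is positive, i.e. the linkage is
#' better than uninformative.
#'
#' @param acc A [linkage_accuracy()] object.
#' @return `TRUE` if `sensitivity + specificity > 1`.
#' @export
is_identifiable <- function(acc) {
  stopifnot(inherits(acc, "linkage_accuracy"))
  acc$sensitivity + acc$specificity > 1
}

assert_identifiable <- function(acc) {
  if (!is_identifiable(acc)) {
    stop("non-identifiable linkage accuracy: sensitivity (",
         acc$sensitivity, ") + specificity (", acc$specificity,
         ") must exceed 1 for the inverse adjustment", call. = FALSE)
  }
  invisible(acc)
}

#' @export
print.linkage_accuracy <- function(x, ...) {
  cat("Linkage accuracy\n")
  cat(sprintf("  sensitivity: %.4g\n", x$sensitivity))
  cat(sprintf("  specificity: %.4g\n", x$specificity))
  if (!is_identifiable(x)) {
    cat("  note: SE + SP <= 1 -- inverse adjustment not identifiable\n")
  }
  invisible(x)
}
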