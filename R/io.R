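#' Read a strata counts table
#'
#' Reads a CSV with one row per stratum and columns `stratum`, `n`,
#' `observed_events` and optionally `expected_events`. Each row is
#' validated (non-negative counts, `observed_events <= n`, positive
#' `expected_events`); violations are reported with the offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame with one row per stratum.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("stratum,n,observed_events,expected_events",
#'              "psych,3919,467,85.25",
#'              "none,72444,4247,1183.43"), path)
#' read_counts_table(path)
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    stop("empty input: no data rows in ", path, call. = FALSE)
  }
  required <- c("stratum", "n", "observed_events")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_e <- "expected_events" %in% names(df)
  for (i in seq_len(nrow(df))) {
    row_id <- paste0("row ", i, " (stratum '", df$stratum[i], "')")
    num <- c(n = df$n[i], observed_events = df$observed_events[i])
    if (has_e) num <- c(num, expected_events = df$expected_events[i])
    bad <- names(num)[!is.finite(suppressWarnings(as.numeric(num)))]
    if (length(bad) > 0) {
      stop("non-numeric value in column(s) ", paste(bad, collapse = ", "),
           " at ", row_id, call. = FALSE)
    }
    if (df$n[i] <= 0) stop("n must be positive at ", row_id, call. = FALSE)
    if (df$observed_events[i] < 0) {
      stop("observed_events must be non-negative at ", row_id, call. = FALSE)
    }
    if (df$observed_events[i] > df$n[i]) {
      stop("observed_events (", df$observed_events[i], ") exceeds n (",
           df$n[i], ") at ", row_id, call. = FALSE)
    }
    if (has_e && df$expected_events[i] <= 0) {
      stop("expected_events must be positive at ", row_id, call. = FALSE)
    }
  }
  df
}

#' Read a validation 2x2 table from file
#'
#' Accepts a one-row CSV with columns `tp,fp,fn,tn` or a JSON object with
#' those keys.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A [validation_table()].
#' @export
read_validation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) != 1) {
      stop("validation-table CSV must have exactly one data row", call. = FALSE)
    }
    as.list(df)
  }
  missing_cells <- setdiff(c("tp", "fp", "fn", "tn"), names(rec))
  if (length(missing_cells) > 0) {
    stop("validation table is missing cell(s): ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  }
  validation_table(rec$tp, rec$fp, rec$fn, rec$tn)
}

#' Read a forward-scenario configuration file
#'
#' Key-value config (JSON, or YAML when the yaml package is installed) with
#' keys `n_exposed`, `n_non_exposed`, `incidence_exposed`,
#' `incidence_non_exposed`, `sensitivity`, `specificity`. Accuracy values
#' may use percent notation (`"88.4%"`).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A list with elements `scenario` (an [exposure_scenario()]) and
#'   `accuracy` (a [linkage_accuracy()]).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the yaml package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  keys <- c("n_exposed", "n_non_exposed", "incidence_exposed",
            "incidence_non_exposed", "sensitivity", "specificity")
  missing_keys <- setdiff(keys, names(cfg))
  if (length(missing_keys) > 0) {
    stop("scenario config is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  list(scenario = scenario_from_incidence(cfg$n_exposed, cfg$n_non_exposed,
                                          cfg$incidence_exposed,
                                          cfg$incidence_non_exposed),
       accuracy = linkage_accuracy(cfg$sensitivity, cfg$specificity))
}

#' Flatten a result object into a report list
#'
#' Produces the named list of numbers (full precision plus display values)
#' that [write_report()] serialises. Methods exist for the adjustment and
#' accuracy result classes; data frames pass through unchanged.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A named list (or the data frame itself).
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.data.frame <- function(x, ...) x

#' @export
as_report.linkage_accuracy <- function(x, ...) {
  list(sensitivity = x$sensitivity, specificity = x$specificity,
       identifiable = is_identifiable(x))
}

#' @export
as_report.adjusted_estimate <- function(x, ...) {
  out <- list(value = x$value, display = x$display, status = x$status)
  if (!is.null(x$interval)) {
    out$interval_lower <- x$interval[1]
    out$interval_upper <- x$interval[2]
  }
  out
}

#' @export
as_report.adjusted_smr <- function(x, ...) {
  list(unadjusted_smr = x$unadjusted,
       unadjusted_smr_display = round(x$unadjusted, 1),
       adjusted_smr = x$adjusted$value,
       adjusted_smr_display = round(x$adjusted$value, 1),
       adjusted_events = x$adjusted_events$value,
       adjusted_events_display = x$adjusted_events$display,
       expected_events = x$expected_events,
       status = x$adjusted$status)
}

#' @export
as_report.adjusted_rr <- function(x, ...) {
  list(unadjusted_rr = x$unadjusted,
       unadjusted_rr_display = round(x$unadjusted, 2),
       adjusted_rr = x$adjusted$value,
       adjusted_rr_display = x$adjusted$display,
       adjusted_events_exposed = x$adjusted_events_exposed$value,
       adjusted_events_non_exposed = x$adjusted_events_non_exposed$value,
       status = x$adjusted$status)
}

#' Write an analysis report
#'
#' Serialises a result object (or a plain list/data frame) to JSON or CSV.
#' JSON carries full precision and round-trips losslessly via
#' [read_report()]; display values follow the package's reporting
#' conventions (ratios to 2 decimals, SMRs to 1, counts truncated toward
#' zero). Non-tabular results are written to CSV as key,value pairs.
#'
#' @param results A result object, named list or data frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  rep <- if (is.data.frame(results) || (is.list(results) &&
             is.null(attr(results, "class")))) {
    results
  } else {
    as_report(results)
  }
  if (format == "json") {
    # 17 significant digits: doubles round-trip bit-exactly
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows")
  } else {
    if (is.data.frame(rep)) {
      utils::write.csv(rep, path, row.names = FALSE)
    } else {
      utils::write.csv(
        data.frame(key = names(rep),
                   value = vapply(rep, function(v) as.character(v[1]),
                                  character(1))),
        path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return The deserialised list or data frame.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}
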