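#' Historical-trial effect tables
#'
#' A `trial_dataset` holds one row per randomized comparison: a summary
#' relative treatment effect `y` on the log odds-ratio or log hazard-ratio
#' scale (negative favours the new treatment), its standard error `se`
#' (treated as known), a `disease_area` label, and optionally a
#' `comparison_type` ("active_vs_inactive" or "active_vs_active"), an
#' `outcome_type` ("binary", "survival" or "continuous") and a publication
#' `year`.  The object is a plain data frame carrying an `area_index`
#' attribute that maps each distinct non-missing disease area to a
#' contiguous integer index used by the hierarchical model.
#'
#' @param x A data frame with (at least) columns `study_id`, `y`, `se`,
#'   `disease_area`.  Optional columns: `comparison_type`, `outcome_type`,
#'   `year`.
#' @return An object of class `trial_dataset`.
#' @seealso [read_trial_dataset()], [filter_for_analysis()],
#'   [simulate_trial_dataset()]
#' @export
trial_dataset <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("study_id", "y", "se", "disease_area")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("trial_dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (opt in c("comparison_type", "outcome_type", "year"))
    if (!opt %in% names(x)) x[[opt]] <- rep(NA, nrow(x))
  x$study_id <- as.character(x$study_id)
  x$y <- as.numeric(x$y)
  x$se <- as.numeric(x$se)
  x$disease_area <- as.character(x$disease_area)
  x$comparison_type <- as.character(x$comparison_type)
  x$outcome_type <- as.character(x$outcome_type)
  x$year <- suppressWarnings(as.integer(x$year))
  validate_trial_dataset(x)
  x <- x[, c(required, "comparison_type", "outcome_type", "year")]
  attr(x, "area_index") <- build_area_index(x$disease_area)
  class(x) <- c("trial_dataset", "data.frame")
  x
}

build_area_index <- function(areas) {
  labs <- unique(areas[!is.na(areas)])
  stats::setNames(seq_along(labs), labs)
}

validate_trial_dataset <- function(x) {
  bad_y <- which(!is.finite(x$y))
  if (length(bad_y) > 0L)
    stop("non-finite effect estimate y for study_id(s): ",
         paste(x$study_id[bad_y], collapse = ", "), call. = FALSE)
  bad_se <- which(!is.finite(x$se) | x$se <= 0)
  if (length(bad_se) > 0L)
    stop("standard error must be finite and > 0; offending study_id(s): ",
         paste(x$study_id[bad_se], collapse = ", "), call. = FALSE)
  known_cmp <- c("active_vs_inactive", "active_vs_active")
  bad_cmp <- which(!is.na(x$comparison_type) & !x$comparison_type %in% known_cmp)
  if (length(bad_cmp) > 0L)
    stop("comparison_type must be one of ", paste(known_cmp, collapse = ", "),
         "; offending study_id(s): ",
         paste(x$study_id[bad_cmp], collapse = ", "), call. = FALSE)
  known_out <- c("binary", "survival", "continuous")
  bad_out <- which(!is.na(x$outcome_type) & !x$outcome_type %in% known_out)
  if (length(bad_out) > 0L)
    stop("outcome_type must be one of ", paste(known_out, collapse = ", "),
         "; offending study_id(s): ",
         paste(x$study_id[bad_out], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  idx <- attr(x, "area_index")
  cat("Trial effect dataset: ", nrow(x), " comparisons, ",
      length(idx), " disease area(s)\n", sep = "")
  n_missing <- sum(is.na(x$disease_area))
  if (n_missing > 0L)
    cat("  (", n_missing, " record(s) with missing disease area)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Area index of a trial dataset
#'
#' @param x A [trial_dataset()].
#' @return Named integer vector mapping disease-area labels to the
#'   contiguous indices used in model fitting.
#' @export
area_index <- function(x) {
  stopifnot(inherits(x, "trial_dataset"))
  attr(x, "area_index")
}

#' Read a trial-effect table from a delimited text file
#'
#' Reads a comma-separated file (header row mandatory, UTF-8) into a
#' [trial_dataset()].  Arbitrary file headers are adapted through
#' `column_map`; empty fields and any token in `na_tokens` are treated as
#' missing.  Rows with non-numeric `y` or `se` are rejected with row-level
#' diagnostics, and continuous-outcome rows can be dropped on read.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping canonical field names
#'   (`study_id`, `y`, `se`, `disease_area`, `comparison_type`,
#'   `outcome_type`, `year`) to the file's column headers.  Fields absent
#'   from the map default to a same-named column when present.
#' @param na_tokens Character vector of tokens read as missing values.
#' @param exclude_continuous If `TRUE`, rows with `outcome_type ==
#'   "continuous"` are dropped; the number dropped is recorded in the
#'   `"n_continuous_removed"` attribute of the result.
#' @return A [trial_dataset()].
#' @export
read_trial_dataset <- function(path, column_map = NULL,
                               na_tokens = c("", "NA"),
                               exclude_continuous = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = na_tokens, check.names = FALSE,
                         colClasses = "character")
  canonical <- c("study_id", "y", "se", "disease_area",
                 "comparison_type", "outcome_type", "year")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0L)
      stop("column_map names must be canonical fields; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    map[names(column_map)] <- unname(column_map)
  }
  need <- c("study_id", "y", "se", "disease_area")
  absent <- need[!map[need] %in% names(raw)]
  if (length(absent) > 0L)
    stop("input file lacks mapped column(s): ",
         paste(sprintf("%s (expected header '%s')", absent, map[absent]),
               collapse = ", "), call. = FALSE)
  out <- data.frame(study_id = raw[[map["study_id"]]],
                    stringsAsFactors = FALSE)
  for (f in c("y", "se")) {
    v <- raw[[map[f]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L)
      stop("non-numeric ", f, " in row(s) ", paste(bad, collapse = ", "),
           " (study_id: ", paste(out$study_id[bad], collapse = ", "), ")",
           call. = FALSE)
    out[[f]] <- num
  }
  out$disease_area <- raw[[map["disease_area"]]]
  for (f in c("comparison_type", "outcome_type", "year"))
    out[[f]] <- if (map[f] %in% names(raw)) raw[[map[f]]] else NA
  if (exclude_continuous) {
    drop <- !is.na(out$outcome_type) & out$outcome_type == "continuous"
    out <- out[!drop, , drop = FALSE]
    ds <- trial_dataset(out)
    attr(ds, "n_continuous_removed") <- sum(drop)
    return(ds)
  }
  trial_dataset(out)
}

#' Write a trial-effect table to CSV
#'
#' Inverse of [read_trial_dataset()]: missing values are written as empty
#' fields so that a write/read round trip reproduces the dataset
#' field-for-field.
#'
#' @param data A [trial_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_dataset <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the analysis inclusion filters
#'
#' Removes records with missing disease area, then removes every disease
#' area with fewer than `min_per_area` records (the conventional minimum
#' for estimating between-trial heterogeneity; areas with exactly
#' `min_per_area` are kept).  Returns the filtered dataset together with a
#' `filter_report` reconciling the counts.
#'
#' @param data A [trial_dataset()].
#' @param min_per_area Minimum records per disease area (default 5).
#' @return A list with elements `data` (filtered [trial_dataset()]) and
#'   `report` (a `filter_report`).
#' @export
filter_for_analysis <- function(data, min_per_area = 5L) {
  stopifnot(inherits(data, "trial_dataset"))
  if (min_per_area < 1L) stop("min_per_area must be >= 1", call. = FALSE)
  n_input <- nrow(data)
  keep1 <- !is.na(data$disease_area)
  n_missing <- sum(!keep1)
  d1 <- as.data.frame(data)[keep1, , drop = FALSE]
  counts <- table(d1$disease_area)
  small <- names(counts)[counts < min_per_area]
  keep2 <- !d1$disease_area %in% small
  n_small <- sum(!keep2)
  d2 <- d1[keep2, , drop = FALSE]
  report <- structure(list(n_input = n_input,
                           n_missing_area_removed = n_missing,
                           n_small_area_removed = n_small,
                           areas_removed = small,
                           n_output = nrow(d2)),
                      class = "filter_report")
  if (nrow(d2) == 0L) {
    warning("all records removed by the analysis filters; ",
            "returning an empty dataset", call. = FALSE)
    out <- structure(d2, area_index = stats::setNames(integer(0), character(0)),
                     class = c("trial_dataset", "data.frame"))
    return(list(data = out, report = report))
  }
  list(data = trial_dataset(d2), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Analysis filter report\n")
  cat("  records in:              ", x$n_input, "\n")
  cat("  missing disease area:   -", x$n_missing_area_removed, "\n")
  cat("  small-area removals:    -", x$n_small_area_removed,
      if (length(x$areas_removed) > 0L)
        paste0("  (", paste(x$areas_removed, collapse = ", "), ")") else "",
      "\n")
  cat("  records out:             ", x$n_output, "\n")
  invisible(x)
}

#' Serialize a filter report as JSON
#'
#' @param x A `filter_report` from [filter_for_analysis()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
filter_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "filter_report"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Summarize dataset composition
#'
#' Tabulates record counts and percentages per disease area and per
#' comparison type, in the style of a study-characteristics table.
#'
#' @param data A [trial_dataset()].
#' @return A `composition_summary`: list with `n_total`, `areas` (data
#'   frame with `disease_area`, `n`, `pct`) and `comparison` (data frame
#'   with `comparison_type`, `n`, `pct`).  Percentages are computed on the
#'   full record count and rounded to one decimal.
#' @export
summarize_composition <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  n_total <- nrow(data)
  tab_pct <- function(v) {
    lab <- ifelse(is.na(v), "(missing)", v)
    counts <- table(lab)
    data.frame(level = names(counts), n = as.integer(counts),
               pct = if (n_total > 0L)
                 round(100 * as.integer(counts) / n_total, 1) else numeric(length(counts)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  areas <- tab_pct(data$disease_area)
  names(areas)[1L] <- "disease_area"
  cmp <- tab_pct(data$comparison_type)
  names(cmp)[1L] <- "comparison_type"
  structure(list(n_total = n_total, areas = areas, comparison = cmp),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Dataset composition (", x$n_total, " comparisons)\n", sep = "")
  cat("Disease areas:\n")
  print.data.frame(x$areas, row.names = FALSE)
  cat("Comparison types:\n")
  print.data.frame(x$comparison, row.names = FALSE)
  invisible(x)
}
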