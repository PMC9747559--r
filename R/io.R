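#' Read and write the pipeline TSV formats
#'
#' Submissions travel as a five-column TSV (`variant_key`, `submitter_id`,
#' `classification`, `assertion_criteria_met`, `submission_date`,
#' ISO-8601); comparison records as a nine-column TSV (`variant_key`,
#' `consensus_binary`, `manual_class`, `automated_class`, `case_count`,
#' `manual_criteria`, `automated_criteria`, `flags`, `manual_date`).
#' Criteria sets are comma-separated `code:source` tokens; flags are
#' semicolon-separated flag names.  Malformed rows abort the run with a
#' validation error naming the offending line; writing then reading gives
#' back equal records.
#'
#' @param path Path to a TSV file.
#' @return `read_submissions()` and `read_comparisons()` return validated
#'   data frames (empty files with a header yield zero-row frames).
#' @name pipeline_io
NULL

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort_validation("file not found: %s", path)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = NULL,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_validation("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", "))
  }
  df
}

# header is line 1, so data row i sits on file line i + 1
bad_line <- function(path, i, msg, ...) {
  abort_validation("%s line %d: %s", path, i + 1L, sprintf(msg, ...))
}

parse_date_col <- function(x, path, col) {
  out <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  bad <- which(is.na(out) | format(out, "%Y-%m-%d") != x)
  if (length(bad) > 0) {
    bad_line(path, bad[1], "unparseable %s '%s' (expected YYYY-MM-DD)",
             col, x[bad[1]])
  }
  out
}

#' @rdname pipeline_io
#' @export
read_submissions <- function(path) {
  cols <- c("variant_key", "submitter_id", "classification",
            "assertion_criteria_met", "submission_date")
  df <- read_tsv_checked(path, cols)[, cols, drop = FALSE]
  if (nrow(df) == 0) {
    df$assertion_criteria_met <- logical(0)
    df$submission_date <- as.Date(character(0))
    return(df)
  }
  empty <- which(!nzchar(df$variant_key) | !nzchar(df$submitter_id))
  if (length(empty) > 0) {
    bad_line(path, empty[1], "variant_key and submitter_id must be non-empty")
  }
  bad_cls <- which(!df$classification %in% classification_levels())
  if (length(bad_cls) > 0) {
    bad_line(path, bad_cls[1], "invalid classification '%s'",
             df$classification[bad_cls[1]])
  }
  bad_acm <- which(!df$assertion_criteria_met %in% c("TRUE", "FALSE"))
  if (length(bad_acm) > 0) {
    bad_line(path, bad_acm[1], "assertion_criteria_met must be TRUE or FALSE")
  }
  df$assertion_criteria_met <- df$assertion_criteria_met == "TRUE"
  df$submission_date <- parse_date_col(df$submission_date, path,
                                       "submission_date")
  dup <- which(duplicated(df[, c("variant_key", "submitter_id")]))
  if (length(dup) > 0) {
    bad_line(path, dup[1], "duplicate (variant_key, submitter_id) pair '%s'/'%s'",
             df$variant_key[dup[1]], df$submitter_id[dup[1]])
  }
  df
}

#' @rdname pipeline_io
#' @export
read_comparisons <- function(path) {
  cols <- c("variant_key", "consensus_binary", "manual_class",
            "automated_class", "case_count", "manual_criteria",
            "automated_criteria", "flags", "manual_date")
  df <- read_tsv_checked(path, cols)[, cols, drop = FALSE]
  if (nrow(df) == 0) {
    df$case_count <- integer(0)
    df$manual_date <- as.Date(character(0))
    return(df)
  }
  bad_bin <- which(!df$consensus_binary %in% c("positive", "negative"))
  if (length(bad_bin) > 0) {
    bad_line(path, bad_bin[1], "invalid consensus_binary '%s'",
             df$consensus_binary[bad_bin[1]])
  }
  for (col in c("manual_class", "automated_class")) {
    bad <- which(!df[[col]] %in% classification_levels())
    if (length(bad) > 0) {
      bad_line(path, bad[1], "invalid %s '%s'", col, df[[col]][bad[1]])
    }
  }
  cc <- suppressWarnings(as.integer(df$case_count))
  bad_cc <- which(is.na(cc) | cc < 1 | as.character(cc) != df$case_count)
  if (length(bad_cc) > 0) {
    bad_line(path, bad_cc[1], "case_count '%s' is not a positive integer",
             df$case_count[bad_cc[1]])
  }
  df$case_count <- cc
  for (col in c("manual_criteria", "automated_criteria")) {
    for (i in seq_len(nrow(df))) {
      ok <- tryCatch({parse_criteria(df[[col]][i]); TRUE},
                     acmgconcord_validation_error = function(e) e)
      if (!isTRUE(ok)) {
        bad_line(path, i, "bad %s: %s", col, conditionMessage(ok))
      }
    }
  }
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({record_flags(df[i, , drop = FALSE]); TRUE},
                   acmgconcord_validation_error = function(e) e)
    if (!isTRUE(ok)) {
      bad_line(path, i, "bad flags: %s", conditionMessage(ok))
    }
  }
  df$manual_date <- parse_date_col(df$manual_date, path, "manual_date")
  dup <- which(duplicated(df$variant_key))
  if (length(dup) > 0) {
    bad_line(path, dup[1], "duplicate variant_key '%s'",
             df$variant_key[dup[1]])
  }
  df
}

write_tsv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @param submissions,comparisons Data frames in the schemas above.
#' @export
write_submissions <- function(submissions, path) {
  write_tsv(submissions, path)
}

#' @rdname pipeline_io
#' @export
write_comparisons <- function(comparisons, path) {
  write_tsv(comparisons, path)
}

#' Write a rendered report to an output directory
#'
#' Emits `report.txt` (the plain-text report) plus one TSV per table
#' (`funnel.tsv`, `per_variant.tsv`, `per_case.tsv`, `categories.tsv`).
#' Output is byte-identical across runs on identical input.
#'
#' @param report A [render_report()] result.
#' @param dir Output directory; created if needed.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "report.txt")
  writeLines(report$text, paths)
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    if (nm == "categories") {
      tab <- rbind(tab, data.frame(category = "total",
                                   count = attr(tab, "total"),
                                   percent = if (attr(tab, "total") > 0) 100.0
                                             else NA_real_))
    }
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(tab, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
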