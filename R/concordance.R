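#' Round half away from zero
#'
#' Percentage rounding used in all printed tables: one decimal,
#' round-half-up (0.05 rounds to 0.1), unlike base [round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Six-month currency rule for manual interpretations
#'
#' A manual interpretation is considered current for six calendar months:
#' within that window new cases with the same variant reuse the existing
#' interpretation; at or beyond six months the variant is re-reviewed.
#' Month arithmetic clamps to the end of shorter months (e.g. 31 August
#' plus six months is 28/29 February).
#'
#' @param manual_date `Date` of the manual interpretation.
#' @param analysis_date `Date` the variant is encountered again.
#' @return `"reuse"` or `"re_review"`.
#' @export
#' @examples
#' reuse_policy(as.Date("2020-01-15"), as.Date("2020-06-14")) # "reuse"
#' reuse_policy(as.Date("2020-01-15"), as.Date("2020-07-15")) # "re_review"
reuse_policy <- function(manual_date, analysis_date) {
  manual_date <- as.Date(manual_date)
  analysis_date <- as.Date(analysis_date)
  if (analysis_date < manual_date) {
    abort_validation("analysis_date precedes manual_date")
  }
  if (analysis_date < add_months(manual_date, 6L)) "reuse" else "re_review"
}

# Add months with day-of-month clamped to the target month's length.
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + n
  first <- as.Date(lt)
  last_day <- as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1,
                                "%d"))
  first + min(day, last_day) - 1L
}

#' Confusion table of automated versus manual binary calls
#'
#' Builds the 2x2 cross-tabulation (automated positive/negative by manual
#' positive/negative) with column percentages at one decimal
#' (round-half-up) and the overall concordance.
#'
#' @param cells 2x2 numeric matrix; rows `automated` positive/negative,
#'   columns `manual` positive/negative.
#' @return An object of class `confusion_table`: a list with `cells`,
#'   `col_totals`, `row_totals`, `total`, `col_pct` (column percentages),
#'   `concordant` and `overall_concordance` (percent).
#' @export
confusion_table <- function(cells) {
  cells <- matrix(as.numeric(cells), 2, 2,
                  dimnames = list(automated = c("positive", "negative"),
                                  manual = c("positive", "negative")))
  if (any(is.na(cells)) || any(cells < 0)) {
    abort_validation("confusion cells must be non-negative counts")
  }
  col_totals <- colSums(cells)
  pct <- sweep(cells, 2, col_totals, "/") * 100
  pct[, col_totals == 0] <- NA_real_
  concordant <- cells["positive", "positive"] + cells["negative", "negative"]
  total <- sum(cells)
  structure(
    list(
      cells = cells,
      col_totals = col_totals,
      row_totals = rowSums(cells),
      total = total,
      col_pct = round_half_up(pct, 1),
      concordant = concordant,
      overall_concordance = if (total > 0) {
        round_half_up(100 * concordant / total, 1)
      } else NA_real_
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Automated vs manual binary calls\n")
  m <- matrix(sprintf("%s (%.1f)", format(x$cells, big.mark = ","),
                      x$col_pct), 2, 2)
  dimnames(m) <- list(c("automated positive", "automated negative"),
                      c("manual positive", "manual negative"))
  print(m, quote = FALSE)
  cat(sprintf("Total %s; overall concordance %.1f%% (%s/%s)\n",
              format(x$total, big.mark = ","), x$overall_concordance,
              format(x$concordant, big.mark = ","),
              format(x$total, big.mark = ",")))
  invisible(x)
}

check_comparison_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("no analyzable comparison records")
  }
  needed <- c("consensus_binary", "automated_class")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_validation("comparison records lack column(s): %s",
                     paste(missing, collapse = ", "))
  }
  records
}

tabulate_cells <- function(records, weights) {
  auto <- factor(binarize(records$automated_class),
                 levels = c("positive", "negative"))
  man <- factor(records$consensus_binary, levels = c("positive", "negative"))
  if (anyNA(man)) {
    abort_validation("consensus_binary must be 'positive' or 'negative'")
  }
  cells <- tapply(weights, list(auto, man), sum, default = 0)
  confusion_table(cells)
}

#' Per-variant confusion table
#'
#' Each retained variant contributes one unit to the cell indexed by its
#' automated binary call and its manual consensus binary.
#'
#' @param records Data frame of comparison records with at least
#'   `automated_class` and `consensus_binary` columns.
#' @return A [confusion_table()].
#' @export
per_variant_table <- function(records) {
  records <- check_comparison_records(records)
  tabulate_cells(records, rep(1, nrow(records)))
}

#' Per-case (frequency-weighted) confusion table
#'
#' Each variant contributes its `case_count` (the number of tested
#' individuals carrying it) to its cell, so interpretation errors on common
#' variants are weighted by how many cases they affect.
#'
#' @inheritParams per_variant_table
#' @return A [confusion_table()] whose grand total is the summed case
#'   counts.
#' @export
per_case_table <- function(records) {
  records <- check_comparison_records(records)
  if (!"case_count" %in% names(records)) {
    abort_validation("comparison records lack column(s): case_count")
  }
  if (any(is.na(records$case_count)) || any(records$case_count < 1)) {
    abort_validation("case_count must be a positive integer for every record")
  }
  tabulate_cells(records, as.numeric(records$case_count))
}

#' The nine discordance categories
#'
#' @return Character vector of the nine category tokens, in classifier
#'   priority order.
#' @export
discordance_categories <- function() {
  c("late_null_variant", "clinvar_entry_not_identified", "atypical_phenotype",
    "high_frequency_pathogenic", "variable_penetrance",
    "case_criteria_not_invoked", "functional_criteria_not_invoked",
    "functional_prediction", "expert_decision")
}

record_flags <- function(record) {
  known <- c("late_null", "phenotype_mismatch", "subpop_freq_elevated",
             "healthy_in_popdb", "clinvar_entry_missed",
             "literature_identified", "expert_reviewed")
  fl <- stats::setNames(rep(FALSE, length(known)), known)
  raw <- record$flags
  if (!is.null(raw) && !is.na(raw) && nzchar(trimws(raw))) {
    toks <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    bad <- setdiff(toks, known)
    if (length(bad) > 0) {
      abort_validation("unknown flag(s): %s", paste(bad, collapse = ", "))
    }
    fl[toks] <- TRUE
  }
  fl
}

#' Classify the mechanism behind one discordant interpretation
#'
#' Assigns a discordant variant (automated binary call differing from the
#' manual consensus binary) to exactly one of nine mechanism categories by
#' comparing the criteria invoked by each side, together with per-variant
#' annotation flags.  Rules are evaluated in a fixed priority order —
#' specific mechanisms first, `expert_decision` as the fallback — so the
#' classifier is deterministic:
#'
#' 1. automated-only PVS1 on a flagged late (NMD-escaping) null variant
#'    -> `late_null_variant`;
#' 2. a missed ClinVar entry with manual-only PP5/BP6
#'    -> `clinvar_entry_not_identified`;
#' 3. automated-only case criteria (PM3/PP1/BS2/BP2) invoked on a
#'    mismatched phenotype -> `atypical_phenotype`;
#' 4. automated-only BS1 from a sub-population frequency on a
#'    consensus-positive variant -> `high_frequency_pathogenic`;
#' 5. automated-only BS2 from healthy individuals in a population database
#'    on a consensus-positive variant -> `variable_penetrance`;
#' 6. manual-only literature-sourced case criteria (PM3/PP1/BS2/BP2)
#'    -> `case_criteria_not_invoked`;
#' 7. manual-only functional criteria (PS3/BS3)
#'    -> `functional_criteria_not_invoked`;
#' 8. the two criteria sets differing only in PM1/PP3/BP4
#'    -> `functional_prediction`;
#' 9. otherwise -> `expert_decision`.
#'
#' @param record A one-row comparison record (see [read_comparisons()] for
#'   the schema): serialized `manual_criteria` / `automated_criteria`,
#'   `flags`, `consensus_binary`, classes.
#' @return A single category token (see [discordance_categories()]).
#' @export
categorize_discordance <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1) {
      abort_validation("categorize_discordance expects exactly one record")
    }
    record <- as.list(record)
  }
  if (binarize(record$automated_class) == record$consensus_binary) {
    abort_validation("record is concordant; only discordant records are categorized")
  }
  manual <- parse_criteria(record$manual_criteria)
  auto <- parse_criteria(record$automated_criteria)
  fl <- record_flags(record)

  auto_only <- auto[!(auto$code %in% manual$code), , drop = FALSE]
  manual_only <- manual[!(manual$code %in% auto$code), , drop = FALSE]
  case_codes <- c("PM3", "PP1", "BS2", "BP2")

  if (fl[["late_null"]] && "PVS1" %in% auto_only$code) {
    return("late_null_variant")
  }
  if (fl[["clinvar_entry_missed"]] &&
      any(c("PP5", "BP6") %in% manual_only$code)) {
    return("clinvar_entry_not_identified")
  }
  if (fl[["phenotype_mismatch"]] && any(case_codes %in% auto_only$code)) {
    return("atypical_phenotype")
  }
  if (fl[["subpop_freq_elevated"]] && "BS1" %in% auto_only$code &&
      record$consensus_binary == "positive") {
    return("high_frequency_pathogenic")
  }
  if (fl[["healthy_in_popdb"]] && "BS2" %in% auto_only$code &&
      record$consensus_binary == "positive") {
    return("variable_penetrance")
  }
  manual_only_case <- manual_only$code %in% case_codes &
    manual_only$source == "literature_case"
  if (any(manual_only_case)) {
    return("case_criteria_not_invoked")
  }
  if (any(c("PS3", "BS3") %in% manual_only$code)) {
    return("functional_criteria_not_invoked")
  }
  sym_diff <- c(auto_only$code, manual_only$code)
  if (length(sym_diff) > 0 && all(sym_diff %in% c("PM1", "PP3", "BP4"))) {
    return("functional_prediction")
  }
  "expert_decision"
}

#' Tabulate discordance mechanisms
#'
#' Counts discordant records per mechanism category and expresses each as a
#' percentage of all discordant records (one decimal, round-half-up).
#' Categories are ordered by descending count (ties broken by the
#' classifier's priority order); empty categories are omitted.
#'
#' @param records Data frame of discordant comparison records.
#' @return A data frame with columns `category`, `count`, `percent`, and an
#'   attribute `total` holding the number of discordant records.
#' @export
tabulate_categories <- function(records) {
  cats <- discordance_categories()
  if (is.null(records) || nrow(records) == 0) {
    out <- data.frame(category = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  assigned <- vapply(seq_len(nrow(records)), function(i) {
    categorize_discordance(records[i, , drop = FALSE])
  }, "")
  counts <- table(factor(assigned, levels = cats))
  total <- sum(counts)
  out <- data.frame(
    category = names(counts),
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / total, 1),
    stringsAsFactors = FALSE
  )
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(-out$count, match(out$category, cats)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- as.integer(total)
  out
}

#' Render the full concordance report
#'
#' Assembles the funnel, the per-variant and per-case confusion tables and
#' the discordance tabulation into a deterministic plain-text report plus
#' TSV-ready data frames.  Identical inputs yield byte-identical output.
#'
#' @param funnel Output of [funnel_report()], or `NULL` to omit.
#' @param per_variant,per_case [confusion_table()] objects, or `NULL`.
#' @param categories Output of [tabulate_categories()], or `NULL`.
#' @return A list of class `concordance_report` with elements `text`
#'   (character vector of report lines) and `tables` (named list of data
#'   frames: `funnel`, `per_variant`, `per_case`, `categories`).
#' @export
render_report <- function(funnel = NULL, per_variant = NULL,
                          per_case = NULL, categories = NULL) {
  lines <- c("Automated versus manual variant interpretation concordance",
             strrep("=", 58))
  tables <- list()

  if (!is.null(funnel)) {
    lines <- c(lines, "", "Inclusion/exclusion funnel",
      sprintf("  total observed variants:        %d", funnel$total),
      sprintf("  high-confidence consensus:      %d", funnel$high_confidence),
      sprintf("  insufficient or discordant:     %d",
              funnel$insufficient_or_discordant),
      sprintf("  internal lab conflicts:         %d", funnel$lab_conflict),
      sprintf("  retained for analysis:          %d", funnel$retained))
    tables$funnel <- data.frame(stage = names(funnel),
                                count = unlist(funnel, use.names = FALSE),
                                stringsAsFactors = FALSE)
  }

  fmt_conf <- function(ct, label) {
    n <- function(v) formatC(v, format = "d")
    c("", label,
      sprintf("  automated positive | manual positive %s (%.1f%%) | manual negative %s (%.1f%%)",
              n(ct$cells[1, 1]), ct$col_pct[1, 1], n(ct$cells[1, 2]), ct$col_pct[1, 2]),
      sprintf("  automated negative | manual positive %s (%.1f%%) | manual negative %s (%.1f%%)",
              n(ct$cells[2, 1]), ct$col_pct[2, 1], n(ct$cells[2, 2]), ct$col_pct[2, 2]),
      sprintf("  overall concordance %.1f%% (%s/%s)",
              ct$overall_concordance, n(ct$concordant), n(ct$total)))
  }
  conf_df <- function(ct) {
    data.frame(
      automated = rep(c("positive", "negative"), 2),
      manual = rep(c("positive", "negative"), each = 2),
      count = as.vector(ct$cells),
      percent = as.vector(ct$col_pct),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(per_variant)) {
    lines <- c(lines, fmt_conf(per_variant, "Per-variant concordance"))
    tables$per_variant <- conf_df(per_variant)
  }
  if (!is.null(per_case)) {
    lines <- c(lines, fmt_conf(per_case, "Per-case concordance"))
    tables$per_case <- conf_df(per_case)
  }
  if (!is.null(categories)) {
    lines <- c(lines, "", "Reasons for discordance")
    if (nrow(categories) == 0) {
      lines <- c(lines, "  (no discordant records)")
    } else {
      lines <- c(lines, sprintf("  %-32s %6d  %5.1f%%", categories$category,
                                categories$count, categories$percent),
                 sprintf("  %-32s %6d  100.0%%", "total",
                         attr(categories, "total")))
    }
    tables$categories <- categories
  }
  structure(list(text = lines, tables = tables),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
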