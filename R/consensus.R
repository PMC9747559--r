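#' Filter ClinVar-style submissions to the qualifying set
#'
#' Keeps submissions from the configured qualifying laboratories that meet
#' assertion criteria and were submitted strictly before the dataset cutoff
#' date.  Input order is preserved.
#'
#' @param submissions Data frame of submission records with columns
#'   `variant_key`, `submitter_id`, `classification`,
#'   `assertion_criteria_met` (logical), `submission_date` (`Date`).
#' @param qualifying_submitters Character vector of qualifying submitter
#'   ids.
#' @param cutoff_date A `Date`; submissions on or after it are dropped.
#' @return The qualifying subset of `submissions` (possibly empty).
#' @export
filter_qualifying <- function(submissions, qualifying_submitters,
                              cutoff_date) {
  cutoff_date <- as.Date(cutoff_date)
  keep <- submissions$submitter_id %in% qualifying_submitters &
    submissions$assertion_criteria_met &
    submissions$submission_date < cutoff_date
  submissions[keep, , drop = FALSE]
}

#' Build a high-confidence binary consensus for one variant
#'
#' A variant's qualifying submissions yield a high-confidence consensus when
#' there are at least two of them and all agree at the binary
#' positive/negative level (sub-type disagreement within a group, e.g. one
#' lab P and another LP, is allowed).  Fewer than two submissions is
#' `insufficient`; two or more spanning both binary groups is `discordant`.
#'
#' @param submissions Qualifying submissions for a single variant.
#' @return A one-row data frame with columns `variant_key`, `status`
#'   (`high_confidence` / `insufficient` / `discordant`),
#'   `consensus_binary` (`positive` / `negative` / `none`) and
#'   `n_qualifying_submissions`.
#' @export
#' @examples
#' subs <- data.frame(
#'   variant_key = "GENE1:c.1A>G", submitter_id = c("labA", "labB"),
#'   classification = c("P", "LP"), assertion_criteria_met = TRUE,
#'   submission_date = as.Date("2020-01-01")
#' )
#' build_consensus(subs) # high_confidence, positive
build_consensus <- function(submissions) {
  keys <- unique(submissions$variant_key)
  if (length(keys) > 1) {
    abort_validation("build_consensus expects one variant, got keys: %s",
                     paste(keys, collapse = ", "))
  }
  n <- nrow(submissions)
  key <- if (n > 0) keys else NA_character_
  if (n < 2) {
    return(consensus_result(key, "insufficient", "none", n))
  }
  bins <- unique(binarize(submissions$classification))
  if (length(bins) > 1) {
    return(consensus_result(key, "discordant", "none", n))
  }
  consensus_result(key, "high_confidence", bins, n)
}

consensus_result <- function(variant_key, status, consensus_binary, n) {
  data.frame(
    variant_key = variant_key,
    status = status,
    consensus_binary = consensus_binary,
    n_qualifying_submissions = as.integer(n),
    stringsAsFactors = FALSE
  )
}

#' Consensus for every variant in a submission table
#'
#' Applies [filter_qualifying()] and then [build_consensus()] per variant.
#' Variants whose submissions are all filtered out still appear, with
#' status `insufficient`.
#'
#' @inheritParams filter_qualifying
#' @return A data frame of consensus results, one row per distinct
#'   `variant_key` in `submissions`, ordered by first appearance.
#' @export
build_consensus_all <- function(submissions, qualifying_submitters,
                                cutoff_date) {
  keys <- unique(submissions$variant_key)
  qual <- filter_qualifying(submissions, qualifying_submitters, cutoff_date)
  out <- lapply(keys, function(k) {
    build_consensus(qual[qual$variant_key == k, , drop = FALSE])
  })
  res <- do.call(rbind, out)
  res$variant_key <- keys # keep keys for variants filtered to zero rows
  res
}

#' Exclude variants where the internal lab disagrees with the consensus
#'
#' High-confidence consensus calls that conflict with the laboratory's own
#' manual interpretation at the binary level are flagged `lab_conflict` and
#' excluded from the concordance analysis downstream.
#'
#' @param consensus A one-row consensus result with status
#'   `high_confidence`.
#' @param internal_manual_binary The laboratory's own binary call,
#'   `"positive"` or `"negative"`.
#' @return The consensus result, with status switched to `lab_conflict`
#'   when the internal call disagrees.
#' @export
apply_lab_conflict_filter <- function(consensus, internal_manual_binary) {
  if (!identical(consensus$status, "high_confidence")) {
    abort_validation("lab-conflict filter applies only to high_confidence results")
  }
  if (!internal_manual_binary %in% c("positive", "negative")) {
    abort_validation("internal_manual_binary must be 'positive' or 'negative'")
  }
  if (consensus$consensus_binary != internal_manual_binary) {
    consensus$status <- "lab_conflict"
  }
  consensus
}

#' Inclusion/exclusion funnel over consensus results
#'
#' Accounts for every observed variant: total observed, high-confidence
#' (before the lab-conflict exclusion), insufficient-or-discordant,
#' lab conflicts, and the retained analysis set
#' (`high_confidence - lab_conflict`).
#'
#' @param results Data frame of consensus results (after any lab-conflict
#'   filtering), with a `status` column.
#' @return A named list of five counts: `total`, `high_confidence`,
#'   `insufficient_or_discordant`, `lab_conflict`, `retained`.
#' @export
funnel_report <- function(results) {
  status <- results$status
  bad <- setdiff(unique(status),
                 c("high_confidence", "insufficient", "discordant",
                   "lab_conflict"))
  if (length(bad) > 0) {
    abort_validation("unknown status value(s): %s", paste(bad, collapse = ", "))
  }
  hc <- sum(status %in% c("high_confidence", "lab_conflict"))
  conflict <- sum(status == "lab_conflict")
  list(
    total = length(status),
    high_confidence = hc,
    insufficient_or_discordant = sum(status %in% c("insufficient",
                                                   "discordant")),
    lab_conflict = conflict,
    retained = hc - conflict
  )
}
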