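#' Study-shaped fixture: retained comparison records
#'
#' Reconstructs, from the published marginal tables, a synthetic set of
#' 5,531 retained comparison records whose per-variant confusion cells are
#' 1,004 / 295 / 73 / 4,159 (automated x manual, positive/negative) and
#' whose case counts sum, per cell, to the published per-case cells
#' 5,083 / 8,789 / 1,244 / 1,989,157 (case counts are spread as evenly as
#' possible within each cell).  The records are synthetic: classes,
#' criteria and flags are schema-valid templates, not the study's variants.
#'
#' @return A comparison-record data frame of 5,531 rows.
#' @export
study_fixture_records <- function() {
  cell <- function(n, case_total, consensus, manual_class, automated_class,
                   manual_criteria, automated_criteria, flags) {
    base <- case_total %/% n
    extra <- case_total %% n
    data.frame(
      consensus_binary = consensus,
      manual_class = manual_class,
      automated_class = automated_class,
      case_count = as.integer(base + (seq_len(n) <= extra)),
      manual_criteria = manual_criteria,
      automated_criteria = automated_criteria,
      flags = flags,
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(
    # concordant positives
    cell(1004, 5083, "positive", "P", "P",
         "PVS1:other,PS3:functional_study", "PVS1:other,PS3:functional_study",
         ""),
    # manual positive, automated negative (missed literature case criteria)
    cell(295, 8789, "positive", "LP", "VUS",
         "PM3:literature_case,PS3:functional_study", "PS3:functional_study",
         ""),
    # manual negative, automated positive (phenotype-mismatched case criteria)
    cell(73, 1244, "negative", "VUS", "LP",
         "PS3:functional_study", "PS3:functional_study,PM3:literature_case",
         "phenotype_mismatch"),
    # concordant negatives
    cell(4159, 1989157, "negative", "VUS", "VUS", "", "", "")
  )
  df <- cbind(variant_key = sprintf("FIX%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df$manual_date <- as.Date("2020-06-01")
  df
}

#' Study-shaped fixture: discordant records with the published mechanism mix
#'
#' Builds 359 discordant comparison records distributed over the nine
#' mechanism categories with the published counts (167, 57, 37, 35, 24,
#' 21, 12, 5, 1).  Each category uses a criteria/flag template constructed
#' so that [categorize_discordance()] assigns exactly that category.
#'
#' @return A comparison-record data frame of 359 rows.
#' @export
study_discordance_fixture <- function() {
  tmpl <- list(
    case_criteria_not_invoked = list(
      n = 167, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PM3:literature_case,PP1:literature_case,PS3:functional_study",
      automated = "PS3:functional_study", flags = ""),
    high_frequency_pathogenic = list(
      n = 57, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PM3:literature_case,PS3:functional_study",
      automated = "PM3:literature_case,PS3:functional_study,BS1:population_frequency",
      flags = "subpop_freq_elevated"),
    functional_criteria_not_invoked = list(
      n = 37, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PM3:literature_case,PS3:functional_study",
      automated = "PM3:literature_case", flags = ""),
    atypical_phenotype = list(
      n = 35, consensus = "negative", manual_class = "VUS",
      automated_class = "LP",
      manual = "PS3:functional_study",
      automated = "PS3:functional_study,PM3:literature_case",
      flags = "phenotype_mismatch"),
    expert_decision = list(
      n = 24, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PS1:literature_case,PM5:other",
      automated = "PS1:literature_case", flags = ""),
    functional_prediction = list(
      n = 21, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PS3:functional_study,PP3:in_silico,PP4:literature_case",
      automated = "PS3:functional_study,PP4:literature_case", flags = ""),
    variable_penetrance = list(
      n = 12, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PM3:literature_case,PS3:functional_study",
      automated = "PM3:literature_case,PS3:functional_study,BS2:population_frequency",
      flags = "healthy_in_popdb"),
    clinvar_entry_not_identified = list(
      n = 5, consensus = "positive", manual_class = "LP",
      automated_class = "VUS",
      manual = "PM1:in_silico,PM3:literature_case,PP1:literature_case,PP5:clinvar_entry",
      automated = "PM1:in_silico,PM3:literature_case,PP1:literature_case",
      flags = "clinvar_entry_missed"),
    late_null_variant = list(
      n = 1, consensus = "negative", manual_class = "VUS",
      automated_class = "LP",
      manual = "PM2:population_frequency",
      automated = "PVS1:other,PM2:population_frequency",
      flags = "late_null")
  )
  parts <- lapply(tmpl, function(t) {
    data.frame(
      consensus_binary = rep(t$consensus, t$n),
      manual_class = t$manual_class,
      automated_class = t$automated_class,
      case_count = 1L,
      manual_criteria = t$manual,
      automated_criteria = t$automated,
      flags = t$flags,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  df <- cbind(variant_key = sprintf("DIS%04d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df$manual_date <- as.Date("2020-06-01")
  df
}

#' Study-shaped fixture: consensus funnel
#'
#' Reconstructs the published inclusion/exclusion funnel as a consensus
#' result table: 116,721 observed variants, 5,548 high-confidence (17 of
#' them internal-lab conflicts, leaving 5,531 retained, split 1,299
#' positive / 4,232 negative), the remainder excluded for insufficient or
#' discordant submissions.
#'
#' @return A data frame with columns `variant_key`, `status`,
#'   `consensus_binary`.
#' @export
study_funnel_fixture <- function() {
  n_total <- 116721L
  n_hc <- 5548L
  n_conflict <- 17L
  n_pos <- 1299L
  n_neg <- 4232L
  n_excluded <- n_total - n_hc
  n_insufficient <- 77821L
  n_discordant <- n_excluded - n_insufficient
  status <- c(rep("high_confidence", n_hc - n_conflict),
              rep("lab_conflict", n_conflict),
              rep("insufficient", n_insufficient),
              rep("discordant", n_discordant))
  consensus <- c(rep("positive", n_pos), rep("negative", n_neg),
                 rep("negative", n_conflict),
                 rep("none", n_excluded))
  data.frame(
    variant_key = sprintf("VAR%06d", seq_len(n_total)),
    status = status,
    consensus_binary = consensus,
    stringsAsFactors = FALSE
  )
}
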