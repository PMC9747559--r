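#' Configuration for a synthetic screening cohort
#'
#' Describes the statistical structure of a simulated carrier-screening
#' dataset: how many variants are observed, which fraction reach a
#' high-confidence consensus, how often the internal laboratory conflicts
#' with that consensus, the positive/negative split, the per-mechanism
#' discordance rates, and the heavy-tailed distribution of per-variant case
#' counts.
#'
#' @param n_variants Number of distinct observed variants.
#' @param high_confidence_fraction Fraction of variants reaching a
#'   high-confidence multi-submitter consensus.
#' @param lab_conflict_rate Fraction of high-confidence variants whose
#'   consensus conflicts with the internal manual interpretation.
#' @param positive_fraction Fraction of retained variants whose consensus is
#'   positive (LP/P).
#' @param mechanism_rates Named numeric vector over the nine
#'   [discordance_categories()]: the probability that a variant in the
#'   mechanism's consensus stratum is made discordant by that mechanism.
#'   Seven mechanisms act on consensus-positive variants (the automated
#'   call flips to negative); `atypical_phenotype` and `late_null_variant`
#'   act on consensus-negative variants.  Rates within each stratum must
#'   sum to at most 1.
#' @param nonhc_discordant_fraction Among variants without a
#'   high-confidence consensus, the fraction excluded for submitter
#'   discordance (the rest are excluded for insufficient submissions).
#' @param case_count Case-count distribution: a list with `family`
#'   (`"lognormal"`, `"zipf"` or `"point"`) and its parameters
#'   (`meanlog`/`sdlog`, `exponent`/`kmax`, or `value`).  The default
#'   log-normal has mean ~360 observations per variant with a heavy but
#'   finite-variance tail, so case-weighted rates concentrate even in
#'   scaled-down cohorts.
#' @param amplification Multiplier (>= 1) applied to the case counts of
#'   discordant consensus-positive variants, modelling the observation that
#'   common variants are over-represented among discordant interpretations.
#' @param submitters List with `n_qualifying` and `n_other`: sizes of the
#'   qualifying and non-qualifying submitter pools.
#' @param cutoff_date Dataset cutoff date (ISO-8601); all qualifying
#'   submissions are generated strictly before it.
#' @param seed Mandatory integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_variants,
                          high_confidence_fraction = 0.05,
                          lab_conflict_rate = 0.003,
                          positive_fraction = 0.235,
                          mechanism_rates = default_mechanism_rates(),
                          nonhc_discordant_fraction = 0.3,
                          case_count = list(family = "lognormal",
                                            meanlog = 4.77, sdlog = 1.5),
                          amplification = 6,
                          submitters = list(n_qualifying = 8, n_other = 4),
                          cutoff_date = "2020-11-04",
                          seed) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    abort_validation("a single integer seed is mandatory")
  }
  cfg <- list(
    n_variants = as.integer(n_variants),
    high_confidence_fraction = high_confidence_fraction,
    lab_conflict_rate = lab_conflict_rate,
    positive_fraction = positive_fraction,
    mechanism_rates = mechanism_rates,
    nonhc_discordant_fraction = nonhc_discordant_fraction,
    case_count = case_count,
    amplification = amplification,
    submitters = submitters,
    cutoff_date = as.Date(cutoff_date),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

positive_mechanisms <- function() {
  c("case_criteria_not_invoked", "high_frequency_pathogenic",
    "functional_criteria_not_invoked", "variable_penetrance",
    "clinvar_entry_not_identified", "functional_prediction",
    "expert_decision")
}

negative_mechanisms <- function() {
  c("atypical_phenotype", "late_null_variant")
}

#' Default per-mechanism discordance rates
#'
#' The packaged default reproduces the study-shaped discordance structure:
#' consensus-positive variants flip to an automated negative call at an
#' overall rate of 295/1299, apportioned across the seven
#' positive-stratum mechanisms in proportion to the published mechanism
#' mix (167, 57, 37, 24, 21, 12, 5); consensus-negative variants flip to
#' positive at 73/4232, apportioned 35:1 between `atypical_phenotype` and
#' `late_null_variant`.
#'
#' @return Named numeric vector over the nine [discordance_categories()].
#' @export
default_mechanism_rates <- function() {
  pos_w <- c(case_criteria_not_invoked = 167, high_frequency_pathogenic = 57,
             functional_criteria_not_invoked = 37, expert_decision = 24,
             functional_prediction = 21, variable_penetrance = 12,
             clinvar_entry_not_identified = 5)
  neg_w <- c(atypical_phenotype = 35, late_null_variant = 1)
  rates <- c((295 / 1299) * pos_w / sum(pos_w),
             (73 / 4232) * neg_w / sum(neg_w))
  rates[discordance_categories()]
}

validate_cohort_config <- function(cfg) {
  p <- c(cfg$high_confidence_fraction, cfg$lab_conflict_rate,
         cfg$positive_fraction, cfg$nonhc_discordant_fraction)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort_validation("all fractions must lie in [0, 1]")
  }
  if (is.na(cfg$n_variants) || cfg$n_variants < 1) {
    abort_validation("n_variants must be a positive integer")
  }
  mr <- cfg$mechanism_rates
  cats <- discordance_categories()
  if (is.null(names(mr)) || !setequal(names(mr), cats)) {
    abort_validation("mechanism_rates must be named with all nine categories")
  }
  if (any(mr < 0) || any(mr > 1)) {
    abort_validation("mechanism rates must lie in [0, 1]")
  }
  if (sum(mr[positive_mechanisms()]) > 1 ||
      sum(mr[negative_mechanisms()]) > 1) {
    abort_validation("mechanism rates within a consensus stratum must sum to <= 1")
  }
  if (!cfg$case_count$family %in% c("zipf", "lognormal", "point")) {
    abort_validation("case_count family must be zipf, lognormal or point")
  }
  if (is.na(cfg$amplification) || cfg$amplification < 1) {
    abort_validation("amplification must be >= 1")
  }
  invisible(cfg)
}

#' Study-shaped cohort preset
#'
#' A [cohort_config()] whose marginals emulate the published study: 116,721
#' observed variants funnelling to 5,548 high-confidence consensus variants
#' (17 of them internal-lab conflicts, leaving 5,531 retained), a
#' 23.5%/76.5% positive/negative split, the published mechanism mix, and
#' heavy-tailed case counts with amplified counts on discordant positives.
#' Scaled to `scale` times the study size (default 1/10) so the full
#' pipeline runs in seconds.
#'
#' @param scale Linear scale factor on the number of observed variants.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
study_preset <- function(scale = 0.1, seed = 20201104, ...) {
  args <- list(
    n_variants = max(1L, as.integer(round(116721 * scale))),
    high_confidence_fraction = 5548 / 116721,
    lab_conflict_rate = 17 / 5548,
    positive_fraction = 1299 / 5531,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

#' Sample heavy-tailed per-variant case counts
#'
#' Draws `n` positive integer case counts from the configured family and
#' multiplies (then ceilings) the counts of masked records by
#' `amplification`, so that masked records have `amplification` times the
#' unmasked expected count.
#'
#' Families: `lognormal` — ceiling of a log-normal; `zipf` — discrete power
#' law, `P(k) proportional to k^-exponent` on `1..kmax`; `point` — all
#' counts equal `value`.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of counts to draw.
#' @param distribution List with `family` and its parameters (see
#'   [cohort_config()]).
#' @param mask Logical vector of length `n` marking amplified records.
#' @param amplification Multiplier >= 1.
#' @return Integer-valued numeric vector of length `n`, all >= 1.
#' @export
sample_case_counts <- function(n, distribution = list(family = "lognormal",
                                                      meanlog = 4.77,
                                                      sdlog = 1.5),
                               mask = rep(FALSE, n), amplification = 1) {
  stopifnot(length(mask) == n, amplification >= 1)
  counts <- switch(distribution$family,
    zipf = {
      k <- seq_len(distribution$kmax)
      sample(k, n, replace = TRUE, prob = k^(-distribution$exponent))
    },
    lognormal = ceiling(stats::rlnorm(n, distribution$meanlog,
                                      distribution$sdlog)),
    point = rep(distribution$value, n),
    abort_validation("unknown case-count family: %s", distribution$family)
  )
  counts <- as.numeric(counts)
  counts[mask] <- ceiling(counts[mask] * amplification)
  counts
}

inject_error <- function(msg) {
  stop(structure(
    class = c("acmgconcord_inject_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Edit an automated view to realize one discordance mechanism
#'
#' Given the manual criteria set of a variant, produces the automated
#' criteria set and annotation flags such that (a) the automated
#' classification flips to the opposite binary group and (b)
#' [categorize_discordance()] recovers exactly `mechanism`.  Edits are
#' iterative (criteria are removed or added until the class actually
#' flips) because the combining rules are nonlinear.  When the manual set
#' cannot support the mechanism (for example `functional_criteria_not_invoked`
#' on a set without a load-bearing PS3) the function fails with a
#' condition of class `acmgconcord_inject_error`, so callers can resample
#' the manual set; it never returns a silently concordant record.
#'
#' @param manual Assessment data frame of the manual criteria.
#' @param consensus_binary `"positive"` or `"negative"` (must match the
#'   binarized manual class).
#' @param mechanism One of [discordance_categories()].
#' @return List with `automated` (assessment data frame) and `flags`
#'   (character vector of flag names, possibly empty).
#' @export
inject_discordance <- function(manual, consensus_binary, mechanism) {
  if (!mechanism %in% discordance_categories()) {
    abort_validation("unknown mechanism: %s", mechanism)
  }
  stratum_ok <- if (mechanism %in% positive_mechanisms()) {
    consensus_binary == "positive"
  } else {
    consensus_binary == "negative"
  }
  if (!stratum_ok) {
    abort_validation("mechanism %s is not defined for a %s-consensus variant",
                     mechanism, consensus_binary)
  }

  add <- function(df, codes, sources = default_source(codes)) {
    rbind(df, assessments(codes, sources))
  }
  flips <- function(auto_df) {
    binarize(combine_criteria(auto_df$code)) != consensus_binary
  }
  # remove rows in `removable` (a logical index into manual) one at a time
  # until the classification flips; NULL when the flip is unreachable
  remove_until_flip <- function(removable) {
    auto <- manual
    idx <- which(removable)
    for (i in idx) {
      auto <- auto[auto$code != manual$code[i], , drop = FALSE]
      if (flips(auto)) return(auto)
    }
    NULL
  }

  res <- switch(mechanism,
    case_criteria_not_invoked = {
      removable <- manual$code %in% c("PM3", "PP1") &
        manual$source == "literature_case"
      if (!any(removable)) {
        inject_error("manual set has no literature-sourced case criteria")
      }
      auto <- remove_until_flip(removable)
      if (is.null(auto)) inject_error("removing case criteria does not flip the class")
      list(automated = auto, flags = character(0))
    },
    functional_criteria_not_invoked = {
      removable <- manual$code %in% c("PS3", "BS3")
      if (!any(removable)) inject_error("manual set has no functional criteria")
      auto <- remove_until_flip(removable)
      if (is.null(auto)) inject_error("removing functional criteria does not flip the class")
      list(automated = auto, flags = character(0))
    },
    clinvar_entry_not_identified = {
      removable <- manual$code %in% c("PP5", "BP6")
      if (!any(removable)) inject_error("manual set has no reputable-source criteria")
      auto <- remove_until_flip(removable)
      if (is.null(auto)) inject_error("removing PP5/BP6 does not flip the class")
      list(automated = auto, flags = "clinvar_entry_missed")
    },
    high_frequency_pathogenic = {
      if ("BS1" %in% manual$code) inject_error("manual set already carries BS1")
      list(automated = add(manual, "BS1", "population_frequency"),
           flags = "subpop_freq_elevated")
    },
    variable_penetrance = {
      if ("BS2" %in% manual$code) inject_error("manual set already carries BS2")
      list(automated = add(manual, "BS2", "population_frequency"),
           flags = "healthy_in_popdb")
    },
    functional_prediction = {
      removable <- manual$code %in% c("PM1", "PP3")
      auto <- if (any(removable)) remove_until_flip(removable) else NULL
      if (is.null(auto)) {
        if ("BP4" %in% manual$code) inject_error("manual set already carries BP4")
        auto <- add(manual, "BP4", "in_silico")
        if (!flips(auto)) inject_error("adding BP4 does not flip the class")
      }
      list(automated = auto, flags = character(0))
    },
    expert_decision = {
      specific <- c("PM3", "PP1", "BS2", "BP2", "PS3", "BS3",
                    "PM1", "PP3", "BP4", "PP5", "BP6")
      removable <- !(manual$code %in% specific)
      if (!any(removable)) inject_error("no generically removable criteria")
      auto <- remove_until_flip(removable)
      if (is.null(auto)) inject_error("generic removal does not flip the class")
      list(automated = auto, flags = character(0))
    },
    atypical_phenotype = {
      if (any(manual$direction == "benign")) {
        inject_error("benign evidence in the manual set blocks a positive flip")
      }
      auto <- manual
      for (code in c("PM3", "PP1")) {
        if (!code %in% auto$code) auto <- add(auto, code, "literature_case")
        if (flips(auto)) break
      }
      if (!flips(auto)) inject_error("added case criteria do not reach LP/P")
      list(automated = auto, flags = "phenotype_mismatch")
    },
    late_null_variant = {
      if (any(manual$direction == "benign")) {
        inject_error("benign evidence in the manual set blocks a positive flip")
      }
      if ("PVS1" %in% manual$code) inject_error("manual set already carries PVS1")
      auto <- add(manual, "PVS1", "other")
      if (!flips(auto)) inject_error("PVS1 alone does not reach LP/P here")
      list(automated = auto, flags = "late_null")
    }
  )

  # verify the round-trip contract before handing the record back
  rec <- list(
    consensus_binary = consensus_binary,
    manual_class = combine_criteria(manual$code),
    automated_class = combine_criteria(res$automated$code),
    manual_criteria = format_criteria(manual),
    automated_criteria = format_criteria(res$automated),
    flags = paste(res$flags, collapse = ";")
  )
  if (categorize_discordance(rec) != mechanism) {
    inject_error(sprintf("injection produced a record categorized as %s, not %s",
                         categorize_discordance(rec), mechanism))
  }
  res
}

#' Generate a synthetic screening cohort
#'
#' Simulates the full data structure the pipeline consumes: a ClinVar-style
#' submission table covering high-confidence, insufficient, discordant and
#' internal-conflict variants, and a comparison-record table (manual versus
#' automated criteria and classes, flags, case counts) for the retained
#' high-confidence variants, with a ground-truth mechanism label for every
#' injected discordance.
#'
#' For each retained variant the generator draws the consensus binary, a
#' manual class in that stratum, and a manual criteria set via
#' [sample_criteria_for_class()]; with the configured stratum mechanism
#' probabilities it then applies [inject_discordance()] (resampling the
#' manual set up to `max_attempts` times when a mechanism needs evidence
#' the sampled set lacks), and finally draws case counts with amplification
#' on discordant positives.  The cohort is a deterministic function of the
#' configuration, including its seed.
#'
#' @param config A [cohort_config()].
#' @param max_attempts Resampling budget per discordant variant.
#' @return A list of class `synthetic_cohort` with elements `submissions`,
#'   `comparisons`, `truth` (per-variant status, consensus, internal binary
#'   and ground-truth mechanism) and `config`.
#' @export
generate_cohort <- function(config, max_attempts = 200L) {
  validate_cohort_config(config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_variants
  qualifying <- sprintf("lab%02d", seq_len(config$submitters$n_qualifying))
  others <- sprintf("ext%02d", seq_len(config$submitters$n_other))
  cutoff <- config$cutoff_date
  keys <- sprintf("GENE%04d:c.%d%s>%s", sample.int(9999, n, replace = TRUE),
                  sample.int(5000, n, replace = TRUE),
                  sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  sample(c("A", "C", "G", "T"), n, replace = TRUE))
  keys <- make.unique(keys, sep = "_")

  is_hc <- stats::runif(n) < config$high_confidence_fraction
  status <- ifelse(is_hc, "high_confidence",
                   ifelse(stats::runif(n) < config$nonhc_discordant_fraction,
                          "discordant", "insufficient"))
  conflict <- is_hc & stats::runif(n) < config$lab_conflict_rate
  status[conflict] <- "lab_conflict"
  consensus <- ifelse(stats::runif(n) < config$positive_fraction,
                      "positive", "negative")
  consensus[!is_hc] <- NA_character_
  internal <- consensus
  internal[conflict] <- ifelse(consensus[conflict] == "positive",
                               "negative", "positive")

  rand_date <- function(k) cutoff - sample.int(730L, k, replace = TRUE)
  pos_classes <- c("P", "LP")
  neg_classes <- c("VUS", "LB", "B")
  draw_class <- function(bin) {
    if (bin == "positive") sample(pos_classes, 1)
    else sample(neg_classes, 1, prob = c(0.6, 0.2, 0.2))
  }

  # --- submissions, accumulated as per-variant column chunks -------------
  sub_key <- sub_lab <- sub_class <- vector("list", n)
  sub_date <- vector("list", n)
  sub_acm <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_hc[i]) {
      k <- sample(2:5, 1)
      labs <- sample(qualifying, k)
      cls <- if (consensus[i] == "positive") {
        sample(pos_classes, k, replace = TRUE)
      } else {
        sample(neg_classes, k, replace = TRUE)
      }
      dates <- rand_date(k)
      acm <- rep(TRUE, k)
    } else if (status[i] == "discordant") {
      k <- sample(2:4, 1)
      labs <- sample(qualifying, k)
      # guarantee both binary groups are present
      cls <- c(sample(pos_classes, 1), sample(neg_classes, 1),
               sample(c(pos_classes, neg_classes), k - 2, replace = TRUE))
      dates <- rand_date(k)
      acm <- rep(TRUE, k)
    } else {
      # insufficient: one qualifying submission, sometimes plus a record
      # that fails one of the qualifying filters
      cls1 <- sample(c(pos_classes, neg_classes), 1)
      labs <- sample(qualifying, 1)
      dates <- rand_date(1)
      acm <- TRUE
      if (stats::runif(1) < 0.5) {
        reason <- sample(c("lab", "criteria", "date"), 1)
        labs <- c(labs, if (reason == "lab") sample(others, 1)
                        else sample(setdiff(qualifying, labs), 1))
        dates <- c(dates, if (reason == "date") cutoff + sample.int(90L, 1)
                          else rand_date(1))
        acm <- c(acm, reason != "criteria")
        cls1 <- c(cls1, cls1[1])
      }
      cls <- cls1
      k <- length(labs)
    }
    sub_key[[i]] <- rep(keys[i], k)
    sub_lab[[i]] <- labs
    sub_class[[i]] <- cls
    sub_date[[i]] <- dates
    sub_acm[[i]] <- acm
  }
  submissions <- data.frame(
    variant_key = unlist(sub_key),
    submitter_id = unlist(sub_lab),
    classification = unlist(sub_class),
    assertion_criteria_met = unlist(sub_acm),
    submission_date = as.Date(unlist(lapply(sub_date, as.integer)),
                              origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  # --- comparison records for the retained variants ----------------------
  retained_idx <- which(status == "high_confidence")
  mr <- config$mechanism_rates
  pos_m <- positive_mechanisms()
  neg_m <- negative_mechanisms()

  nr <- length(retained_idx)
  mechanism <- rep(NA_character_, nr)
  manual_class <- automated_class <- character(nr)
  manual_crit <- automated_crit <- flags <- character(nr)

  for (j in seq_len(nr)) {
    i <- retained_idx[j]
    bin <- consensus[i]
    mechs <- if (bin == "positive") pos_m else neg_m
    u <- stats::runif(1)
    cum <- cumsum(mr[mechs])
    hit <- which(u < cum)
    mech <- if (length(hit) > 0) mechs[hit[1]] else NA_character_

    if (is.na(mech)) {
      cls <- draw_class(bin)
      manual <- sample_criteria_for_class(cls)
      auto <- manual
      fl <- character(0)
    } else {
      done <- FALSE
      for (att in seq_len(max_attempts)) {
        cls <- draw_class(bin)
        manual <- sample_criteria_for_class(cls)
        res <- tryCatch(inject_discordance(manual, bin, mech),
                        acmgconcord_inject_error = function(e) NULL)
        if (!is.null(res)) {
          auto <- res$automated
          fl <- res$flags
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop(sprintf(
          "generate_cohort: could not realize mechanism %s within %d attempts",
          mech, max_attempts
        ))
      }
    }
    mechanism[j] <- mech
    manual_class[j] <- cls
    automated_class[j] <- combine_criteria(auto$code)
    manual_crit[j] <- format_criteria(manual)
    automated_crit[j] <- format_criteria(auto)
    flags[j] <- paste(fl, collapse = ";")
  }

  discordant_positive <- !is.na(mechanism) &
    consensus[retained_idx] == "positive"
  case_count <- sample_case_counts(nr, config$case_count,
                                   mask = discordant_positive,
                                   amplification = config$amplification)

  comparisons <- data.frame(
    variant_key = keys[retained_idx],
    consensus_binary = consensus[retained_idx],
    manual_class = manual_class,
    automated_class = automated_class,
    case_count = as.integer(case_count),
    manual_criteria = manual_crit,
    automated_criteria = automated_crit,
    flags = flags,
    manual_date = cutoff - sample.int(365L, nr, replace = TRUE),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    variant_key = keys,
    status = status,
    consensus_binary = consensus,
    internal_binary = internal,
    mechanism = NA_character_,
    stringsAsFactors = FALSE
  )
  truth$mechanism[retained_idx] <- mechanism

  structure(
    list(submissions = submissions, comparisons = comparisons,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )
}
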