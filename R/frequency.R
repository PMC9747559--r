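#' Allele frequency profile
#'
#' Per-population allele frequencies for one variant, plus the
#' disorder-specific maximum credible frequency above which BS1 (allele
#' frequency greater than expected for the disorder) applies.
#'
#' @param frequencies Named numeric vector of allele frequencies in
#'   `[0, 1]`; must include a `"global"` entry.
#' @param max_credible_frequency Disorder-specific threshold in `[0, 1]`.
#' @return An object of class `frequency_profile`.
#' @export
#' @examples
#' frequency_profile(c(ashkenazi = 0.010, global = 0.001), 0.005)
frequency_profile <- function(frequencies, max_credible_frequency) {
  frequencies <- unlist(frequencies)
  if (is.null(names(frequencies)) || !("global" %in% names(frequencies))) {
    abort_validation("frequencies must be named and include a 'global' entry")
  }
  if (any(is.na(frequencies)) || any(frequencies < 0) || any(frequencies > 1)) {
    abort_validation("all frequencies must lie in [0, 1]")
  }
  if (length(max_credible_frequency) != 1 || is.na(max_credible_frequency) ||
      max_credible_frequency < 0 || max_credible_frequency > 1) {
    abort_validation("max_credible_frequency must be a single value in [0, 1]")
  }
  structure(
    list(frequencies = frequencies,
         max_credible_frequency = max_credible_frequency),
    class = "frequency_profile"
  )
}

#' Evaluate BS1 from an allele frequency profile
#'
#' Two behaviours are exposed, because automated engines and manual review
#' differ in which frequency they compare against the disorder's maximum
#' credible frequency.  `subpopulation_max` mode (automated behaviour)
#' invokes BS1 when the highest frequency across any population exceeds the
#' threshold, so a variant enriched in a founder sub-population can acquire
#' strong benign evidence even though it is rare globally.  `global` mode
#' (manual behaviour) compares only the global frequency.
#'
#' @param profile A [frequency_profile()].
#' @param mode `"subpopulation_max"` or `"global"`.
#' @return An assessment data frame containing BS1 with source
#'   `population_frequency`, or an empty assessment set.
#' @export
#' @examples
#' p <- frequency_profile(c(ashkenazi = 0.010, global = 0.001), 0.005)
#' nrow(evaluate_bs1(p, "subpopulation_max")) # 1: BS1 fires
#' nrow(evaluate_bs1(p, "global"))            # 0
evaluate_bs1 <- function(profile, mode = c("subpopulation_max", "global")) {
  if (!inherits(profile, "frequency_profile")) {
    abort_validation("profile must be a frequency_profile")
  }
  mode <- match.arg(mode)
  freq <- switch(mode,
    subpopulation_max = max(profile$frequencies),
    global = unname(profile$frequencies[["global"]])
  )
  if (freq > profile$max_credible_frequency) {
    assessments("BS1", "population_frequency")
  } else {
    assessments(character(0))
  }
}
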