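#' Transcript exon model
#'
#' Minimal transcript representation for nonsense-mediated decay (NMD)
#' reasoning: the ordered 5'-to-3' exon lengths in transcript coordinates.
#'
#' @param exon_lengths Positive integer vector of exon lengths, 5' to 3'.
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' tm <- transcript_model(c(200, 150, 90))
transcript_model <- function(exon_lengths) {
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) < 1 || any(is.na(exon_lengths)) ||
      any(exon_lengths <= 0)) {
    abort_validation("exon_lengths must be a non-empty vector of positive integers")
  }
  structure(
    list(exon_count = length(exon_lengths), exon_lengths = exon_lengths),
    class = "transcript_model"
  )
}

#' Is a truncating variant predicted to escape nonsense-mediated decay?
#'
#' A premature termination variant escapes NMD when it falls in the last
#' exon, or within the last 50 bases (inclusive) of the penultimate exon.
#' Transcripts with a single exon are not NMD substrates, so they always
#' escape.
#'
#' @param model A [transcript_model()].
#' @param variant_exon 1-based exon index of the variant.
#' @param offset_from_exon_end Distance in bases from the 3' end of that
#'   exon (0 = the last base of the exon).
#' @return `TRUE` if NMD escape is predicted.
#' @export
#' @examples
#' tm <- transcript_model(c(300, 200, 120))
#' check_nmd_escape(tm, 3, 100)  # last exon: TRUE
#' check_nmd_escape(tm, 2, 50)   # penultimate, within 50 bp: TRUE
#' check_nmd_escape(tm, 2, 51)   # FALSE
check_nmd_escape <- function(model, variant_exon, offset_from_exon_end) {
  if (!inherits(model, "transcript_model")) {
    abort_validation("model must be a transcript_model")
  }
  variant_exon <- as.integer(variant_exon)
  offset_from_exon_end <- as.integer(offset_from_exon_end)
  if (is.na(variant_exon) || variant_exon < 1 ||
      variant_exon > model$exon_count) {
    abort_validation("variant_exon %s out of range for a %d-exon transcript",
                     variant_exon, model$exon_count)
  }
  if (is.na(offset_from_exon_end) || offset_from_exon_end < 0 ||
      offset_from_exon_end >= model$exon_lengths[variant_exon]) {
    abort_validation("offset_from_exon_end invalid for exon of length %d",
                     model$exon_lengths[variant_exon])
  }
  if (model$exon_count == 1 || variant_exon == model$exon_count) {
    return(TRUE)
  }
  variant_exon == model$exon_count - 1L && offset_from_exon_end <= 50L
}

#' Decide whether PVS1 applies to a null variant
#'
#' PVS1 (very strong pathogenic) applies to a null variant predicted to
#' undergo NMD.  For variants 3' of the NMD-competent region ("late" null
#' variants) the criterion is withheld, unless clinical cases with
#' likely pathogenic/pathogenic variants even further 3' establish that
#' truncation in that region is deleterious.
#'
#' @param is_null_variant Is this a null variant (nonsense, frameshift,
#'   canonical splice site)?
#' @param nmd_escape Result of [check_nmd_escape()].
#' @param downstream_lp_p_cases_exist Do clinical cases exist with LP/P
#'   variants 3' of this one?
#' @return An assessment data frame containing PVS1, or an empty assessment
#'   set when the criterion does not apply.
#' @export
apply_pvs1 <- function(is_null_variant, nmd_escape,
                       downstream_lp_p_cases_exist = FALSE) {
  stopifnot(is.logical(is_null_variant), is.logical(nmd_escape),
            is.logical(downstream_lp_p_cases_exist))
  applies <- isTRUE(is_null_variant) &&
    (!isTRUE(nmd_escape) || isTRUE(downstream_lp_p_cases_exist))
  if (applies) assessments("PVS1") else assessments(character(0))
}
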