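#' In silico prediction panel
#'
#' Collects the tool calls consulted when deciding whether computational
#' evidence (PP3/BP4) applies: four missense predictors (CADD, PolyPhen,
#' SIFT, MutationTaster) and two splicing predictors (MaxEntScan,
#' GeneSplicer).
#'
#' @param variant_class `"nonsynonymous"` or `"synonymous_or_intronic"`.
#' @param cadd,polyphen,sift,mutation_taster Missense tool calls, each
#'   `"deleterious"`, `"benign"` or `"no_call"`.
#' @param maxentscan,genesplicer Splicing tool calls, same tokens.
#' @return An object of class `insilico_panel`.
#' @export
insilico_panel <- function(variant_class = c("nonsynonymous",
                                             "synonymous_or_intronic"),
                           cadd = "no_call", polyphen = "no_call",
                           sift = "no_call", mutation_taster = "no_call",
                           maxentscan = "no_call", genesplicer = "no_call") {
  variant_class <- match.arg(variant_class)
  calls <- c(cadd = cadd, polyphen = polyphen, sift = sift,
             mutation_taster = mutation_taster,
             maxentscan = maxentscan, genesplicer = genesplicer)
  ok <- calls %in% c("deleterious", "benign", "no_call")
  if (!all(ok)) {
    abort_validation("invalid tool call(s): %s",
                     paste(calls[!ok], collapse = ", "))
  }
  if (all(calls == "no_call")) {
    abort_validation("at least one tool must have a call")
  }
  structure(list(variant_class = variant_class, calls = calls),
            class = "insilico_panel")
}

#' Majority / concordance consensus over in silico predictors
#'
#' For nonsynonymous variants, PP3 is invoked when a strict majority of the
#' missense tools with a call predict a deleterious effect, and BP4 when a
#' strict majority predict a benign effect; ties (including all-no-call)
#' invoke nothing.  For synonymous or intronic variants, the two splicing
#' tools must be concordant: both deleterious invokes PP3, both benign
#' invokes BP4, anything else invokes nothing.
#'
#' @param panel An [insilico_panel()].
#' @return An assessment data frame containing PP3 or BP4 with source
#'   `in_silico`, or an empty assessment set.
#' @export
#' @examples
#' p <- insilico_panel("nonsynonymous", cadd = "deleterious",
#'                     polyphen = "deleterious", sift = "deleterious",
#'                     mutation_taster = "benign")
#' insilico_consensus(p)$code # "PP3"
insilico_consensus <- function(panel) {
  if (!inherits(panel, "insilico_panel")) {
    abort_validation("panel must be an insilico_panel")
  }
  if (panel$variant_class == "nonsynonymous") {
    calls <- panel$calls[c("cadd", "polyphen", "sift", "mutation_taster")]
    calls <- calls[calls != "no_call"]
    n_del <- sum(calls == "deleterious")
    n_ben <- sum(calls == "benign")
    code <- if (n_del > n_ben) "PP3" else if (n_ben > n_del) "BP4" else NULL
  } else {
    calls <- panel$calls[c("maxentscan", "genesplicer")]
    code <- if (all(calls == "deleterious")) "PP3"
            else if (all(calls == "benign")) "BP4"
            else NULL
  }
  if (is.null(code)) {
    assessments(character(0))
  } else {
    assessments(code, "in_silico")
  }
}
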