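#' The 28 ACMG/AMP evidence codes
#'
#' Returns the full table of evidence codes defined by the ACMG/AMP sequence
#' variant interpretation guideline.  Direction and strength are fully
#' determined by the code prefix: `PVS` (very strong pathogenic), `PS`
#' (strong pathogenic), `PM` (moderate pathogenic), `PP` (supporting
#' pathogenic), `BA` (stand-alone benign), `BS` (strong benign), `BP`
#' (supporting benign).
#'
#' @return A data frame with columns `code_id`, `direction`
#'   (`pathogenic`/`benign`) and `strength` (`stand_alone`, `very_strong`,
#'   `strong`, `moderate`, `supporting`), with exactly 28 rows.
#' @export
#' @examples
#' nrow(acmg_codes()) # 28
acmg_codes <- function() {
  code_id <- c(
    "PVS1",
    paste0("PS", 1:4),
    paste0("PM", 1:6),
    paste0("PP", 1:5),
    "BA1",
    paste0("BS", 1:4),
    paste0("BP", 1:7)
  )
  prefix <- sub("[0-9]+$", "", code_id)
  strength <- c(
    PVS = "very_strong", PS = "strong", PM = "moderate", PP = "supporting",
    BA = "stand_alone", BS = "strong", BP = "supporting"
  )[prefix]
  direction <- ifelse(prefix %in% c("PVS", "PS", "PM", "PP"),
                      "pathogenic", "benign")
  data.frame(
    code_id = code_id,
    direction = unname(direction),
    strength = unname(strength),
    stringsAsFactors = FALSE
  )
}

#' Recognized evidence sources
#'
#' Every invoked criterion carries the kind of evidence that supported it.
#' The discordance classifier distinguishes, for example, case criteria
#' drawn from the literature from the same codes invoked on other grounds.
#'
#' @return Character vector of valid source tokens.
#' @export
evidence_sources <- function() {
  c("literature_case", "functional_study", "population_frequency",
    "in_silico", "clinvar_entry", "allelic_data", "other")
}

#' Construct a set of evidence assessments
#'
#' An assessment set is a data frame with one row per invoked criterion,
#' holding the code, its fixed direction and strength, and the evidence
#' source.  At most one assessment per code is allowed.
#'
#' @param codes Character vector of code ids (e.g. `c("PM3", "PP1")`).
#' @param sources Character vector of evidence sources, recycled to the
#'   length of `codes`; defaults to the typical source for each code
#'   (see [default_source()]).
#' @return A data frame with columns `code`, `direction`, `strength`,
#'   `source`.
#' @export
#' @examples
#' assessments(c("PM3", "PP1"), "literature_case")
assessments <- function(codes, sources = default_source(codes)) {
  codes <- as.character(codes)
  tab <- acmg_codes()
  bad <- setdiff(codes, tab$code_id)
  if (length(bad) > 0) {
    abort_validation("unknown evidence code(s): %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(codes)) {
    abort_validation(
      "duplicate evidence code(s): %s",
      paste(unique(codes[duplicated(codes)]), collapse = ", ")
    )
  }
  sources <- rep_len(as.character(sources), length(codes))
  bad_src <- setdiff(sources, evidence_sources())
  if (length(bad_src) > 0) {
    abort_validation("unknown evidence source(s): %s",
                     paste(bad_src, collapse = ", "))
  }
  idx <- match(codes, tab$code_id)
  data.frame(
    code = codes,
    direction = tab$direction[idx],
    strength = tab$strength[idx],
    source = sources,
    stringsAsFactors = FALSE
  )
}

#' Default evidence source for a code
#'
#' Maps each evidence code to the kind of evidence that typically backs it:
#' clinical-case codes (PM3, PP1, BS2, BP2, ...) to `literature_case`,
#' functional-study codes (PS3, BS3) to `functional_study`, frequency codes
#' (BA1, BS1, PM2, PS4) to `population_frequency`, computational codes
#' (PM1, PP3, BP4, BP7) to `in_silico`, reputable-source codes (PP5, BP6)
#' to `clinvar_entry`, and everything else to `other`.
#'
#' @param codes Character vector of code ids.
#' @return Character vector of source tokens, same length as `codes`.
#' @export
default_source <- function(codes) {
  map <- c(
    PVS1 = "other",
    PS1 = "literature_case", PS2 = "literature_case",
    PS3 = "functional_study", PS4 = "population_frequency",
    PM1 = "in_silico", PM2 = "population_frequency",
    PM3 = "literature_case", PM4 = "other", PM5 = "other",
    PM6 = "literature_case",
    PP1 = "literature_case", PP2 = "other", PP3 = "in_silico",
    PP4 = "literature_case", PP5 = "clinvar_entry",
    BA1 = "population_frequency",
    BS1 = "population_frequency", BS2 = "literature_case",
    BS3 = "functional_study", BS4 = "literature_case",
    BP1 = "other", BP2 = "literature_case", BP3 = "other",
    BP4 = "in_silico", BP5 = "other", BP6 = "clinvar_entry",
    BP7 = "in_silico"
  )
  out <- unname(map[as.character(codes)])
  out[is.na(out)] <- "other"
  out
}

#' Serialize / parse criteria sets
#'
#' Criteria sets travel through the pipeline TSVs as comma-separated
#' `code:source` tokens, e.g. `"PM3:literature_case,PP1:literature_case"`.
#' An empty string denotes the empty set.
#'
#' @param x For `parse_criteria()`, a single string of comma-separated
#'   tokens; for `format_criteria()`, an assessment data frame as returned
#'   by [assessments()].
#' @return `parse_criteria()` returns an assessment data frame;
#'   `format_criteria()` returns a single string.
#' @export
parse_criteria <- function(x) {
  if (length(x) != 1 || is.na(x)) {
    abort_validation("criteria field must be a single non-NA string")
  }
  x <- trimws(x)
  if (!nzchar(x)) {
    return(assessments(character(0)))
  }
  toks <- strsplit(x, ",", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  parts <- strsplit(toks, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(n > 2)) {
    abort_validation("malformed criteria token(s): %s",
                     paste(toks[n > 2], collapse = ", "))
  }
  codes <- vapply(parts, `[[`, "", 1L)
  sources <- vapply(parts, function(p) {
    if (length(p) == 2) p[[2]] else default_source(p[[1]])
  }, "")
  assessments(codes, sources)
}

#' @rdname parse_criteria
#' @export
format_criteria <- function(x) {
  if (nrow(x) == 0) return("")
  # canonical order keeps serialized output byte-stable across runs
  ord <- order(match(x$code, acmg_codes()$code_id))
  paste(x$code[ord], x$source[ord], sep = ":", collapse = ",")
}
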