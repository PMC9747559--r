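#' Five-level variant classification scale
#'
#' The ordered pathogenicity scale used throughout the package:
#' `B < LB < VUS < LP < P` (benign, likely benign, uncertain significance,
#' likely pathogenic, pathogenic).
#'
#' @return Character vector of the five class tokens, from most benign to
#'   most pathogenic.
#' @export
#' @examples
#' classification_levels()
classification_levels <- function() {
  c("B", "LB", "VUS", "LP", "P")
}

#' Coerce to an ordered classification factor
#'
#' @param x Character vector of class tokens (`P`, `LP`, `VUS`, `LB`, `B`).
#' @return An ordered factor on the five-level scale.
#' @export
as_classification <- function(x) {
  bad <- !is.na(x) & !(x %in% classification_levels())
  if (any(bad)) {
    abort_validation(sprintf(
      "invalid classification token(s): %s (expected one of %s)",
      paste(unique(x[bad]), collapse = ", "),
      paste(classification_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = classification_levels(), ordered = TRUE)
}

#' Binarize a classification into the carrier-screening reporting groups
#'
#' Pathogenic (`P`) and likely pathogenic (`LP`) variants are clinically
#' actionable in carrier screening and are reported as `"positive"`; variants
#' of uncertain significance (`VUS`), likely benign (`LB`) and benign (`B`)
#' are reported as `"negative"`.
#'
#' @param x Character vector (or factor) of classification tokens.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
#' @examples
#' binarize(c("P", "LP", "VUS", "LB", "B"))
binarize <- function(x) {
  x <- as.character(x)
  as_classification(x) # validates tokens
  ifelse(x %in% c("P", "LP"), "positive", "negative")
}

# Validation condition used across the package: callers can catch
# class "acmgconcord_validation_error" to distinguish bad input from bugs.
abort_validation <- function(msg, ...) {
  stop(structure(
    class = c("acmgconcord_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
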