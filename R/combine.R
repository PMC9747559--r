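# memoized code ids; combine_criteria sits in tight sampling loops
valid_code_ids <- c(
  "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

#' Combine ACMG/AMP evidence into a five-level classification
#'
#' Applies the ACMG/AMP combining rules to a set of invoked criteria and
#' returns one of `P`, `LP`, `VUS`, `LB`, `B`.
#'
#' Pathogenic fires for: PVS1 with (>=1 PS, >=2 PM, >=1 PM and >=1 PP, or
#' >=2 PP); >=2 PS; or 1 PS with (>=3 PM, 2 PM and >=2 PP, or 1 PM and
#' >=4 PP).  Likely pathogenic fires for: PVS1 with 1 PM; 1 PS with 1-2 PM;
#' 1 PS with >=2 PP; >=3 PM; 2 PM with >=2 PP; or 1 PM with >=4 PP.
#' Benign fires for BA1 or >=2 BS; likely benign for 1 BS with 1 BP or
#' >=2 BP.  When no rule fires the result is `VUS`.
#'
#' Conflicting evidence defaults to uncertainty: whenever the set contains
#' criteria in both the pathogenic and the benign direction, the result is
#' `VUS` regardless of which combining rules would otherwise fire.  This
#' mirrors the behaviour of automated interpretation engines, where e.g. a
#' single strong benign criterion (BS1) added to an otherwise likely
#' pathogenic set pulls the call down to `VUS`.
#'
#' @param x An assessment data frame from [assessments()] /
#'   [parse_criteria()], or simply a character vector of code ids.
#' @return A single classification token (`"P"`, `"LP"`, `"VUS"`, `"LB"`,
#'   `"B"`).  The result is deterministic and independent of the order of
#'   the input.
#' @export
#' @examples
#' combine_criteria(c("PVS1", "PS1"))      # "P"
#' combine_criteria(c("PS3", "PM3"))       # "LP"
#' combine_criteria(c("PS3", "PM3", "BS1")) # "VUS" (conflicting evidence)
#' combine_criteria(c("BS1", "BP4"))       # "LB"
#' combine_criteria(character(0))          # "VUS"
combine_criteria <- function(x) {
  codes <- if (is.data.frame(x)) x$code else as.character(x)
  if (anyDuplicated(codes)) {
    abort_validation(
      "duplicate evidence code(s): %s",
      paste(unique(codes[duplicated(codes)]), collapse = ", ")
    )
  }
  bad <- setdiff(codes, valid_code_ids)
  if (length(bad) > 0) {
    abort_validation("unknown evidence code(s): %s", paste(bad, collapse = ", "))
  }

  prefix <- sub("[0-9]+$", "", codes)
  n_pvs <- sum(prefix == "PVS")
  n_ps <- sum(prefix == "PS")
  n_pm <- sum(prefix == "PM")
  n_pp <- sum(prefix == "PP")
  n_ba <- sum(prefix == "BA")
  n_bs <- sum(prefix == "BS")
  n_bp <- sum(prefix == "BP")

  has_path <- (n_pvs + n_ps + n_pm + n_pp) > 0
  has_benign <- (n_ba + n_bs + n_bp) > 0
  if (has_path && has_benign) {
    return("VUS")
  }

  pathogenic <-
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 || (n_pm >= 1 && n_pp >= 1) ||
                      n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps >= 1 && (n_pm >= 3 || (n_pm >= 2 && n_pp >= 2) ||
                     (n_pm >= 1 && n_pp >= 4)))
  if (pathogenic) return("P")

  likely_pathogenic <-
    (n_pvs >= 1 && n_pm >= 1) ||
    (n_ps >= 1 && n_pm >= 1) ||
    (n_ps >= 1 && n_pp >= 2) ||
    n_pm >= 3 ||
    (n_pm >= 2 && n_pp >= 2) ||
    (n_pm >= 1 && n_pp >= 4)
  if (likely_pathogenic) return("LP")

  if (n_ba >= 1 || n_bs >= 2) return("B")
  if ((n_bs >= 1 && n_bp >= 1) || n_bp >= 2) return("LB")
  "VUS"
}

#' Draw a criteria set that combines to a target classification
#'
#' Inverse sampler used by the synthetic cohort generator: repeatedly draws
#' bounded random subsets of evidence codes and keeps the first whose
#' [combine_criteria()] result equals `target`.  Sampling pools are
#' direction-restricted (pathogenic codes for `P`/`LP`, benign codes for
#' `B`/`LB`, mixed small sets for `VUS`) so that acceptance is fast, but
#' every returned set is verified against the target.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param target Target classification token.
#' @param max_attempts Rejection-sampling budget; exceeding it is an error,
#'   never a silently wrong class.
#' @return An assessment data frame `S` with `combine_criteria(S) == target`.
#' @export
#' @examples
#' set.seed(1)
#' s <- sample_criteria_for_class("LP")
#' combine_criteria(s) # "LP"
sample_criteria_for_class <- function(target, max_attempts = 1000L) {
  if (!(length(target) == 1 && target %in% classification_levels())) {
    abort_validation("target must be one of %s",
                     paste(classification_levels(), collapse = ", "))
  }
  tab <- acmg_codes()
  path_codes <- tab$code_id[tab$direction == "pathogenic"]
  benign_codes <- tab$code_id[tab$direction == "benign"]

  draw <- switch(target,
    P = function() sample(path_codes, sample(3:6, 1)),
    LP = function() sample(path_codes, sample(2:4, 1)),
    VUS = function() {
      if (stats::runif(1) < 0.25) return(character(0))
      sample(tab$code_id, sample(1:3, 1))
    },
    LB = function() sample(benign_codes, sample(1:3, 1)),
    B = function() sample(benign_codes, sample(2:4, 1))
  )
  for (i in seq_len(max_attempts)) {
    codes <- draw()
    if (combine_criteria(codes) == target) {
      return(assessments(sort(codes)))
    }
  }
  stop(sprintf(
    "sample_criteria_for_class: no %s set found in %d attempts",
    target, max_attempts
  ))
}
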