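# Independent brute-force evaluation of the ACMG/AMP combining rule table,
# coded as a literal list of rule tuples over counted strengths.  Kept
# deliberately separate from combine_criteria(): the tests compare the two
# implementations exhaustively over subsets of a representative code panel.

oracle_classify <- function(codes) {
  pvs <- sum(codes %in% "PVS1")
  ps <- sum(codes %in% c("PS1", "PS2", "PS3", "PS4"))
  pm <- sum(codes %in% c("PM1", "PM2", "PM3", "PM4", "PM5", "PM6"))
  pp <- sum(codes %in% c("PP1", "PP2", "PP3", "PP4", "PP5"))
  ba <- sum(codes %in% "BA1")
  bs <- sum(codes %in% c("BS1", "BS2", "BS3", "BS4"))
  bp <- sum(codes %in% c("BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7"))

  # conflicting evidence defaults to uncertainty
  if ((pvs + ps + pm + pp) > 0 && (ba + bs + bp) > 0) {
    return("VUS")
  }

  pathogenic_rules <- c(
    pvs >= 1 && ps >= 1,
    pvs >= 1 && pm >= 2,
    pvs >= 1 && pm >= 1 && pp >= 1,
    pvs >= 1 && pp >= 2,
    ps >= 2,
    ps >= 1 && pm >= 3,
    ps >= 1 && pm >= 2 && pp >= 2,
    ps >= 1 && pm >= 1 && pp >= 4
  )
  likely_pathogenic_rules <- c(
    pvs >= 1 && pm >= 1,
    ps >= 1 && pm >= 1,
    ps >= 1 && pp >= 2,
    pm >= 3,
    pm >= 2 && pp >= 2,
    pm >= 1 && pp >= 4
  )
  if (any(pathogenic_rules)) return("P")
  if (any(likely_pathogenic_rules)) return("LP")
  if (ba >= 1 || bs >= 2) return("B")
  if ((bs >= 1 && bp >= 1) || bp >= 2) return("LB")
  "VUS"
}

# representative 11-code panel spanning every strength tier and direction
oracle_panel <- c("PVS1", "PS1", "PM1", "PM3", "PP1", "PP3",
                  "BA1", "BS1", "BS2", "BP2", "BP4")

# all subsets of the panel as a list of character vectors, indexed by bitmask
oracle_subsets <- function(panel = oracle_panel) {
  n <- length(panel)
  lapply(0:(2^n - 1), function(mask) {
    panel[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
}

ord_class <- function(x) match(x, classification_levels())
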