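test_that("code table has 28 entries with strength fixed by prefix", {
  tab <- acmg_codes()
  expect_equal(nrow(tab), 28)
  expect_equal(sum(tab$direction == "pathogenic"), 16)
  expect_equal(sum(tab$direction == "benign"), 12)
  expect_equal(tab$strength[tab$code_id == "PVS1"], "very_strong")
  expect_equal(tab$strength[tab$code_id == "BA1"], "stand_alone")
  expect_equal(unique(tab$strength[grepl("^BS", tab$code_id)]), "strong")
})

test_that("combine_criteria reproduces the rule-table examples", {
  expect_equal(combine_criteria(character(0)), "VUS")
  expect_equal(combine_criteria(c("PVS1", "PS1")), "P")
  expect_equal(combine_criteria(c("PS3", "PM3")), "LP")
  # a strong benign criterion added to an LP set pulls the call to VUS
  expect_equal(combine_criteria(c("PS3", "PM3", "BS1")), "VUS")
  expect_equal(combine_criteria(c("BS1", "BP4")), "LB")
  expect_equal(combine_criteria(c("BS1", "BS2")), "B")
  expect_equal(combine_criteria("BA1"), "B")
  expect_equal(combine_criteria("PVS1"), "VUS")
})

test_that("combine_criteria rejects duplicates and unknown codes", {
  expect_error(combine_criteria(c("PS1", "PS1")),
               class = "acmgconcord_validation_error")
  expect_error(combine_criteria("PX9"),
               class = "acmgconcord_validation_error")
})

test_that("combine_criteria is independent of input order", {
  set.seed(11)
  for (i in 1:50) {
    codes <- sample(acmg_codes()$code_id, sample(1:8, 1))
    expect_equal(combine_criteria(codes), combine_criteria(sample(codes)))
  }
})

test_that("NMD escape covers last exon, penultimate 50 bp window, single exon", {
  tm <- transcript_model(c(300, 200, 120))
  expect_true(check_nmd_escape(tm, 3, 0))
  expect_true(check_nmd_escape(tm, 3, 119))
  expect_true(check_nmd_escape(tm, 2, 50))   # inclusive boundary
  expect_false(check_nmd_escape(tm, 2, 51))
  expect_false(check_nmd_escape(tm, 1, 10))
  expect_true(check_nmd_escape(transcript_model(500), 1, 250))
  expect_error(check_nmd_escape(tm, 4, 0),
               class = "acmgconcord_validation_error")
  expect_error(check_nmd_escape(tm, 2, 200),
               class = "acmgconcord_validation_error")
})

test_that("PVS1 is withheld for NMD-escaping nulls without downstream cases", {
  expect_equal(apply_pvs1(TRUE, FALSE, FALSE)$code, "PVS1")
  expect_equal(nrow(apply_pvs1(TRUE, TRUE, FALSE)), 0)
  expect_equal(apply_pvs1(TRUE, TRUE, TRUE)$code, "PVS1")
  expect_equal(nrow(apply_pvs1(FALSE, FALSE, FALSE)), 0)
  expect_equal(nrow(apply_pvs1(FALSE, TRUE, TRUE)), 0)
})

test_that("in silico consensus needs a strict majority of missense tools", {
  p <- insilico_panel("nonsynonymous", cadd = "deleterious",
                      polyphen = "deleterious", sift = "deleterious",
                      mutation_taster = "benign")
  res <- insilico_consensus(p)
  expect_equal(res$code, "PP3")
  expect_equal(res$source, "in_silico")

  tie <- insilico_panel("nonsynonymous", cadd = "deleterious",
                        polyphen = "deleterious", sift = "benign",
                        mutation_taster = "benign")
  expect_equal(nrow(insilico_consensus(tie)), 0)

  # no_calls drop out of the denominator: 1 deleterious vs 0 is a majority
  lone <- insilico_panel("nonsynonymous", cadd = "deleterious")
  expect_equal(insilico_consensus(lone)$code, "PP3")

  ben <- insilico_panel("nonsynonymous", cadd = "benign",
                        polyphen = "benign", sift = "deleterious")
  expect_equal(insilico_consensus(ben)$code, "BP4")
})

test_that("splicing tools must be concordant for synonymous/intronic variants", {
  both <- insilico_panel("synonymous_or_intronic", maxentscan = "deleterious",
                         genesplicer = "deleterious")
  expect_equal(insilico_consensus(both)$code, "PP3")
  ben <- insilico_panel("synonymous_or_intronic", maxentscan = "benign",
                        genesplicer = "benign")
  expect_equal(insilico_consensus(ben)$code, "BP4")
  mixed <- insilico_panel("synonymous_or_intronic", maxentscan = "deleterious",
                          genesplicer = "benign")
  expect_equal(nrow(insilico_consensus(mixed)), 0)
  one <- insilico_panel("synonymous_or_intronic", maxentscan = "deleterious")
  expect_equal(nrow(insilico_consensus(one)), 0)
  expect_error(insilico_panel("nonsynonymous"),
               class = "acmgconcord_validation_error")
})

test_that("BS1 fires on sub-population max but not global frequency", {
  p <- frequency_profile(c(ashkenazi = 0.010, global = 0.001), 0.005)
  expect_equal(evaluate_bs1(p, "subpopulation_max")$code, "BS1")
  expect_equal(evaluate_bs1(p, "subpopulation_max")$source,
               "population_frequency")
  expect_equal(nrow(evaluate_bs1(p, "global")), 0)
  common <- frequency_profile(c(global = 0.020), 0.005)
  expect_equal(evaluate_bs1(common, "subpopulation_max")$code, "BS1")
  expect_equal(evaluate_bs1(common, "global")$code, "BS1")
})

test_that("global BS1 never fires when subpopulation-max BS1 does not", {
  set.seed(5)
  for (i in 1:100) {
    f <- stats::runif(3, 0, 0.05)
    p <- frequency_profile(c(popA = f[1], popB = f[2], global = f[3]),
                           max_credible_frequency = stats::runif(1, 0, 0.05))
    sub_fires <- nrow(evaluate_bs1(p, "subpopulation_max")) > 0
    glob_fires <- nrow(evaluate_bs1(p, "global")) > 0
    expect_true(!glob_fires || sub_fires)
  }
})

test_that("sample_criteria_for_class always hits its target and is seeded", {
  set.seed(99)
  for (target in classification_levels()) {
    for (i in 1:10) {
      s <- sample_criteria_for_class(target)
      expect_equal(combine_criteria(s$code), target)
    }
  }
  set.seed(123)
  a <- sample_criteria_for_class("P")
  set.seed(123)
  b <- sample_criteria_for_class("P")
  expect_identical(a, b)
  expect_error(sample_criteria_for_class("pathogenic"),
               class = "acmgconcord_validation_error")
})
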