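test_that("binarize groups P/LP as positive and VUS/LB/B as negative", {
  expect_equal(binarize(c("P", "LP", "VUS", "LB", "B")),
               c("positive", "positive", "negative", "negative", "negative"))
  expect_error(binarize("Pathogenic/LP"),
               class = "acmgconcord_validation_error")
})

test_that("interpretations stay current for strictly less than six months", {
  d <- as.Date("2020-01-15")
  expect_equal(reuse_policy(d, as.Date("2020-06-14")), "reuse")  # ~5 months
  expect_equal(reuse_policy(d, as.Date("2020-07-14")), "reuse")  # last day in
  expect_equal(reuse_policy(d, as.Date("2020-07-15")), "re_review") # exactly 6
  expect_equal(reuse_policy(d, as.Date("2020-08-15")), "re_review") # 7 months
  expect_equal(reuse_policy(d, d), "reuse")
  # month-end clamping: 31 Aug + 6 months clamps to 28 Feb
  expect_equal(reuse_policy(as.Date("2020-08-31"), as.Date("2021-02-27")),
               "reuse")
  expect_equal(reuse_policy(as.Date("2020-08-31"), as.Date("2021-02-28")),
               "re_review")
  expect_error(reuse_policy(as.Date("2020-06-01"), as.Date("2020-05-31")),
               class = "acmgconcord_validation_error")
})

test_that("per-variant table counts records; degenerate concordance values", {
  both <- rbind(make_record("positive", "P", "P"),
                make_record("negative", "VUS", "VUS", variant_key = "v2"))
  expect_equal(per_variant_table(both)$overall_concordance, 100.0)
  one <- make_record("positive", "P", "VUS")
  expect_equal(per_variant_table(one)$overall_concordance, 0.0)
  expect_error(per_variant_table(both[0, ]),
               class = "acmgconcord_validation_error")
})

test_that("case weighting amplifies discordance on common variants", {
  recs <- rbind(
    make_record("positive", "P", "VUS", case_count = 100, variant_key = "A"),
    make_record("positive", "P", "P", case_count = 10, variant_key = "B")
  )
  expect_equal(per_variant_table(recs)$overall_concordance, 50.0)
  pc <- per_case_table(recs)
  expect_equal(pc$total, 110)
  expect_equal(pc$overall_concordance, 9.1) # 10/110
})

test_that("per-case equals per-variant when all counts are one, and on expansion", {
  set.seed(31)
  n <- 40
  recs <- make_record(
    consensus_binary = sample(c("positive", "negative"), n, replace = TRUE),
    manual_class = "VUS", automated_class = sample(c("P", "VUS"), n, TRUE),
    case_count = sample(1:20, n, replace = TRUE),
    variant_key = sprintf("v%02d", 1:n)
  )
  recs$manual_class <- ifelse(recs$consensus_binary == "positive", "P", "VUS")
  unit <- recs
  unit$case_count <- 1L
  expect_equal(per_case_table(unit)$cells, per_variant_table(unit)$cells)
  expanded <- recs[rep(seq_len(n), recs$case_count), ]
  expect_equal(per_case_table(recs)$cells, per_variant_table(expanded)$cells)
  # cell conservation
  expect_equal(per_variant_table(recs)$total, n)
  expect_equal(per_case_table(recs)$total, sum(recs$case_count))
})

test_that("discordance classifier resolves each mechanism by priority", {
  # missed literature case criteria
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PM3:literature_case,PP1:literature_case,PS3:functional_study",
    automated_criteria = "PS3:functional_study")),
    "case_criteria_not_invoked")
  # sub-population frequency invoking BS1 on a consensus-positive variant
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PS3:functional_study,PM3:literature_case",
    automated_criteria = "PS3:functional_study,PM3:literature_case,BS1:population_frequency",
    flags = "subpop_freq_elevated")),
    "high_frequency_pathogenic")
  # automated-only PVS1 on a flagged late null variant
  expect_equal(categorize_discordance(make_record(
    "negative", "VUS", "LP",
    manual_criteria = "PM2:population_frequency",
    automated_criteria = "PVS1:other,PM2:population_frequency",
    flags = "late_null")),
    "late_null_variant")
  # symmetric difference confined to computational criteria
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PS3:functional_study,PP3:in_silico,PP4:literature_case",
    automated_criteria = "PS3:functional_study,PP4:literature_case")),
    "functional_prediction")
  # missed ClinVar entry beats later rules
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PM1:in_silico,PM3:literature_case,PP1:literature_case,PP5:clinvar_entry",
    automated_criteria = "PM1:in_silico,PM3:literature_case,PP1:literature_case",
    flags = "clinvar_entry_missed")),
    "clinvar_entry_not_identified")
  # phenotype-mismatched case criteria invoked by automation
  expect_equal(categorize_discordance(make_record(
    "negative", "VUS", "LP",
    manual_criteria = "PS3:functional_study",
    automated_criteria = "PS3:functional_study,PM3:literature_case",
    flags = "phenotype_mismatch")),
    "atypical_phenotype")
  # healthy individuals in a population database (BS2) on a positive variant
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PS3:functional_study,PM3:literature_case",
    automated_criteria = "PS3:functional_study,PM3:literature_case,BS2:population_frequency",
    flags = "healthy_in_popdb")),
    "variable_penetrance")
  # missed functional studies
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PM3:literature_case,PS3:functional_study",
    automated_criteria = "PM3:literature_case")),
    "functional_criteria_not_invoked")
  # nothing specific matches
  expect_equal(categorize_discordance(make_record(
    "positive", "LP", "VUS",
    manual_criteria = "PS1:literature_case,PM5:other",
    automated_criteria = "PS1:literature_case")),
    "expert_decision")
})

test_that("classifier rejects concordant records", {
  expect_error(categorize_discordance(make_record("positive", "P", "LP")),
               class = "acmgconcord_validation_error")
})

test_that("priority puts the late-null rule ahead of the phenotype rule", {
  rec <- make_record(
    "negative", "VUS", "LP",
    manual_criteria = "PM2:population_frequency",
    automated_criteria = "PVS1:other,PM2:population_frequency,PM3:literature_case",
    flags = "late_null;phenotype_mismatch")
  expect_equal(categorize_discordance(rec), "late_null_variant")
})

test_that("category tabulation covers degenerate inputs", {
  single <- make_record("positive", "LP", "VUS",
                        manual_criteria = "PM3:literature_case,PS3:functional_study",
                        automated_criteria = "PS3:functional_study")
  t1 <- tabulate_categories(single)
  expect_equal(t1$percent, 100.0)
  expect_equal(attr(t1, "total"), 1L)

  two <- rbind(single,
               make_record("positive", "LP", "VUS", variant_key = "v2",
                           manual_criteria = "PM3:literature_case,PS3:functional_study",
                           automated_criteria = "PM3:literature_case"))
  t2 <- tabulate_categories(two)
  expect_equal(sort(t2$percent), c(50.0, 50.0))
  expect_equal(attr(t2, "total"), 2L)

  t0 <- tabulate_categories(single[0, ])
  expect_equal(nrow(t0), 0)
  expect_equal(attr(t0, "total"), 0L)
})

test_that("rendered reports are byte-identical across runs", {
  recs <- study_discordance_fixture()
  mk <- function() {
    render_report(
      funnel = funnel_report(data.frame(status = c("high_confidence",
                                                   "insufficient"))),
      per_variant = per_variant_table(recs),
      per_case = per_case_table(recs),
      categories = tabulate_categories(recs)
    )
  }
  r1 <- mk()
  r2 <- mk()
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  write_tables(r1, d1)
  write_tables(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # empty discordance section renders without error
  r0 <- render_report(categories = tabulate_categories(recs[0, ]))
  expect_true(any(grepl("no discordant records", r0$text)))
})
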