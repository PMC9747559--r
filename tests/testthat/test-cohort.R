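test_that("case counts honor point mass, amplification and positivity", {
  pt <- sample_case_counts(50, list(family = "point", value = 1))
  expect_true(all(pt == 1))
  amp <- sample_case_counts(50, list(family = "point", value = 1),
                            mask = rep(c(TRUE, FALSE), 25),
                            amplification = 20)
  expect_equal(unique(amp[c(TRUE, FALSE)]), 20)
  expect_equal(unique(amp[c(FALSE, TRUE)]), 1)

  set.seed(17)
  z <- sample_case_counts(20000, list(family = "zipf", exponent = 1.5,
                                      kmax = 1e4))
  expect_true(all(z >= 1))
  expect_true(all(z == floor(z)))
  # heavy tail: a non-trivial mass far above the median
  expect_gt(stats::quantile(z, 0.99), 50 * stats::median(z))
})

test_that("amplified and unamplified counts have matching means at amplification 1", {
  set.seed(18)
  mask <- rep(c(TRUE, FALSE), 5000)
  z <- sample_case_counts(10000, list(family = "zipf", exponent = 2.5,
                                      kmax = 1e4),
                          mask = mask, amplification = 1)
  # the two groups are draws from the same distribution: Welch test should
  # not reject at any sensible level
  expect_gt(stats::t.test(z[mask], z[!mask])$p.value, 0.001)
})

test_that("each injected mechanism flips the class and round-trips", {
  set.seed(41)
  lp <- assessments(c("PM3", "PS3"))
  for (mech in c("case_criteria_not_invoked", "high_frequency_pathogenic",
                 "functional_criteria_not_invoked", "variable_penetrance")) {
    res <- inject_discordance(lp, "positive", mech)
    auto_class <- combine_criteria(res$automated$code)
    expect_equal(binarize(auto_class), "negative")
  }
  # canonical edits for the two template mechanisms
  ccni <- inject_discordance(lp, "positive", "case_criteria_not_invoked")
  expect_equal(sort(ccni$automated$code), "PS3")
  hfp <- inject_discordance(lp, "positive", "high_frequency_pathogenic")
  expect_equal(combine_criteria(hfp$automated$code), "VUS")
  expect_true("BS1" %in% hfp$automated$code)

  ln <- inject_discordance(assessments("PM2"), "negative", "late_null_variant")
  expect_true("PVS1" %in% ln$automated$code)
  expect_equal(binarize(combine_criteria(ln$automated$code)), "positive")
})

test_that("injection fails loudly when the manual set cannot support a mechanism", {
  no_ps3 <- assessments(c("PS1", "PS2")) # P without functional evidence
  expect_error(inject_discordance(no_ps3, "positive",
                                  "functional_criteria_not_invoked"),
               class = "acmgconcord_inject_error")
  # PVS1 added to an empty VUS set cannot reach LP/P
  expect_error(inject_discordance(assessments(character(0)), "negative",
                                  "late_null_variant"),
               class = "acmgconcord_inject_error")
  # stratum mismatch is a validation error, not an injection failure
  expect_error(inject_discordance(no_ps3, "negative",
                                  "high_frequency_pathogenic"),
               class = "acmgconcord_validation_error")
})

test_that("cohort configs are validated before any generation", {
  expect_error(cohort_config(n_variants = 100), "seed")
  expect_error(cohort_config(n_variants = 100, positive_fraction = 1.5,
                             seed = 1),
               class = "acmgconcord_validation_error")
  bad_rates <- default_mechanism_rates()
  bad_rates["case_criteria_not_invoked"] <- 0.9
  bad_rates["high_frequency_pathogenic"] <- 0.9
  expect_error(cohort_config(n_variants = 100, mechanism_rates = bad_rates,
                             seed = 1),
               class = "acmgconcord_validation_error")
})

test_that("generated cohorts are deterministic in config and seed", {
  cfg <- cohort_config(n_variants = 400, high_confidence_fraction = 0.5,
                       seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_variants = 400,
                                      high_confidence_fraction = 0.5,
                                      seed = 78))
  expect_false(identical(a$submissions, c2$submissions))
})

test_that("zero mechanism rates yield a fully concordant cohort", {
  rates <- stats::setNames(rep(0, 9), discordance_categories())
  cfg <- cohort_config(n_variants = 300, high_confidence_fraction = 1,
                       lab_conflict_rate = 0, mechanism_rates = rates,
                       seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(per_variant_table(co$comparisons)$overall_concordance, 100.0)
  expect_true(all(is.na(co$truth$mechanism)))
})

test_that("comparison records respect the consensus invariant and recover mechanisms", {
  cfg <- cohort_config(n_variants = 600, high_confidence_fraction = 1,
                       lab_conflict_rate = 0, seed = 11)
  co <- generate_cohort(cfg)
  cmp <- co$comparisons
  expect_equal(cmp$consensus_binary, binarize(cmp$manual_class))
  expect_true(all(cmp$case_count >= 1))

  truth_mech <- co$truth$mechanism[match(cmp$variant_key,
                                         co$truth$variant_key)]
  disc <- which(binarize(cmp$automated_class) != cmp$consensus_binary)
  expect_equal(sort(disc), sort(which(!is.na(truth_mech))))
  got <- vapply(disc, function(i) {
    categorize_discordance(cmp[i, , drop = FALSE])
  }, "")
  expect_equal(got, truth_mech[disc])
})

test_that("the consensus stage reproduces the generated funnel exactly", {
  cfg <- cohort_config(n_variants = 800, high_confidence_fraction = 0.3,
                       lab_conflict_rate = 0.02, seed = 13)
  co <- generate_cohort(cfg)
  labs <- sprintf("lab%02d", seq_len(cfg$submitters$n_qualifying))
  res <- build_consensus_all(co$submissions, labs, cfg$cutoff_date)
  idx <- match(res$variant_key, co$truth$variant_key)
  for (i in which(res$status == "high_confidence")) {
    ib <- co$truth$internal_binary[idx[i]]
    if (!is.na(ib)) {
      res[i, ] <- apply_lab_conflict_filter(res[i, , drop = FALSE], ib)
    }
  }
  expect_equal(res$status, co$truth$status[idx])
  hc <- res$status %in% c("high_confidence", "lab_conflict")
  expect_equal(res$consensus_binary[hc], co$truth$consensus_binary[idx][hc])
})
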