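test_that("sample QC applies inclusive purity bounds and the mass floor", {
  expect_true(qc_sample(1.9, 2.0, 150)$pass)
  expect_true(qc_sample(1.8, 2.2, 100)$pass)   # boundaries included
  r <- qc_sample(1.7, 2.0, 150)
  expect_false(r$pass)
  expect_equal(r$reasons, "a260_280")
  r <- qc_sample(1.9, 2.3, 99)
  expect_setequal(r$reasons, c("a260_230", "mass_ng"))
  expect_error(qc_sample(-1, 2, 100), "non-negative")
})

test_that("variant-fraction filter keeps the inclusive 15-100% interval", {
  calls <- rbind(make_call(cdna = "c.1A>G", variant_fraction = 0.14),
                 make_call(cdna = "c.2A>G", variant_fraction = 0.15),
                 make_call(cdna = "c.3A>G", variant_fraction = 0.50),
                 make_call(cdna = "c.4A>G", variant_fraction = 1.00),
                 make_call(cdna = "c.5A>G", variant_fraction = NA_real_))
  res <- filter_vaf(calls)
  expect_equal(res$kept$cdna, c("c.2A>G", "c.3A>G", "c.4A>G"))
  expect_equal(res$removed$removal_reason[res$removed$cdna == "c.5A>G"],
               "missing_vaf")
})

test_that("population-frequency filter uses the max over databases", {
  calls <- rbind(
    make_call(cdna = "c.1A>G", freq_gnomad = 0.0005),
    make_call(cdna = "c.2A>G", freq_gnomad = 0.0005, freq_1000g = 0.002),
    make_call(cdna = "c.3A>G"),                        # absent everywhere
    make_call(cdna = "c.4A>G", freq_esp = 0.001))      # at threshold
  res <- filter_population_frequency(calls)
  expect_equal(res$kept$cdna, c("c.1A>G", "c.3A>G"))
  # "below 0.1%" is strict: exactly 0.001 is removed
  expect_true("c.4A>G" %in% res$removed$cdna)

  strictly <- filter_population_frequency(
    calls, cascade_config(missing_frequency_passes = FALSE))
  expect_false("c.3A>G" %in% strictly$kept$cdna)

  bad <- make_call(freq_gnomad = 1.5)
  expect_error(filter_population_frequency(bad), "frequency")
})

test_that("ClinVar filter removes only benign and likely benign", {
  calls <- rbind(make_call(cdna = "c.1A>G", clinvar = "likely_benign"),
                 make_call(cdna = "c.2A>G", clinvar = "benign"),
                 make_call(cdna = "c.3A>G", clinvar = "conflicting"),
                 make_call(cdna = "c.4A>G", clinvar = "none"),
                 make_call(cdna = "c.5A>G", clinvar = "pathogenic"))
  res <- filter_clinvar(calls)
  expect_equal(res$kept$cdna, c("c.3A>G", "c.4A>G", "c.5A>G"))
})

test_that("consequence filter keeps coding classes and rescues synonymous", {
  calls <- rbind(
    make_call(cdna = "c.100G>A", protein = "p.Gly34Gly",
              splice_pred_mt = "no_effect", splice_pred_hsf = "no_effect"),
    make_call(cdna = "c.200G>A", protein = "p.Gly67Gly",
              splice_pred_mt = "affects", splice_pred_hsf = "no_effect"),
    make_call(cdna = "c.300G>A", protein = "p.Gly100Gly"),  # no predictor
    make_call(cdna = "c.400+35G>A", protein = "p.?"),
    make_call(cdna = "c.500-2A>G", protein = "p.?"),
    make_call(cdna = "c.600G>T", protein = "p.Glu200*"))
  res <- filter_consequence_class(calls)
  expect_false("c.100G>A" %in% res$kept$cdna)  # all predictors dismiss
  expect_true("c.200G>A" %in% res$kept$cdna)   # one predictor objects
  expect_true("c.300G>A" %in% res$kept$cdna)   # nothing demonstrated inert
  expect_false("c.400+35G>A" %in% res$kept$cdna)  # beyond splice window
  expect_true("c.500-2A>G" %in% res$kept$cdna)
  expect_true("c.600G>T" %in% res$kept$cdna)

  # any_predictor policy eliminates on a single dismissal
  res2 <- filter_consequence_class(
    calls, cascade_config(synonymous_rescue = "any_predictor"))
  expect_false("c.200G>A" %in% res2$kept$cdna)
})

test_that("the cascade removes each planted violator at its stage", {
  calls <- rbind(
    make_call(cdna = "c.1A>G", variant_fraction = 0.05),
    make_call(cdna = "c.2A>G", freq_gnomad = 0.01),
    make_call(cdna = "c.3A>G", clinvar = "benign"),
    make_call(cdna = "c.4G>A", protein = "p.Gly2Gly",
              splice_pred_mt = "no_effect", splice_pred_hsf = "no_effect"),
    make_call(cdna = "c.5+40A>G", protein = "p.?"),
    make_call(cdna = "c.6A>G"))
  res <- run_cascade(calls)
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$survivors$cdna, "c.6A>G")
  expect_equal(res$funnel$stages$n_removed, c(1L, 1L, 1L, 2L))

  # funnel conservation and stage chaining
  st <- res$funnel$stages
  expect_equal(st$n_in[-1], st$n_out[-4])
  expect_equal(sum(st$n_removed) + nrow(res$survivors), nrow(calls))
})

test_that("empty and all-clean inputs pass through the cascade", {
  empty <- make_call()[0, ]
  res <- run_cascade(empty)
  expect_equal(nrow(res$survivors), 0L)
  expect_equal(res$funnel$stages$n_in, rep(0L, 4))

  clean <- do.call(rbind, lapply(1:7, function(i) {
    make_call(cdna = sprintf("c.%dA>G", i))
  }))
  res <- run_cascade(clean)
  expect_equal(nrow(res$survivors), 7L)
})

test_that("the survivor set is invariant under stage order", {
  set.seed(23)
  cohort <- generate_cohort(simulation_config(n_patients = 25), seed = 5)
  stages <- c("vaf", "frequency", "clinvar", "consequence")
  perms <- list(stages, rev(stages),
                c("clinvar", "vaf", "consequence", "frequency"),
                c("consequence", "frequency", "vaf", "clinvar"),
                c("frequency", "consequence", "clinvar", "vaf"))
  baseline <- sort(run_cascade(cohort$calls)$survivors$call_id)
  for (p in perms) {
    expect_identical(sort(run_cascade(cohort$calls, order = p)$survivors$call_id),
                     baseline)
  }
})

test_that("tightening thresholds never enlarges the survivor set", {
  cohort <- generate_cohort(simulation_config(n_patients = 30), seed = 9)
  base <- run_cascade(cohort$calls)$survivors$call_id
  tighter <- list(
    cascade_config(vaf_min = 0.30),
    cascade_config(maf_threshold = 0.0002),
    cascade_config(splice_window = 5))
  for (cfg in tighter) {
    surv <- run_cascade(cohort$calls, cfg)$survivors$call_id
    expect_true(all(surv %in% base))
  }
})

test_that("reporting retains P/LP survivors and routes the rest aside", {
  survivors <- rbind(make_call(cdna = "c.1A>G", criteria = "PVS1PM2"),
                     make_call(cdna = "c.2A>G", criteria = ""),
                     make_call(cdna = "c.3A>G", criteria = "BA1"),
                     make_call(cdna = "c.4A>G", criteria = "PVS1PS4"))
  res <- report_clinically_relevant(survivors)
  expect_setequal(res$reportable$cdna, c("c.1A>G", "c.4A>G"))
  expect_equal(res$not_reportable$engine_class[
    res$not_reportable$cdna == "c.2A>G"], "VUS")
  expect_equal(res$not_reportable$engine_class[
    res$not_reportable$cdna == "c.3A>G"], "B")
})
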