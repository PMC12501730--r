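tab2 <- load_fixture("table2")
tab3 <- load_fixture("table3")

test_that("case solving applies the three rules with correct precedence", {
  sc <- solve_cases(tab2)
  solved <- sc$solved

  # homozygous rule: P2 carries a homozygous USH2A record
  expect_equal(solved$rule[solved$patient_id == "P2"], "homozygous")
  # AD heterozygous rule: P35 carries a PAX6 stop-gain in an AD gene
  expect_equal(solved$rule[solved$patient_id == "P35"], "heterozygous_AD")
  # compound heterozygote: P7 carries two heterozygous USH2A records
  expect_equal(solved$rule[solved$patient_id == "P7"], "compound_het_AR")
  expect_true(solved$phase_assumed[solved$patient_id == "P7"])
  # XLR hemizygous male: P65, RS1
  expect_equal(solved$rule[solved$patient_id == "P65"], "hemizygous")

  # a single heterozygous record in an AR-only gene is a carrier
  expect_true(all(c("P1", "P30", "P36", "P63", "P85", "P91") %in%
                    sc$carriers$patient_id))
  for (pid in sc$carriers$patient_id) {
    recs <- tab2[tab2$patient_id == pid, ]
    plp <- recs[recs$reported_class %in% c("P", "LP"), ]
    expect_true(all(tolower(plp$zygosity) == "heterozygous"))
    expect_false(any(grepl("AD", plp$inheritance)))
  }
})

test_that("diagnostic yield rounds half-up to the integer percent", {
  expect_equal(diagnostic_yield(data.frame(patient_id = "a"), 10)$pct_rounded,
               10L)
  y <- diagnostic_yield(data.frame(patient_id = "a"), 3)
  expect_equal(round(y$pct_raw, 2), 33.33)
  expect_equal(y$pct_rounded, 33L)
  expect_equal(diagnostic_yield(data.frame()[0, ], 10)$pct_rounded, 0L)
  expect_error(diagnostic_yield(data.frame(patient_id = "a"), 0),
               "positive")
})

test_that("pathogenicity distribution uses half-up two-decimal shares", {
  one <- data.frame(reported_class = "LP")
  d <- pathogenicity_distribution(one)
  expect_equal(d$pct[d$class == "LP"], 100.00)

  mix <- data.frame(reported_class = c("P", "LP", "LP"))
  d <- pathogenicity_distribution(mix)
  expect_equal(d$pct[d$class == "P"], 33.33)
  expect_equal(d$pct[d$class == "LP"], 66.67)
  expect_lt(abs(sum(d$pct) - 100), 0.02)
})

test_that("distribution percentages sum to 100 within rounding slack", {
  d <- pathogenicity_distribution(tab2)
  expect_lt(abs(sum(d$pct) - 100), 0.02)
  t <- variant_type_distribution(tab2)
  expect_lt(abs(sum(t$pct) - 100), 0.02)
})

test_that("type distribution flags divergence from a supplied tally", {
  t <- variant_type_distribution(tab2,
                                 expected = c(nonsense = 23, missense = 46))
  expect_false(t$flagged[t$consequence == "nonsense"])
  # the classifier calls the synonymous row synonymous, so the supplied
  # missense tally diverges and must be flagged, not absorbed
  expect_true(t$flagged[t$consequence == "missense"])
  expect_equal(variant_type_distribution(tab2[0, ])$n, rep(0L, 11))
})

test_that("gene distribution sorts by rows with alphabetical ties", {
  g <- gene_distribution(tab2)
  expect_equal(g$gene[1], "ABCA4")
  ties <- g[g$n_variants == 2, "gene"]
  expect_identical(ties, sort(ties))
  one <- gene_distribution(make_call())
  expect_equal(one$n_variants, 1L)
  expect_equal(one$n_patients, 1L)
})

test_that("recurrence counts distinct patients and ignores row order", {
  r <- recurrence(tab2)
  expect_equal(r$n_patients[r$gene == "ABCA4" & r$cdna == "c.5882G>A"], 6L)
  # en-dash and hyphen spellings are one variant
  expect_equal(
    r$n_patients[r$gene == "CYP4V2" & r$cdna == "c.802-8_810delinsGC"], 2L)

  shuffled <- tab2[sample(nrow(tab2)), ]
  doubled <- rbind(tab2, tab2)
  expect_identical(recurrence(shuffled), recurrence(tab2))
  expect_identical(recurrence(doubled), recurrence(tab2))
})

test_that("novelty reconciliation is a bijection and errors loudly", {
  flagged <- flag_novel(tab2, tab3)
  expect_equal(sum(flagged$novel), 28L)
  # matching is per (patient, gene, cdna): P84 has two novel records
  expect_equal(sum(flagged$novel[flagged$patient_id == "P84"]), 2L)

  expect_equal(sum(flag_novel(tab2, tab3[0, ])$novel), 0L)

  bogus <- tab3[1, ]
  bogus$cdna <- "c.999999A>T"
  expect_error(flag_novel(tab2, bogus), "unmatched")
})

test_that("counts reconstruct from printed subgroup percentages", {
  expect_equal(reconstruct_counts_from_percentages(
    c(28, 10, 4, 7, 8, 4, 9, 24),
    c(82.14, 90, 100, 85.71, 62.50, 75, 100, 41.67)), 69L)
  expect_equal(reconstruct_counts_from_percentages(94, 55.32), 52L)
  expect_equal(reconstruct_counts_from_percentages(c(10, 5), c(0, 0)), 0L)
  expect_error(reconstruct_counts_from_percentages(10, 120), "\\[0, 100\\]")
})

test_that("the assembled summary round-trips through its TSV rendering", {
  s <- summarize_cohort(tab2, 94, novel_list = tab3)
  expect_equal(s$yield$pct_rounded, 74L)
  expect_equal(s$n_novel, 28L)
  path <- withr::local_tempfile(fileext = ".tsv")
  render_summary(s, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$value[back$section == "yield" & back$key == "n_solved"],
               "70")
  expect_true("recurrence" %in% back$section)

  empty <- summarize_cohort(tab2[0, ], 94)
  expect_equal(empty$yield$n_solved, 0L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  expect_no_error(render_summary(empty, path2))
})
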