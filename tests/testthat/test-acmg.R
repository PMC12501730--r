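test_that("rule-table combination reproduces the canonical examples", {
  expect_equal(combine_richards("PVS1PM2"), "LP")
  expect_equal(combine_richards("PVS1PM2PS4PP5"), "P")
  expect_equal(combine_richards(""), "VUS")
  expect_equal(combine_richards("PM2PP4"), "VUS")
  expect_equal(combine_richards("PVS1"), "VUS")
  expect_equal(combine_richards("BA1"), "B")
  expect_equal(combine_richards("BS1BP4"), "LB")
  expect_equal(combine_richards("BS1BS3"), "B")
  # mixed evidence splits by conflict policy
  expect_equal(combine_richards("PVS1PM3PM2BS2PP5", "pathogenic_dominant"),
               "P")
  expect_equal(combine_richards("PVS1PM3PM2BS2PP5", "strict"), "VUS")
})

test_that("rule-table engine agrees with the requirement-vector oracle", {
  set.seed(7)
  subsets <- c(
    list(character(0)),
    lapply(all_tokens, identity),
    lapply(1:800, function(i) sample(all_tokens, sample(2:7, 1))))
  for (tokens in subsets) {
    cs <- criteria_set(tokens)
    for (policy in c("pathogenic_dominant", "strict")) {
      expect_identical(combine_richards(cs, policy),
                       oracle_richards(tokens, policy),
                       info = paste(policy, ":",
                                    paste(tokens, collapse = "+")))
    }
  }
})

test_that("adding a pathogenic code never moves the class toward benign", {
  levels <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  set.seed(11)
  path_tokens <- all_tokens[startsWith(all_tokens, "P")]
  for (i in 1:150) {
    base <- sample(all_tokens, sample(0:5, 1))
    extra <- sample(setdiff(path_tokens, base), 1)
    for (policy in c("pathogenic_dominant", "strict")) {
      before <- combine_richards(criteria_set(base), policy)
      after <- combine_richards(criteria_set(c(base, extra)), policy)
      expect_gte(levels[[after]], levels[[before]])
    }
    cfg <- combiner_config(mode = "points")
    before <- combine_points(criteria_set(base), cfg)$class
    after <- combine_points(criteria_set(c(base, extra)), cfg)$class
    expect_gte(levels[[after]], levels[[before]])
  }
})

test_that("point totals and thresholds behave as configured", {
  expect_equal(combine_points("PVS1PM2"), list(points = 10L, class = "P"))
  expect_equal(combine_points(""), list(points = 0L, class = "VUS"))
  expect_equal(combine_points("PM2PM3PP5"),
               list(points = 5L, class = "VUS"))
  expect_equal(combine_points("PS1PM1"), list(points = 6L, class = "LP"))
  expect_equal(combine_points("BS1BS2"), list(points = -8L, class = "B"))
  expect_equal(combine_points("BS1BP1BP2"),
               list(points = -6L, class = "LB"))
  # BA1 disqualifies regardless of pathogenic load
  expect_equal(combine_points("PVS1PS1BA1")$class, "B")

  # all-benign input never exceeds VUS; all-pathogenic never falls below
  levels <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  set.seed(3)
  ben <- all_tokens[startsWith(all_tokens, "B")]
  pat <- all_tokens[startsWith(all_tokens, "P")]
  for (i in 1:50) {
    b <- combine_points(criteria_set(sample(ben, sample(1:5, 1))))$class
    p <- combine_points(criteria_set(sample(pat, sample(1:5, 1))))$class
    expect_lte(levels[[b]], levels[["VUS"]])
    expect_gte(levels[[p]], levels[["VUS"]])
  }
})

test_that("classification is invariant to token order", {
  set.seed(19)
  for (i in 1:40) {
    tokens <- sample(all_tokens, sample(1:6, 1))
    shuffled <- sample(tokens)
    expect_identical(combine_richards(criteria_set(tokens)),
                     combine_richards(criteria_set(shuffled)))
    expect_identical(combine_points(criteria_set(tokens)),
                     combine_points(criteria_set(shuffled)))
  }
})

test_that("reconciliation measures concordance and lists discordant rows", {
  tab2 <- load_fixture("table2")
  rep <- reconcile_with_reported(tab2)
  expect_equal(rep$n_concordant + rep$n_discordant, nrow(tab2))
  expect_equal(rep$n_uninformative, 0L)
  # rows the rule table does explain
  tab <- rep$table
  expect_true(all(tab$concordant[tab$patient_id == "P3" &
                                   tab$criteria == "PVS1PM2"]))
  expect_true(all(tab$concordant[tab$patient_id == "P16"]))
  # a row no face-value combination explains must surface as discordant
  expect_true("P55" %in% rep$discordant$patient_id)

  # rows lacking a reported class are uninformative, not counted
  tab2$reported_class[1:5] <- NA
  rep2 <- reconcile_with_reported(tab2)
  expect_equal(rep2$n_uninformative, 5L)
  expect_equal(rep2$n_concordant + rep2$n_discordant, nrow(tab2) - 5L)

  empty <- reconcile_with_reported(tab2[0, ])
  expect_equal(nrow(empty$table), 0L)
  expect_equal(empty$n_concordant + empty$n_discordant, 0L)
})
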