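test_that("report percentages round half-up to one decimal", {
  expect_equal(round_half_up(100 * 6 / 76), 7.9)
  expect_equal(round_half_up(100 * 2 / 61), 3.3)
  expect_equal(round_half_up(100 * 8 / 69), 11.6)
  expect_equal(round_half_up(11.55), 11.6)  # banker's rounding would give 11.5
  expect_equal(round_half_up(-11.55), -11.6)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("phenotype distribution partitions the cohort with exact marginals", {
  cohort <- make_cohort(
    c19 = c("*1/*1", "*2/*2", "*1/*17", "*1/*2"),
    d6 = c("*1/*1", "*4/*4", "*1/*4", "*1/*999"))
  dist <- phenotype_distribution(cohort)
  expect_equal(dist$n, 4)
  expect_equal(sum(dist$combinations$count), 4)
  # marginals of the combination table equal the per-gene counts
  m19 <- tapply(dist$combinations$count, dist$combinations$cyp2c19, sum)
  expect_equal(as.vector(m19[names(dist$per_gene$CYP2C19)]),
               as.vector(dist$per_gene$CYP2C19))
  m6 <- tapply(dist$combinations$count, dist$combinations$cyp2d6, sum)
  expect_equal(as.vector(m6[names(dist$per_gene$CYP2D6)]),
               as.vector(dist$per_gene$CYP2D6))
  # indeterminate CYP2D6 call does not count as altered
  expect_equal(dist$n_altered_any, 3)

  single <- phenotype_distribution(make_cohort("*1/*1", "*1/*1"))
  combos <- single$combinations
  expect_equal(combos$count[combos$cyp2c19 == "NM" & combos$cyp2d6 == "NM"],
               1)
  expect_equal(single$n_altered_any, 0)
})

test_that("empty cohorts summarize to zeros, not errors", {
  empty <- make_cohort(character(0), character(0))
  dist <- phenotype_distribution(empty)
  expect_equal(dist$n, 0)
  expect_equal(sum(dist$combinations$count), 0)
  res <- run_pipeline(empty, shipped_kb)
  expect_equal(nrow(res$verdicts), 0)
  expect_equal(res$summary$actionability$n_pgx_med_users, 0)
  expect_true(is.na(res$summary$medication_centered$overall$percent_consistent[1]))
})

test_that("actionability counts users of guideline medications only", {
  trials <- data.frame(
    participant_id = c("P1", "P2", "P3"),
    medication = c("sertraline", "sertraline", "methylphenidate"),
    response = c("adr", "none", "adr"), stringsAsFactors = FALSE)
  cohort <- make_cohort(
    c19 = c("*2/*2", "*1/*1", "*2/*2"),
    d6 = c("*1/*1", "*1/*1", "*1/*1"),
    trials = trials)
  act <- actionability_summary(cohort, shipped_kb)
  # P3 used only a non-guideline medication: excluded from the denominator
  expect_equal(act$n_pgx_med_users, 2)
  # P1 is a CYP2C19 PM on sertraline: actionable; P2 is NM: not
  expect_equal(act$n_actionable_participants, 1)
  expect_equal(act$percent_actionable, 50)

  all_nm <- make_cohort(c19 = rep("*1/*1", 3), d6 = rep("*1/*1", 3),
                        trials = trials)
  act <- actionability_summary(all_nm, shipped_kb)
  expect_equal(act$n_actionable_participants, 0)
  expect_equal(act$percent_actionable, 0)
})

test_that("medication-centered fractions guard zero denominators", {
  cohort <- make_cohort("*1/*1", "*1/*1",
                        trials = data.frame(participant_id = "P1",
                                            medication = "sertraline",
                                            response = "adr",
                                            stringsAsFactors = FALSE))
  v <- adjudicate_cohort(cohort, shipped_kb)
  m <- medication_centered_summary(v, shipped_kb)
  adr <- m$overall[m$overall$event_type == "adr", ]
  ineff <- m$overall[m$overall$event_type == "inefficacy", ]
  expect_equal(adr$n_events, 1)
  expect_equal(adr$percent_consistent, 0)
  expect_equal(ineff$n_events, 0)
  expect_true(is.na(ineff$percent_consistent))
})

test_that("per-medication consistent counts sum to the overall count", {
  fx <- build_reference_cohort()
  v <- adjudicate_cohort(fx, shipped_kb)
  m <- medication_centered_summary(v, shipped_kb)
  for (type in c("adr", "inefficacy")) {
    per <- m$per_medication[m$per_medication$event_type == type, ]
    ov <- m$overall[m$overall$event_type == type, ]
    expect_equal(sum(per$n_consistent), ov$n_consistent)
    expect_equal(sum(per$n_events), ov$n_events)
  }
})

test_that("participant tallies obey the explained-count ordering", {
  fx <- build_reference_cohort()
  v <- adjudicate_cohort(fx, shipped_kb)
  pc <- participant_centered_summary(v, shipped_kb)
  expect_lte(pc$n_fully_explained_all_medications,
             pc$n_fully_explained_guideline)
  expect_lte(pc$n_fully_explained_guideline, pc$n_any_consistent)
  expect_lte(pc$n_any_consistent, pc$n_participants_with_events)

  # a single consistent event and nothing else: fully explained both ways
  one <- make_cohort("*2/*2", "*1/*1",
                     trials = data.frame(participant_id = "P1",
                                         medication = "sertraline",
                                         response = "adr",
                                         stringsAsFactors = FALSE))
  pc1 <- participant_centered_summary(adjudicate_cohort(one, shipped_kb),
                                      shipped_kb)
  expect_equal(pc1$n_fully_explained_guideline, 1)
  expect_equal(pc1$n_fully_explained_all_medications, 1)

  # adding a methylphenidate ADR breaks the all-medication view only
  two <- make_cohort("*2/*2", "*1/*1",
                     trials = data.frame(
                       participant_id = c("P1", "P1"),
                       medication = c("sertraline", "methylphenidate"),
                       response = c("adr", "adr"), stringsAsFactors = FALSE))
  pc2 <- participant_centered_summary(adjudicate_cohort(two, shipped_kb),
                                      shipped_kb)
  expect_equal(pc2$n_fully_explained_guideline, 1)
  expect_equal(pc2$n_fully_explained_all_medications, 0)
  expect_equal(pc2$n_any_consistent, 1)
})
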