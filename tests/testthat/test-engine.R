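rs <- default_ichd_ruleset()
bank <- default_question_bank(rs)

test_that("answering no to the headache screen ends the session at once", {
  a <- mwoa_full_answers()
  a["has_headache"] <- "no"
  tr <- run_session(bank, a)
  expect_identical(tr$question_count, 1L)
  expect_identical(tr$labels, "no_headache")
  expect_length(tr$skipped, length(bank$questions) - 1L)
})

test_that("aura-detail questions are never asked once aura is absent", {
  tr <- run_session(bank, mwoa_full_answers())
  aura_detail <- c("aura_reversible", "aura_gradual_spread", "aura_succession",
                   "aura_duration_5_60", "aura_unilateral_symptom",
                   "aura_positive_phenomenon", "aura_headache_within_60")
  expect_true("migraine_without_aura" %in% tr$labels)
  expect_false(any(aura_detail %in% tr$asked$atom_id))
})

test_that("the screening question is relevant on an empty answer set", {
  expect_true(is_relevant("has_headache", rs, character(0))$relevant)
  # once headache is denied, every remaining question is provably moot
  ans <- c(has_headache = "no")
  for (q in bank$questions[-1]) {
    rel <- is_relevant(q, rs, ans)
    expect_false(rel$relevant)
    expect_true(rel$exact)
  }
  expect_error(is_relevant("has_headache", rs, ans), "already answered")
})

test_that("duration stays relevant while it can flip migraine to probable", {
  ans <- mwoa_full_answers()
  ans <- ans[setdiff(names(ans), c("duration", "aura_reversible",
                                   "aura_gradual_spread", "aura_succession",
                                   "aura_duration_5_60",
                                   "aura_unilateral_symptom",
                                   "aura_positive_phenomenon",
                                   "aura_headache_within_60",
                                   "headache_days", "months_ge3",
                                   "acute_med_days"))]
  expect_true(is_relevant("duration", rs, ans)$relevant)
  expect_true(oracle_is_relevant(rs, ans, "duration"))
})

test_that("adaptive sessions reproduce the exhaustive diagnosis", {
  set.seed(11)
  for (i in 1:250) {
    a <- rand_full_assignment(rs)
    tr <- run_session(bank, a)
    expect_identical(sort(tr$labels),
                     sort(resolve(rs, a, validate = FALSE)$labels))
    expect_lte(tr$question_count, length(bank$questions))
  }
})

test_that("replaying the same responder yields an identical transcript", {
  set.seed(12)
  a <- rand_full_assignment(rs)
  expect_identical(run_session(bank, a), run_session(bank, a))
})

test_that("out-of-domain answers are rejected with the offending atom named", {
  s <- new_session(bank)
  q <- next_question(s)
  expect_s3_class(q, "hdx_question")
  expect_error(answer_question(s, "sometimes"), q$atom_id)
  expect_error(answer_question(s, c("yes", "no")), "domain")
})

test_that("the completion oracle enumerates label sets exactly", {
  toy <- ruleset(list(atom("A"), atom("B")),
                 list(rule("r1", "L1", atom_eq("A", "yes")),
                      rule("r2", "L2", atom_eq("B", "yes"))))
  sets <- enumerate_label_sets(toy)
  expect_length(sets, 4L)
  expect_true(any(vapply(sets, function(s) length(s) == 0L, NA)))
  expect_true(any(vapply(sets, function(s) identical(s, c("L1", "L2")), NA)))
  # a complete assignment has a single outcome
  expect_length(enumerate_label_sets(toy, c(A = "yes", B = "no")), 1L)
  # above budget the oracle refuses rather than truncates
  expect_error(enumerate_label_sets(rs), "refused")
})

test_that("with only red flags free, completions differ only on the alert", {
  fixed <- mwoa_full_answers()
  flags <- c("rf_thunderclap", "rf_systemic", "rf_neuro_deficit",
             "rf_onset_after_50", "rf_pattern_change")
  sets <- enumerate_label_sets(rs, fixed[setdiff(names(fixed), flags)])
  expect_length(sets, 2L)
  d <- setdiff(sets[[which.max(lengths(sets))]],
               sets[[which.min(lengths(sets))]])
  expect_identical(d, "secondary_headache_suspected")
})

test_that("no asked question is irrelevant, certified on small sub-banks", {
  set.seed(13)
  for (mk in list(redflag_subbank, tth_subbank)) {
    sb <- mk()
    for (i in 1:6) {
      a <- rand_full_assignment(sb$rs)
      tr <- run_session(sb$bank, a)
      expect_identical(sort(tr$labels),
                       sort(resolve(sb$rs, a, validate = FALSE)$labels))
      failures <- audit_transcript_with_oracle(sb$rs, sb$bank, tr)
      expect_length(failures, 0L)
    }
  }
})
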