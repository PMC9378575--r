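rs <- default_ichd_ruleset()

test_that("the shipped bank validates and covers the expected diagnoses", {
  expect_s3_class(rs, "hdx_ruleset")
  expect_length(rs$atoms, 26)
  expect_setequal(
    vapply(rs$rules, `[[`, "", "label"),
    c("no_headache", "secondary_headache_suspected", "migraine_with_aura",
      "migraine_without_aura", "chronic_migraine", "probable_migraine",
      "tension_type", "medication_overuse", "other_headache"))
})

test_that("a fully migrainous answer set resolves to migraine without aura", {
  imp <- resolve(rs, mwoa_full_answers())
  expect_true("migraine_without_aura" %in% imp$labels)
  expect_false("probable_migraine" %in% imp$labels)
  expect_false(anyNA(imp$status))
})

test_that("failing only the duration criterion demotes to probable migraine", {
  a <- mwoa_full_answers()
  a["duration"] <- "30min-4h"
  imp <- resolve(rs, a)
  expect_true("probable_migraine" %in% imp$labels)
  expect_false("migraine_without_aura" %in% imp$labels)
  expect_false("tension_type" %in% imp$labels)
})

test_that("no headache shuts every symptom-dependent rule off", {
  imp <- resolve(rs, c(has_headache = "no"))
  expect_identical(imp$labels, "no_headache")
  others <- setdiff(names(imp$status), "R-NoHeadache")
  expect_true(all(imp$status[others] == FALSE))
})

test_that("red flags alert in exactly the 2^5 - 1 non-empty combinations", {
  flags <- c("rf_thunderclap", "rf_systemic", "rf_neuro_deficit",
             "rf_onset_after_50", "rf_pattern_change")
  base <- mwoa_full_answers()
  hits <- 0L
  for (mask in 0:31) {
    base[flags] <- ifelse(bitwAnd(mask, 2^(0:4)) > 0, "yes", "no")
    if ("secondary_headache_suspected" %in% resolve(rs, base)$labels)
      hits <- hits + 1L
  }
  expect_identical(hits, 31L)
})

test_that("tension-type excludes probable migraine even with one failed block", {
  # meets tension-type fully while failing only the associated-symptom block
  # of migraine without aura: the probable rule must stay FALSE
  a <- mwoa_full_answers()
  a[c("pulsating", "aggravation_activity")] <- "no"
  a["intensity"] <- "moderate"
  a[c("nausea_vomiting", "phonophobia")] <- "no"
  imp <- resolve(rs, a)
  expect_true("tension_type" %in% imp$labels)
  expect_false("probable_migraine" %in% imp$labels)
  expect_false("migraine_without_aura" %in% imp$labels)
})

test_that("migraine without aura TRUE forces probable migraine FALSE", {
  set.seed(7)
  for (i in 1:200) {
    a <- rand_full_assignment(rs)
    imp <- resolve(rs, a, validate = FALSE)
    if ("migraine_without_aura" %in% imp$labels ||
        "migraine_with_aura" %in% imp$labels)
      expect_false("probable_migraine" %in% imp$labels)
    expect_false(anyNA(imp$status))
  }
})

test_that("chronic migraine and medication overuse can co-occur", {
  a <- mwoa_full_answers()
  a["headache_days"] <- ">=15"
  a["acute_med_days"] <- ">=10"
  labs <- resolve(rs, a)$labels
  expect_true(all(c("chronic_migraine", "medication_overuse") %in% labs))
})
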