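# The published 2x2 table of the validation study the toolkit is modeled
# on: 121 true positives, 2 false positives, 15 false negatives, 64 true
# negatives (migraine/probable-migraine contrast, n = 202).
t3 <- contingency_table(121, 2, 15, 64)

test_that("core rates match the published table", {
  r <- core_rates(t3)
  expect_equal(r$sensitivity, 121 / 136)
  expect_equal(r$specificity, 64 / 66)
  expect_equal(r$accuracy, 185 / 202)
  expect_equal(r$ppv, 121 / 123)
  expect_equal(r$npv, 64 / 79)
  expect_equal(round(100 * r$sensitivity, 1), 89.0)
  expect_equal(round(100 * r$specificity, 1), 97.0)
  expect_equal(round(100 * r$accuracy, 1), 91.6)
  expect_equal(round(100 * r$ppv, 1), 98.4)
  expect_equal(round(100 * r$npv, 1), 81.0)
})

test_that("degenerate tables flag undefined rates instead of crashing", {
  r <- core_rates(contingency_table(5, 0, 0, 5))
  expect_true(all(unlist(r[c("sensitivity", "specificity", "ppv", "npv")]) == 1))
  r0 <- core_rates(contingency_table(0, 0, 5, 5))
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$specificity, 1)
  expect_true(is.na(r0$ppv))
})

test_that("accuracy at the table's own prevalence equals the count accuracy", {
  set.seed(31)
  for (i in 1:25) {
    cells <- stats::rpois(4, 20) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    r <- core_rates(t)
    expect_equal(accuracy_at_prevalence(r$sensitivity, r$specificity,
                                        r$prevalence), r$accuracy)
    pv <- predictive_values_at_prevalence(r$sensitivity, r$specificity,
                                          r$prevalence)
    expect_equal(pv$ppv, r$ppv)
    expect_equal(pv$npv, r$npv)
  }
  expect_equal(accuracy_at_prevalence(0.7, 0.7, 0.123), 0.7)
  expect_equal(accuracy_at_prevalence(1, 1, 0.3), 1)
})

test_that("predictive values transport to community prevalence", {
  r <- core_rates(t3)
  pv <- predictive_values_at_prevalence(r$sensitivity, r$specificity, 0.10)
  expect_equal(round(100 * pv$ppv, 1), 76.5)
  expect_equal(round(100 * pv$npv, 1), 98.8)
  expect_equal(predictive_values_at_prevalence(0.9, 0.9, 1)$ppv, 1)
  expect_true(is.na(predictive_values_at_prevalence(1, 0.9, 1)$npv))
})

test_that("Clopper-Pearson matches the exact interval from binom.test", {
  for (n in c(10, 66, 136, 202)) {
    for (x in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- clopper_pearson(x, n)
      want <- stats::binom.test(x, n)$conf.int
      expect_equal(got$lower, want[1], tolerance = 1e-10)
      expect_equal(got$upper, want[2], tolerance = 1e-10)
    }
  }
  ci <- clopper_pearson(121, 136)
  expect_equal(round(100 * ci$lower, 1), 82.5)
  expect_equal(round(100 * ci$upper, 1), 93.7)
  expect_identical(clopper_pearson(0, 10)$lower, 0)
  expect_identical(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "0 <= x <= n")
})

test_that("exact intervals cover at least nominally", {
  set.seed(32)
  n <- 30
  for (p in c(0.1, 0.5, 0.9)) {
    x <- stats::rbinom(10000, n, p)
    a <- 0.05
    lo <- ifelse(x == 0, 0, stats::qbeta(a / 2, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(1 - a / 2, x + 1, n - x))
    expect_gte(mean(lo <= p & p <= hi), 0.95 - 0.01)
  }
})

test_that("likelihood ratios and their log-method intervals are reproduced", {
  lr <- likelihood_ratios(t3)
  expect_equal(round(lr$lr_pos$point, 1), 29.4)
  expect_equal(round(lr$lr_pos$lower, 1), 7.5)
  expect_equal(round(lr$lr_pos$upper, 1), 115.1)
  expect_equal(round(lr$lr_neg$point, 2), 0.11)
  expect_equal(round(lr$lr_neg$lower, 2), 0.07)
  expect_equal(round(lr$lr_neg$upper, 2), 0.18)
  # an uninformative test has both ratios at 1
  lr1 <- likelihood_ratios(contingency_table(5, 5, 5, 5))
  expect_equal(lr1$lr_pos$point, 1)
  expect_equal(lr1$lr_neg$point, 1)
  # perfect separation: infinite LR+ flagged, LR- zero
  lrp <- likelihood_ratios(contingency_table(8, 0, 0, 9))
  expect_true(is.infinite(lrp$lr_pos$point))
  expect_equal(lrp$lr_neg$point, 0)
  expect_match(lrp$lr_neg$method, "continuity")
})

test_that("kappa agrees with an independent implementation", {
  k <- cohen_kappa(t3)
  expect_equal(round(k$kappa, 2), 0.82)
  expect_equal(round(k$ci$lower, 2), 0.74)
  expect_equal(round(k$ci$upper, 2), 0.90)
  expect_identical(k$interpretation, "almost perfect agreement")
  skip_if_not_installed("e1071")
  set.seed(33)
  for (i in 1:20) {
    cells <- stats::rpois(4, 15) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2)
    expect_equal(cohen_kappa(t)$kappa, e1071::classAgreement(m)$kappa)
  }
})

test_that("kappa hits its boundary cases and stays rater-symmetric", {
  expect_identical(cohen_kappa(contingency_table(50, 0, 0, 50))$kappa, 1)
  expect_identical(cohen_kappa(contingency_table(25, 25, 25, 25))$kappa, 0)
  set.seed(34)
  for (i in 1:20) {
    cells <- stats::rpois(4, 15) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    tt <- contingency_table(cells[1], cells[3], cells[2], cells[4])
    k <- cohen_kappa(t)
    expect_equal(k$kappa, cohen_kappa(tt)$kappa)
    expect_lte(k$kappa, k$p_o)
    if (t$fp + t$fn > 0) expect_lt(k$kappa, 1)
  }
})

test_that("post-test probability follows the odds update and inverts", {
  expect_equal(round(fagan_posttest(0.50, 29.36)$posttest, 2), 0.97)
  expect_equal(fagan_posttest(0.4, 1)$posttest, 0.4)
  expect_equal(round(fagan_posttest(0.67, 0.11)$posttest, 2), 0.18)
  expect_true(fagan_posttest(0, 5)$degenerate)
  set.seed(35)
  for (i in 1:25) {
    p <- stats::runif(1, 0.05, 0.95)
    lr <- stats::rlnorm(1)
    q <- fagan_posttest(p, lr)$posttest
    # inverse update recovers the pre-test probability exactly in odds algebra
    back <- (q / (1 - q) / lr) / (1 + q / (1 - q) / lr)
    expect_equal(back, p)
  }
})

test_that("the exact-CI sample-size search reproduces the planned totals", {
  sens <- sample_size_for_ci(0.80, 0.15, 0.85, group_fraction = 0.35)
  expect_identical(sens$n_total, 203L)
  expect_identical(sens$m, 71L)
  spec <- sample_size_for_ci(0.80, 0.15, 0.85, group_fraction = 0.65)
  expect_identical(spec$n_total, 110L)
  # minimality: one fewer subject violates the width bound
  ci <- clopper_pearson(floor(0.8 * 70 + 0.5), 70, 0.85)
  expect_gt(ci$upper - ci$lower, 0.15)
  # vacuous width bound is met by the smallest possible group
  expect_identical(sample_size_for_ci(0.80, 0.999, 0.85, 1)$m, 1L)
})

test_that("symptom agreement counts channel matches per atom", {
  pairs <- data.frame(
    id = rep(sprintf("D%02d", 1:17), each = 2),
    atom = rep(c("phonophobia", "unilateral"), 17),
    reference = "yes",
    index = c(rbind(c(rep("yes", 8), rep("no", 9)), rep("yes", 17))),
    stringsAsFactors = FALSE)
  ag <- symptom_agreement(pairs, c("phonophobia", "unilateral"))
  expect_equal(round(100 * ag[["phonophobia"]]), 47)
  expect_equal(ag[["unilateral"]], 1)
  expect_error(symptom_agreement(pairs, ids = "nope"), "no records")
})

test_that("contrasts classify and exclude label sets as specified", {
  ct <- dx_contrast("m_vs_nom")
  expect_identical(ct$classify("migraine_without_aura"), "positive")
  expect_identical(ct$classify("probable_migraine"), "excluded")
  expect_identical(ct$classify(c("tension_type", "medication_overuse")),
                   "negative")
  expect_identical(dx_contrast("m_vs_nompm")$classify("probable_migraine"),
                   "negative")
  expect_identical(dx_contrast("mpm_vs_nom")$classify("probable_migraine"),
                   "positive")
  pairs <- data.frame(
    reference_labels = c("migraine_without_aura", "probable_migraine",
                         "tension_type"),
    index_labels = c("migraine_without_aura", "probable_migraine",
                     "tension_type"))
  t <- contingency_from_pairs(pairs, "m_vs_nom")
  expect_equal(attr(t, "excluded"), 1)
  expect_equal(attr(t, "n"), 2)
})

test_that("a table-margin cohort reproduces the full published analysis", {
  pairs <- pairs_from_table(121, 2, 15, 64)
  rep <- build_report(pairs, "mpm_vs_nom", extra_prevalences = 0.10)
  expect_equal(rep$n, 202)
  expect_equal(round(100 * rep$rates$sensitivity$point, 1), 89.0)
  expect_equal(round(100 * rep$rates$specificity$point, 1), 97.0)
  expect_equal(round(100 * rep$rates$accuracy$point, 1), 91.6)
  expect_equal(round(100 * rep$rates$prevalence$point), 67)
  pv <- rep$predictive_at$prevalence_0.1
  expect_equal(round(100 * pv$ppv$point, 1), 76.5)
  expect_equal(round(100 * pv$npv$point, 1), 98.8)
  # the transported predictive-value intervals (logit method); these track
  # the conventional printed intervals closely but are not an exact target
  expect_lt(abs(100 * pv$ppv$lower - 45.4), 0.15)
  expect_lt(abs(100 * pv$ppv$upper - 92.8), 0.15)
  expect_lt(abs(100 * pv$npv$lower - 98.0), 0.15)
  expect_lt(abs(100 * pv$npv$upper - 99.2), 0.15)
  expect_equal(rep$discordant_count, 17)
  expect_length(rep$discordant_ids, 17)
  expect_equal(round(100 * rep$fagan$positive_at_study$posttest), 98)
  out <- capture.output(print(rep))
  expect_true(any(grepl("89.0%", out, fixed = TRUE)))
  expect_true(any(grepl("almost perfect", out)))
})
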