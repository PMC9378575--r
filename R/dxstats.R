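#' 2x2 contingency table of index test vs reference standard
#'
#' @param tp,fp,fn,tn Non-negative counts: true positive, false positive,
#'   false negative, true negative (reference standard defines disease
#'   status; index test defines test status).
#' @return A list of class `dx_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("table must hold at least one record")
  structure(as.list(counts), n = sum(counts), class = "dx_table")
}

#' @export
print.dx_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Shipped outcome contrasts
#'
#' A contrast maps a resolved label set to a positive, negative, or excluded
#' test/disease status. The three shipped contrasts:
#'
#' * `"mpm_vs_nom"` — migraine or probable migraine positive, no migraine
#'   negative (the primary analysis).
#' * `"m_vs_nom"` — definitive migraine positive, no migraine negative;
#'   records whose labels include probable migraine (without definitive
#'   migraine) are excluded from both classes.
#' * `"m_vs_nompm"` — definitive migraine positive, everything else
#'   (including probable migraine) negative.
#'
#' A contrast is data: a label set counted positive, and a label set whose
#' presence (without any positive label) excludes the record. Anything else
#' is negative. Custom contrasts can be built directly and are carried in
#' the rule-bank JSON document.
#'
#' @param name Contrast name (one of the shipped three, or free-form when
#'   `positive_labels` is supplied).
#' @param positive_labels,excluded_labels Label sets for a custom contrast.
#' @return A list of class `dx_contrast` with `name`, `positive_labels`,
#'   `excluded_labels`, and a `classify(labels)` function returning
#'   `"positive"`, `"negative"` or `"excluded"`.
#' @export
dx_contrast <- function(name = c("mpm_vs_nom", "m_vs_nom", "m_vs_nompm"),
                        positive_labels = NULL, excluded_labels = character(0)) {
  if (is.null(positive_labels)) {
    name <- match.arg(name)
    positive_labels <- switch(name,
      mpm_vs_nom = mpm_labels(),
      m_vs_nom = migraine_labels(),
      m_vs_nompm = migraine_labels())
    excluded_labels <- switch(name,
      mpm_vs_nom = character(0),
      m_vs_nom = "probable_migraine",
      m_vs_nompm = character(0))
  }
  force(positive_labels); force(excluded_labels)
  classify <- function(labels) {
    if (any(labels %in% positive_labels)) "positive"
    else if (any(labels %in% excluded_labels)) "excluded"
    else "negative"
  }
  structure(list(name = name, positive_labels = positive_labels,
                 excluded_labels = excluded_labels, classify = classify),
            class = "dx_contrast")
}

split_labels <- function(s) strsplit(s, ";", fixed = TRUE)

#' Build a 2x2 table from paired diagnoses
#'
#' @param pairs Data frame with columns `reference_labels` and
#'   `index_labels` (label sets joined by `";"`), e.g. the `diagnoses`
#'   element of [run_study()].
#' @param contrast A [dx_contrast()] (or its name).
#' @return A `dx_table`; attribute `excluded` counts dropped records (those
#'   the contrast excludes in either channel).
#' @export
contingency_from_pairs <- function(pairs, contrast = dx_contrast("mpm_vs_nom")) {
  if (is.character(contrast)) contrast <- dx_contrast(contrast)
  ref <- vapply(split_labels(pairs$reference_labels), contrast$classify, "")
  idx <- vapply(split_labels(pairs$index_labels), contrast$classify, "")
  keep <- ref != "excluded" & idx != "excluded"
  ref <- ref[keep]; idx <- idx[keep]
  t <- contingency_table(
    tp = sum(ref == "positive" & idx == "positive"),
    fp = sum(ref == "negative" & idx == "positive"),
    fn = sum(ref == "positive" & idx == "negative"),
    tn = sum(ref == "negative" & idx == "negative"))
  attr(t, "excluded") <- sum(!keep)
  t
}

#' Point estimates of the core accuracy rates
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, overall accuracy
#' `(tp+tn)/n`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`. A rate with a zero denominator is
#' undefined and returned as `NA` (never an error).
#'
#' @param t A [contingency_table()].
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `ppv`,
#'   `npv`, plus `prevalence` (`(tp+fn)/n`).
#' @export
core_rates <- function(t) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  n <- attr(t, "n")
  list(sensitivity = safe(t$tp, t$tp + t$fn),
       specificity = safe(t$tn, t$tn + t$fp),
       accuracy = safe(t$tp + t$tn, n),
       ppv = safe(t$tp, t$tp + t$fp),
       npv = safe(t$tn, t$tn + t$fn),
       prevalence = safe(t$tp + t$fn, n))
}

#' Overall accuracy at a given prevalence
#'
#' `sensitivity * prevalence + specificity * (1 - prevalence)`; at the
#' table's own prevalence this equals `(tp+tn)/n` exactly.
#'
#' @param sens,spec,prev Proportions in `[0, 1]`.
#' @return Accuracy as a proportion.
#' @export
accuracy_at_prevalence <- function(sens, spec, prev) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, prev >= 0, prev <= 1)
  sens * prev + spec * (1 - prev)
}

#' Predictive values transported to a given prevalence
#'
#' Bayes' rule: `ppv = sens*prev / (sens*prev + (1-spec)*(1-prev))` and
#' `npv = spec*(1-prev) / (spec*(1-prev) + (1-sens)*prev)`. At the table's
#' own prevalence these equal the count-based PPV/NPV. A zero denominator
#' (e.g. NPV at prevalence 1) yields `NA`.
#'
#' @inheritParams accuracy_at_prevalence
#' @return Named list `ppv`, `npv`.
#' @export
predictive_values_at_prevalence <- function(sens, spec, prev) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, prev >= 0, prev <= 1)
  dp <- sens * prev + (1 - spec) * (1 - prev)
  dn <- spec * (1 - prev) + (1 - sens) * prev
  list(ppv = if (dp > 0) sens * prev / dp else NA_real_,
       npv = if (dn > 0) spec * (1 - prev) / dn else NA_real_)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Lower bound: the `(1-conf)/2` quantile of `Beta(x, n-x+1)` (0 when
#' `x = 0`); upper: the `1-(1-conf)/2` quantile of `Beta(x+1, n-x)` (1 when
#' `x = n`).
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `dx_interval`: `point`, `lower`, `upper`,
#'   `conf`, `method`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (length(x) != 1 || length(n) != 1 || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n))
    stop("require integer counts with 0 <= x <= n, n >= 1")
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  interval(x / n, lower, upper, conf, "clopper-pearson")
}

interval <- function(point, lower, upper, conf, method) {
  structure(list(point = point, lower = lower, upper = upper,
                 conf = conf, method = method), class = "dx_interval")
}

#' @export
print.dx_interval <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (%d%% CI: %.*f-%.*f) [%s]\n", digits, x$point,
              round(100 * x$conf), digits, x$lower, digits, x$upper,
              x$method))
  invisible(x)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`, with confidence intervals
#' symmetric on the log scale:
#' `se(ln LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and the
#' analogous expression with the fn/tn roles for LR-. When a needed cell is
#' zero, 0.5 is added to every cell (continuity correction, flagged via the
#' method tag); a perfect LR+ (specificity 1) is reported as `Inf` with an
#' undefined interval.
#'
#' @param t A [contingency_table()].
#' @param conf Confidence level.
#' @return List with `lr_pos` and `lr_neg`, each a `dx_interval`.
#' @export
likelihood_ratios <- function(t, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  one <- function(num_cell, num_tot, den_cell, den_tot) {
    if (num_tot == 0 || den_tot == 0)
      return(interval(NA_real_, NA_real_, NA_real_, conf, "log (undefined)"))
    point <- (num_cell / num_tot) / (den_cell / den_tot)
    if (den_cell == 0 && num_cell > 0)
      return(interval(Inf, NA_real_, NA_real_, conf, "log (infinite)"))
    cells <- c(num_cell, num_tot, den_cell, den_tot)
    method <- "log"
    if (num_cell == 0 || den_cell == 0) {
      # point estimate kept raw; interval from continuity-corrected cells
      cells <- cells + 0.5
      method <- "log (continuity-corrected +0.5)"
    }
    lr <- (cells[1] / cells[2]) / (cells[3] / cells[4])
    se <- sqrt(1 / cells[1] - 1 / cells[2] + 1 / cells[3] - 1 / cells[4])
    interval(point, exp(log(lr) - z * se), exp(log(lr) + z * se), conf, method)
  }
  list(lr_pos = one(t$tp, t$tp + t$fn, t$fp, t$fp + t$tn),
       lr_neg = one(t$fn, t$tp + t$fn, t$tn, t$fp + t$tn))
}

#' Unweighted Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between the two instruments:
#' `kappa = (p_o - p_e)/(1 - p_e)` with observed agreement
#' `p_o = (tp+tn)/n` and expected agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn))/n^2`. The confidence interval is
#' normal with the asymptotic standard error
#' `sqrt(p_o(1-p_o)/(n(1-p_e)^2))`. Interpretation uses the conventional
#' bins (<=0 none, 0.01-0.20 none to slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect).
#'
#' @param t A [contingency_table()] (n >= 2).
#' @param conf Confidence level.
#' @return A list of class `dx_kappa`: `kappa`, `p_o`, `p_e`, `se`, `ci`
#'   (a `dx_interval`, clipped to `[-1, 1]`), `interpretation`.
#' @export
cohen_kappa <- function(t, conf = 0.95) {
  n <- attr(t, "n")
  if (n < 2) stop("kappa requires n >= 2")
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, p_o = p_o, p_e = p_e,
                          se = NA_real_, ci = NULL,
                          interpretation = "undefined (expected agreement = 1)"),
                     class = "dx_kappa"))
  }
  k <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- interval(k, max(-1, k - z * se), min(1, k + z * se), conf,
                 "asymptotic normal")
  structure(list(kappa = k, p_o = p_o, p_e = p_e, se = se, ci = ci,
                 interpretation = kappa_interpretation(k)),
            class = "dx_kappa")
}

kappa_interpretation <- function(k) {
  if (k <= 0) "no agreement"
  else if (k <= 0.20) "none to slight agreement"
  else if (k <= 0.40) "fair agreement"
  else if (k <= 0.60) "moderate agreement"
  else if (k <= 0.80) "substantial agreement"
  else "almost perfect agreement"
}

#' @export
print.dx_kappa <- function(x, ...) {
  if (is.na(x$kappa)) {
    cat("kappa undefined (expected agreement = 1)\n")
  } else {
    cat(sprintf("kappa = %.2f (%d%% CI: %.2f-%.2f) - %s\n", x$kappa,
                round(100 * x$ci$conf), x$ci$lower, x$ci$upper,
                x$interpretation))
  }
  invisible(x)
}

#' Fagan (Bayes) post-test probability
#'
#' Converts a pre-test probability to odds, multiplies by the likelihood
#' ratio, and converts back:
#' `post = (pre/(1-pre) * lr) / (1 + pre/(1-pre) * lr)`.
#'
#' @param pretest Pre-test probability in `(0, 1)`; the degenerate values 0
#'   and 1 are fixed points and returned as such with a flag.
#' @param lr Likelihood ratio (non-negative).
#' @return A list of class `dx_fagan`: `pretest`, `lr`, `posttest`,
#'   `degenerate`.
#' @export
fagan_posttest <- function(pretest, lr) {
  stopifnot(pretest >= 0, pretest <= 1, lr >= 0)
  if (pretest %in% c(0, 1))
    return(structure(list(pretest = pretest, lr = lr, posttest = pretest,
                          degenerate = TRUE), class = "dx_fagan"))
  odds <- pretest / (1 - pretest) * lr
  structure(list(pretest = pretest, lr = lr, posttest = odds / (1 + odds),
                 degenerate = FALSE), class = "dx_fagan")
}

#' @export
print.dx_fagan <- function(x, ...) {
  cat(sprintf("pre-test %.1f%% x LR %.2f -> post-test %.1f%%%s\n",
              100 * x$pretest, x$lr, 100 * x$posttest,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Sample size for an exact confidence interval of bounded width
#'
#' Finds the smallest index-group size `m` such that the two-sided
#' Clopper-Pearson interval at `conf`, with successes `round(p * m)`
#' (half-up), has width at most `max_width`; the total enrolment is then
#' `N = ceiling(m / group_fraction)`, where `group_fraction` is the
#' fraction of the cohort falling in the relevant group (the anticipated
#' disease prevalence when sizing a sensitivity interval, one minus it for
#' specificity).
#'
#' @param p Anticipated proportion (e.g. anticipated sensitivity).
#' @param max_width Maximal CI width, in `(0, 1)`.
#' @param conf Confidence level of the interval.
#' @param group_fraction Fraction of total enrolment in the relevant group.
#' @param m_max Search bound.
#' @return A list of class `dx_samplesize`: `p`, `max_width`, `conf`,
#'   `group_fraction`, `m` (group size), `n_total`, `achieved_width`.
#' @export
sample_size_for_ci <- function(p, max_width, conf = 0.95, group_fraction = 1,
                               m_max = 100000L) {
  stopifnot(p > 0, p < 1, max_width > 0, max_width < 1,
            group_fraction > 0, group_fraction <= 1)
  for (m in seq_len(m_max)) {
    x <- floor(p * m + 0.5)
    ci <- clopper_pearson(x, m, conf)
    w <- ci$upper - ci$lower
    if (w <= max_width) {
      return(structure(list(p = p, max_width = max_width, conf = conf,
                            group_fraction = group_fraction, m = m,
                            n_total = as.integer(ceiling(m / group_fraction)),
                            achieved_width = w),
                       class = "dx_samplesize"))
    }
  }
  stop("no group size up to ", m_max, " achieves the requested width")
}

#' @export
print.dx_samplesize <- function(x, ...) {
  cat(sprintf(
    "group size m = %d (achieved %d%% CI width %.3f <= %.3f at p = %.2f)\n",
    x$m, round(100 * x$conf), x$achieved_width, x$max_width, x$p))
  cat(sprintf("total N = %d at group fraction %.2f\n", x$n_total,
              x$group_fraction))
  invisible(x)
}

#' Per-symptom agreement between the two channels
#'
#' For each atom, the fraction of (optionally filtered) respondents whose
#' reference and index answers agree. The conventional filter restricts to
#' the diagnosis-discordant respondents (false positives and false
#' negatives), where symptom-level disagreement concentrates.
#'
#' @param answers Long data frame with columns `id`, `atom`, `reference`,
#'   `index` (the `answers` element of [run_study()]).
#' @param atoms Atoms to tabulate (default [tracked_symptoms()]).
#' @param ids Optional respondent ids to restrict to; an empty selection is
#'   an error naming the filter.
#' @return Named numeric vector of agreement fractions, ascending.
#' @export
symptom_agreement <- function(answers, atoms = tracked_symptoms(), ids = NULL) {
  if (!is.null(ids)) {
    answers <- answers[answers$id %in% ids, , drop = FALSE]
    if (nrow(answers) == 0)
      stop("symptom_agreement: no records left after restricting to ",
           length(ids), " ids")
  }
  if (nrow(answers) == 0) stop("symptom_agreement: empty answer table")
  out <- vapply(atoms, function(a) {
    sub <- answers[answers$atom == a, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$reference == sub$index)
  }, 0)
  sort(out)
}
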