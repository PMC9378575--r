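#' Predictive-value intervals at a fixed prevalence (logit method)
#'
#' Confidence intervals for prevalence-transported PPV/NPV on the logit
#' scale, using the delta-method variances of `log(sens/(1-spec))` and
#' `log(spec/(1-sens))` from the study counts. The method tag records the
#' choice, since several interval constructions exist for transported
#' predictive values.
#'
#' @param t A [contingency_table()] supplying the sens/spec counts.
#' @param prev Target prevalence in `(0, 1)`.
#' @param conf Confidence level.
#' @return List with `ppv` and `npv`, each a `dx_interval`.
#' @export
predictive_value_intervals <- function(t, prev, conf = 0.95) {
  stopifnot(prev > 0, prev < 1)
  r <- core_rates(t)
  n1 <- t$tp + t$fn
  n0 <- t$fp + t$tn
  pv <- predictive_values_at_prevalence(r$sensitivity, r$specificity, prev)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  logit <- function(p) log(p / (1 - p))
  inv <- function(x) 1 / (1 + exp(-x))
  one <- function(point, v) {
    if (is.na(point) || point %in% c(0, 1) || !is.finite(v))
      return(interval(point, NA_real_, NA_real_, conf, "logit (degenerate)"))
    interval(point, inv(logit(point) - z * sqrt(v)),
             inv(logit(point) + z * sqrt(v)), conf, "logit")
  }
  v_ppv <- (1 - r$sensitivity) / (r$sensitivity * n1) +
    r$specificity / ((1 - r$specificity) * n0)
  v_npv <- (1 - r$specificity) / (r$specificity * n0) +
    r$sensitivity / ((1 - r$sensitivity) * n1)
  list(ppv = one(pv$ppv, v_ppv), npv = one(pv$npv, v_npv))
}

#' Assemble the full diagnostic-accuracy report
#'
#' Computes, from paired diagnoses (or a prebuilt 2x2 table), every
#' statistic of the accuracy analysis: the contingency table, sensitivity,
#' specificity, overall accuracy, predictive values and study prevalence
#' with exact Clopper-Pearson intervals; predictive values transported to
#' each extra prevalence with logit intervals; positive and negative
#' likelihood ratios with log-method intervals; unweighted Cohen's kappa
#' with its asymptotic interval and interpretation; Fagan post-test
#' probabilities at a 50% pre-test probability and at the study prevalence;
#' and, when per-atom answer pairs are available, symptom agreement among
#' the diagnosis-discordant respondents.
#'
#' @param x An `hdx_study`, a paired-diagnosis data frame (columns
#'   `reference_labels`, `index_labels`, optionally `id`), or a `dx_table`.
#' @param contrast A [dx_contrast()] or its name.
#' @param extra_prevalences Numeric vector of prevalences to transport
#'   predictive values to (default 0.10, a general-population migraine
#'   prevalence).
#' @param conf Confidence level for every interval.
#' @return A list of class `dx_report`.
#' @export
build_report <- function(x, contrast = dx_contrast("mpm_vs_nom"),
                         extra_prevalences = 0.10, conf = 0.95) {
  if (is.character(contrast)) contrast <- dx_contrast(contrast)
  answers <- NULL
  pairs <- NULL
  if (inherits(x, "hdx_study")) {
    answers <- x$answers
    pairs <- x$diagnoses
    t <- contingency_from_pairs(pairs, contrast)
  } else if (inherits(x, "dx_table")) {
    t <- x
  } else if (is.data.frame(x)) {
    pairs <- x
    t <- contingency_from_pairs(pairs, contrast)
  } else stop("cannot build a report from class ", paste(class(x), collapse = "/"))

  n <- attr(t, "n")
  r <- core_rates(t)
  cp <- function(num, den) if (den > 0) clopper_pearson(num, den, conf) else NULL
  rates <- list(
    sensitivity = cp(t$tp, t$tp + t$fn),
    specificity = cp(t$tn, t$tn + t$fp),
    accuracy = cp(t$tp + t$tn, n),
    ppv = cp(t$tp, t$tp + t$fp),
    npv = cp(t$tn, t$tn + t$fn),
    prevalence = cp(t$tp + t$fn, n))

  lrs <- likelihood_ratios(t, conf)
  kap <- cohen_kappa(t, conf)

  transported <- lapply(extra_prevalences, function(p)
    predictive_value_intervals(t, p, conf))
  names(transported) <- sprintf("prevalence_%g", extra_prevalences)

  fagan <- list(
    positive_at_50 = fagan_posttest(0.5, lrs$lr_pos$point),
    negative_at_50 = fagan_posttest(0.5, lrs$lr_neg$point))
  if (!is.na(r$prevalence) && r$prevalence > 0 && r$prevalence < 1) {
    fagan$positive_at_study <- fagan_posttest(r$prevalence, lrs$lr_pos$point)
    fagan$negative_at_study <- fagan_posttest(r$prevalence, lrs$lr_neg$point)
  }

  discordant_ids <- NULL
  agreement <- NULL
  if (!is.null(pairs) && !is.null(pairs$id)) {
    ref <- vapply(split_labels(pairs$reference_labels), contrast$classify, "")
    idx <- vapply(split_labels(pairs$index_labels), contrast$classify, "")
    disc <- ref != idx & ref != "excluded" & idx != "excluded"
    discordant_ids <- pairs$id[disc]
    if (!is.null(answers) && length(discordant_ids) > 0)
      agreement <- symptom_agreement(answers, tracked_symptoms(),
                                     ids = discordant_ids)
  }

  structure(list(contrast = contrast$name, table = t, n = n,
                 excluded = attr(t, "excluded") %||% 0L,
                 rates = rates, likelihood_ratios = lrs, kappa = kap,
                 predictive_at = transported, fagan = fagan,
                 discordant_count = t$fp + t$fn,
                 discordant_ids = discordant_ids,
                 symptom_agreement = agreement, conf = conf),
            class = "dx_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_pct <- function(ci, digits = 1) {
  if (is.null(ci)) return("undefined")
  sprintf("%.*f%% (%.*f%%-%.*f%%)", digits, 100 * ci$point,
          digits, 100 * ci$lower, digits, 100 * ci$upper)
}

fmt_lr <- function(ci) {
  if (is.null(ci) || is.na(ci$point)) return("undefined")
  if (is.infinite(ci$point)) return("infinite (specificity = 1)")
  d <- if (ci$point >= 10) 1 else 2
  sprintf("%.*f (%.*f-%.*f)", d, ci$point, d, ci$lower, d, ci$upper)
}

#' @export
print.dx_report <- function(x, ...) {
  w <- function(lhs, rhs) cat(sprintf("  %-34s %s\n", lhs, rhs))
  cat("Diagnostic accuracy report - contrast:", x$contrast, "\n")
  cat(sprintf("  2x2 table (n = %d%s): TP %d  FP %d  FN %d  TN %d\n", x$n,
              if (x$excluded > 0) sprintf(", %d excluded", x$excluded) else "",
              x$table$tp, x$table$fp, x$table$fn, x$table$tn))
  pc <- round(100 * x$conf)
  w(sprintf("Accuracy, %% (%d%% CI)", pc), fmt_pct(x$rates$accuracy))
  w(sprintf("Sensitivity, %% (%d%% CI)", pc), fmt_pct(x$rates$sensitivity))
  w(sprintf("Specificity, %% (%d%% CI)", pc), fmt_pct(x$rates$specificity))
  w(sprintf("PPV, %% (%d%% CI)", pc), fmt_pct(x$rates$ppv))
  w(sprintf("NPV, %% (%d%% CI)", pc), fmt_pct(x$rates$npv))
  w(sprintf("Prevalence, %% (%d%% CI)", pc), fmt_pct(x$rates$prevalence))
  for (nm in names(x$predictive_at)) {
    p <- sub("prevalence_", "", nm)
    w(sprintf("PPV at prevalence %s", p), fmt_pct(x$predictive_at[[nm]]$ppv))
    w(sprintf("NPV at prevalence %s", p), fmt_pct(x$predictive_at[[nm]]$npv))
  }
  w(sprintf("LR+, ratio (%d%% CI)", pc), fmt_lr(x$likelihood_ratios$lr_pos))
  w(sprintf("LR-, ratio (%d%% CI)", pc), fmt_lr(x$likelihood_ratios$lr_neg))
  if (is.na(x$kappa$kappa)) {
    w("Cohen's kappa", "undefined")
  } else {
    w(sprintf("Cohen's kappa (%d%% CI)", pc),
      sprintf("%.2f (%.2f-%.2f), %s", x$kappa$kappa, x$kappa$ci$lower,
              x$kappa$ci$upper, x$kappa$interpretation))
  }
  fg <- x$fagan
  w("Post-test, 50% pre-test, positive",
    sprintf("%.0f%%", 100 * fg$positive_at_50$posttest))
  w("Post-test, 50% pre-test, negative",
    sprintf("%.0f%%", 100 * fg$negative_at_50$posttest))
  if (!is.null(fg$positive_at_study)) {
    w("Post-test, study prevalence, positive",
      sprintf("%.0f%%", 100 * fg$positive_at_study$posttest))
    w("Post-test, study prevalence, negative",
      sprintf("%.0f%%", 100 * fg$negative_at_study$posttest))
  }
  w("Discordant records (FP + FN)", as.character(x$discordant_count))
  if (!is.null(x$symptom_agreement)) {
    cat("  Symptom agreement among discordant respondents (ascending):\n")
    for (a in names(x$symptom_agreement))
      cat(sprintf("    %-26s %3.0f%%\n", a, 100 * x$symptom_agreement[[a]]))
  }
  invisible(x)
}
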