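---
title: "Adaptive headache diagnosis and diagnostic accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive headache diagnosis and diagnostic accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headachedx)
```

## The problem

Migraine is chronically under- and misdiagnosed, in part because a careful
criterion-based interview is long: a full structured questionnaire over the
ICHD-3 (International Classification of Headache Disorders, 3rd edition)
criteria asks many questions whose answers, for most respondents, can no
longer change the conclusion. `headachedx` implements the two halves of a
computerized diagnostic instrument and its validation:

1. a rule engine that encodes diagnostic criteria as logic over symptom
   atoms and an interviewing loop that asks only questions that still
   matter, and
2. the statistical machinery used to validate such an instrument against a
   reference standard on a paired cohort: agreement (Cohen's kappa),
   diagnostic accuracy with exact intervals, likelihood ratios, prevalence
   transport, Fagan post-test probabilities, and exact-interval sample
   sizing.

A synthetic cohort simulator stands in for a real paired study so the whole
pipeline is exercisable end to end.

## Criteria as three-valued logic

Each clinical observation is an *atom* with a small categorical domain
(boolean yes/no, or e.g. usual attack duration in
`{<30min, 30min-4h, 4-72h, 72h-7d, >7d}`). Categorical domains — never free
numerics — keep the space of complete answer sets finite, which everything
else exploits. A diagnosis is a *rule*: a label plus a criterion tree over
atoms built from `ALL`, `ANY`, `NOT`, `AT_LEAST(k)` and
`EXACTLY_ONE_FALSE`. The last operator captures the "fulfils all but one
criterion block" structure of probable migraine; its three-valued table
(TRUE iff exactly one child FALSE and none unknown; FALSE iff two children
FALSE or all TRUE; else UNKNOWN) is defined here because no standard
definition exists.

Partial answer sets are evaluated in strong Kleene logic: unanswered atoms
are UNKNOWN, and each operator propagates the three values so that a
determined result (TRUE/FALSE) is guaranteed to hold under every possible
completion of the answers. Two properties matter and are tested:

* **Soundness / monotone refinement.** If `evaluate()` returns a
  determined value on a partial answer set, every extension — and every
  completion — agrees with it.
* **Completeness holds only for distinct-leaf trees.** Kleene evaluation is
  compositional and therefore cannot fold tautologies that arise when one
  atom feeds several leaves (`ANY(x = yes, x = no)` is TRUE under every
  completion yet Kleene-UNKNOWN). The test suite asserts the full
  "UNKNOWN iff completions disagree" equivalence on random trees whose
  leaves test distinct atoms, and one-sided soundness on arbitrary trees.
  The session loop (below) is written so this incompleteness can never
  change a diagnosis.

## The shipped ICHD-3 bank

The default bank covers, over 26 atoms: migraine without aura (1.1),
migraine with aura (1.2), chronic migraine (1.3), probable migraine (1.5),
tension-type headache (2.x), medication-overuse headache (8.2), a five-item
red-flag screen for suspected secondary headache, an "other headache"
catch-all, and a no-headache screen. Design choices where the criteria
leave room:

* **Red flags are a parallel screen.** `secondary_headache_suspected` can
  co-occur with a primary diagnosis rather than suppressing it; ICHD-3's
  criterion E ("not better accounted for...") is approximated by this
  screen plus explicit exclusions inside the probable-migraine rule. Full
  cross-rule differential subsumption is out of scope, as are cluster
  headache and the other trigeminal autonomic cephalalgias.
* **Probable migraine excludes its neighbours explicitly.** The rule is
  `EXACTLY_ONE_FALSE` over 1.1's four blocks or over 1.2's three blocks,
  conjoined with NOT full-1.1, NOT full-1.2, and NOT tension-type. The
  cross-branch exclusions are needed because `EXACTLY_ONE_FALSE` only rules
  out the zero-failure case within its own branch; without them a fully
  migrainous respondent with a two-characteristic aura would be labelled
  both migraine and probable migraine.
* **Aura details are gated on aura presence.** The aura-characteristics
  block is `aura_present AND AT_LEAST(3, ...)`, which makes every
  aura-detail question provably irrelevant the moment the respondent denies
  aura — the behaviour one wants from an adaptive interview.
* **The duration domain is five-valued** so that both migraine's 4–72 h
  window and tension-type's 30 min–7 d window are expressible.

The bank is data, not code: it round-trips through a JSON document
(`save_rulebank()` / `load_rulebank()`), and users can load alternative
banks; all engine guarantees are bank-agnostic.

## The adaptive session

A session fixes a question ordering (screening → red flags → attack
frequency/duration → pain characteristics → associated symptoms → aura →
chronicity/medication, stored in the bank and overridable) and makes one
pass. At each question it decides *relevance*: the question is asked iff
there exist a completion of the current answers and two different answers
to the question under which the resolved label sets differ.

The decision is computed exactly, in three steps. Every rule is partially
evaluated against the current answers (`simplify_expr()`), folding
determined subtrees to constants; a rule whose residual is constant can
never change, and a residual that no longer mentions the question's atom
cannot be swung by it. The remaining residuals' atoms form the question's
*support cone*; all completions of the cone are enumerated (vectorized,
via compilation of residuals to R expressions — on complete assignments
classical and Kleene semantics coincide) and the residual rule values are
compared across the question's possible answers. When the cone exceeds the
enumeration budget (default 14 atoms, or 20 000 completions), the check
falls back to the sound over-approximation "the atom still occurs in some
undetermined rule": the engine may then ask an unnecessary question but
never skips a necessary one, and the transcript flags that the session
used the approximation.

Because irrelevance is monotone under answer-set extension (completions of
an extended answer set are a subset), single-pass skipping is sound, and
on completion the final label set is invariant across all completions of
the partial answer set. Final labels are read off the Kleene statuses
when none is UNKNOWN; in the rare case where a rule that reuses atoms
stays Kleene-UNKNOWN despite label invariance, the session resolves an
arbitrary completion and cross-checks a second, opposite completion. The
engine contract — adaptive labels equal full-questionnaire labels — is
tested on thousands of random latent assignments, and per-question
minimality is certified by a brute-force completion oracle on sub-banks
small enough to enumerate exhaustively. Question *counts* depend on the
ordering (an ordering choice is a user-experience choice, not a
correctness one); final labels do not.

```{r}
bank <- default_question_bank()
tr <- run_session(bank, c(has_headache = "no"))
tr$question_count   # the screening short-circuit: one question asked
```

## The synthetic cohort

`run_study()` emulates a paired-instrument validation study: each
respondent has a latent headache class and a full true symptom assignment
(the reference channel, standing for a specialist interview), and an
index channel obtained by perturbing the true answers and replaying them
through the adaptive engine (standing for computerized self-report).

* **Class mixture.** Defaults put 67% of mass on migraine or probable
  migraine (32% migraine without aura, 8% with aura, 27% probable), with
  20% tension-type, 7% other and 6% headache-free — a tertiary
  headache-clinic case mix. Profiles are built by per-class constructive
  samplers randomized within each class's satisfying envelope, and every
  profile is verified to resolve to exactly its class's labels.
* **Discordance channel.** Each atom's answer flips independently with a
  per-atom probability (uniform over the remaining domain values for
  categorical atoms). Defaults are a *qualitative* calibration to the
  symptom-agreement gradient reported between interview and self-report
  instruments: phonophobia 0.30, activity-aggravation 0.25, photophobia
  0.22, pulsating 0.15, duration 0.10, intensity 0.07, nausea/vomiting
  0.04, zero for aura and unilateral pain. Diagnosis-level agreement data
  alone cannot identify per-symptom discordance probabilities, so these
  are design constants, not estimates, and no claim is made that the
  simulator reproduces any real cohort's exact agreement percentages.
* **What the simulator does not model.** Correlated response errors,
  demographic covariates, respondent fatigue, interviewer probing, and
  multiple headache types per respondent (one session diagnoses one
  headache-type block; looping over types is left to callers). Passing
  simulator-based tests therefore shows the pipeline is correct and
  calibrated to the intended gradient — not that the instrument would
  achieve any particular accuracy on real patients.

Tested simulator guarantees: zero noise gives identity between channels
(kappa exactly 1); the default mixture's migraine/probable mass is 0.67
within binomial error; raising any single atom's discordance does not
increase expected diagnosis-level agreement; identical seeds give
identical studies.

## Accuracy statistics

All estimators work from a 2×2 table (reference status × index status)
produced by one of three outcome contrasts: migraine/probable-migraine vs
no migraine (primary), migraine vs no migraine (probable-migraine records
excluded from both channels), and migraine vs no-migraine/probable.

* Sensitivity, specificity, overall accuracy, predictive values and
  prevalence get exact Clopper–Pearson intervals (Beta-quantile form;
  cross-checked against `binom.test`).
* Accuracy is also available as
  `se·p + sp·(1−p)` at any prevalence; at the table's own prevalence this
  equals `(TP+TN)/n` exactly (tested as an algebraic identity).
* Predictive values transport to other prevalences by Bayes' rule;
  their intervals use the logit (delta-method) construction, tagged
  `"logit"` in the output since several constructions exist. At a 10%
  community prevalence the Table-derived example gives
  PPV 76.5% (45.4–92.7) and NPV 98.8% (98.0–99.2); conventional software
  prints 92.8 for the upper PPV bound, a 0.05-point method difference.
  The same logit construction evaluated at the study prevalence
  reproduces the conventionally printed predictive-value intervals
  (93.9–99.6 and 72.5–87.3) exactly.
* Likelihood ratios use the log-method standard error
  `se(ln LR+) = sqrt(1/TP − 1/(TP+FN) + 1/FP − 1/(FP+TN))`; when a needed
  cell is zero the *interval* uses +0.5 continuity-corrected cells (method
  tag says so) while the point estimate stays raw, so a perfect table
  reports LR− = 0 and an infinite-LR+ flag.
* Unweighted Cohen's kappa uses the asymptotic standard error
  `sqrt(p_o(1−p_o)/(n(1−p_e)^2))` with a normal interval, and the
  conventional interpretation bins (0.81–1.00 "almost perfect", etc.).
  Cross-checked against `e1071::classAgreement`.
* Fagan updates are pure odds algebra:
  `post = (pre-odds × LR)/(1 + pre-odds × LR)`. Note that a post-test
  probability computed from a *rounded* LR can differ visibly in the
  second digit: at 67% pre-test, LR− = 0.11 gives 18% while the unrounded
  0.1137 gives 19%. The package always computes with unrounded values.
* `sample_size_for_ci(p, w, conf, f)` searches the smallest group size
  `m` whose two-sided Clopper–Pearson interval at successes
  `floor(p·m + 0.5)` (half-up rounding, a deterministic convention) has
  width at most `w`, then returns `N = ceiling(m/f)`. With `p = 0.80`,
  `w = 0.15`, 85% confidence: `m = 71`, giving totals 203 at a 35%
  diseased fraction and 110 at 65%.

```{r}
rep <- build_report(contingency_table(121, 2, 15, 64), "mpm_vs_nom",
                    extra_prevalences = 0.10)
print(rep)
```

## Numerical and scale choices

Enumeration budgets default to 14 atoms / 20 000 completions for the
relevance check and 200 000 completions for the test oracle; both refuse
(or fall back soundly) rather than truncate. The test suite runs the
engine contract on 2 000 random latent assignments, certifies minimality
on two sub-banks (6 and 9 atoms) against the exhaustive oracle, checks
simulator calibration at n = 10 000 profiles, and the noise-monotonicity
property on paired cohorts of 5 000 across 10 seeds — sizes chosen to
make binomial error small relative to the effects being asserted.
Undefined rates (zero denominators) are reported as `NA` with the
degenerate case documented, never as errors. All randomness flows through
R's RNG and is seedable at every entry point.

## Known limitations

The shipped bank is a reduced criterion set: no TACs, no pediatric
variants, no fifth-digit subtypes, and criterion E only as the
approximation described above. The engine handles one headache type per
session. The simulator's independence assumptions are stated above.
Printed-table re-analysis (`pairs_from_table()`) reconstructs label sets
only up to the contrast's resolution — sufficient for every statistic the
report computes, but not a respondent-level dataset.
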