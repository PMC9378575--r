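# Shared fixtures, built in code.

# A full answer set satisfying every block of migraine without aura, with no
# red flags and episodic frequency.
mwoa_full_answers <- function() {
  c(has_headache = "yes", rf_thunderclap = "no", rf_systemic = "no",
    rf_neuro_deficit = "no", rf_onset_after_50 = "no",
    rf_pattern_change = "no", attack_count = ">=5", duration = "4-72h",
    unilateral = "yes", pulsating = "yes", intensity = "severe",
    aggravation_activity = "yes", nausea_vomiting = "yes",
    photophobia = "yes", phonophobia = "yes", aura_present = "no",
    aura_reversible = "no", aura_gradual_spread = "no",
    aura_succession = "no", aura_duration_5_60 = "no",
    aura_unilateral_symptom = "no", aura_positive_phenomenon = "no",
    aura_headache_within_60 = "no", headache_days = "<15",
    months_ge3 = "yes", acute_med_days = "<10")
}

rand_full_assignment <- function(rs) {
  vapply(rs$atoms, function(a) a$domain[sample.int(length(a$domain), 1L)], "")
}

# Independent classical evaluator for *complete* assignments: counts child
# truths directly, no short-circuiting, no Kleene bookkeeping. Base oracle
# for the Kleene-soundness property.
classical_eval <- function(e, full) {
  if (e$op == "atom_equals") return(unname(full[[e$atom]] == e$value))
  vals <- vapply(e$children, classical_eval, NA, full = full)
  switch(e$op,
    not = !vals[1],
    all = all(vals),
    any = any(vals),
    at_least = sum(vals) >= e$k,
    exactly_one_false = sum(!vals) == 1)
}

# Random expression trees over a small boolean atom bank.
rand_expr <- function(atom_ids, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(atom_eq(sample(atom_ids, 1), sample(c("yes", "no"), 1)))
  }
  nk <- sample(2:4, 1)
  kids <- replicate(nk, rand_expr(atom_ids, depth - 1), simplify = FALSE)
  op <- sample(c("not", "all", "any", "at_least", "exactly_one_false"), 1)
  switch(op,
    not = e_not(kids[[1]]),
    all = do.call(e_all, kids),
    any = do.call(e_any, kids),
    at_least = do.call(at_least, c(list(sample(nk, 1)), kids)),
    exactly_one_false = do.call(exactly_one_false, kids))
}

# Random expression tree in which every leaf tests a distinct atom (split
# the atom list across subtrees). For such trees Kleene evaluation is not
# just sound but complete wrt completions.
rand_expr_distinct <- function(atom_ids) {
  if (length(atom_ids) == 1L || stats::runif(1) < 0.25)
    return(atom_eq(atom_ids[1], sample(c("yes", "no"), 1)))
  ng <- sample(2:min(4, length(atom_ids)), 1)
  groups <- split(atom_ids, sort(rep_len(seq_len(ng), length(atom_ids))))
  kids <- lapply(groups, rand_expr_distinct)
  op <- sample(c("not", "all", "any", "at_least", "exactly_one_false"), 1)
  switch(op,
    not = e_not(kids[[1]]),
    all = do.call(e_all, kids),
    any = do.call(e_any, kids),
    at_least = do.call(at_least, c(list(sample(length(kids), 1)), kids)),
    exactly_one_false = do.call(exactly_one_false, kids))
}

# All completions of a partial assignment over boolean atoms, as a list.
bool_completions <- function(atom_ids, partial) {
  free <- setdiff(atom_ids, names(partial))
  if (!length(free)) return(list(partial))
  grid <- expand.grid(rep(list(c("yes", "no")), length(free)),
                      stringsAsFactors = FALSE)
  names(grid) <- free
  lapply(seq_len(nrow(grid)), function(i)
    c(partial, unlist(grid[i, , drop = FALSE])))
}

# Tiny two-rule screening sub-bank: a headache screen plus the red-flag
# alert (6 boolean atoms).
redflag_subbank <- function() {
  flags <- c("rf_thunderclap", "rf_systemic", "rf_neuro_deficit",
             "rf_onset_after_50", "rf_pattern_change")
  atoms <- c(list(atom("has_headache")), lapply(flags, atom))
  rules <- list(
    rule("R-NoHeadache", "no_headache", atom_eq("has_headache", "no")),
    rule("R-RedFlag", "secondary_headache_suspected",
         do.call(e_all, c(list(atom_eq("has_headache", "yes")),
                          list(do.call(e_any, lapply(flags, atom_eq,
                                                     value = "yes")))))))
  rs <- ruleset(atoms, rules, version = "test-redflag")
  qs <- lapply(seq_along(atoms), function(i)
    question(paste0("Q", i), atoms[[i]]$id, atoms[[i]]$id, i))
  list(rs = rs, bank = question_bank(qs, rs))
}

# Tension-type sub-bank: 9 atoms, three rules, small enough for the
# brute-force oracle (5760 completions).
tth_subbank <- function() {
  atoms <- list(
    atom("has_headache"),
    atom("duration", c("<30min", "30min-4h", "4-72h", "72h-7d", ">7d")),
    atom("unilateral"), atom("pulsating"),
    atom("intensity", c("mild", "moderate", "severe")),
    atom("aggravation_activity"), atom("nausea_vomiting"),
    atom("photophobia"), atom("phonophobia"))
  hh <- atom_eq("has_headache", "yes")
  tth_dur <- e_any(atom_eq("duration", "30min-4h"), atom_eq("duration", "4-72h"),
                   atom_eq("duration", "72h-7d"))
  tth_c <- at_least(2, atom_eq("unilateral", "no"), atom_eq("pulsating", "no"),
                    e_any(atom_eq("intensity", "mild"),
                          atom_eq("intensity", "moderate")),
                    atom_eq("aggravation_activity", "no"))
  tth_d <- e_all(atom_eq("nausea_vomiting", "no"),
                 e_not(e_all(atom_eq("photophobia", "yes"),
                             atom_eq("phonophobia", "yes"))))
  tth <- e_all(hh, tth_dur, tth_c, tth_d)
  rules <- list(
    rule("R-NoHeadache", "no_headache", atom_eq("has_headache", "no")),
    rule("R-TTH", "tension_type", tth),
    rule("R-Other", "other_headache", e_all(hh, e_not(tth))))
  rs <- ruleset(atoms, rules, version = "test-tth")
  qs <- lapply(seq_along(atoms), function(i)
    question(paste0("Q", i), atoms[[i]]$id, atoms[[i]]$id, i))
  list(rs = rs, bank = question_bank(qs, rs))
}

# Replay a transcript against the brute-force oracle: every asked question
# must be relevant at its ask time, every skipped question irrelevant at
# its skip time. Returns a list of failures (empty = pass).
audit_transcript_with_oracle <- function(rs, bank, tr) {
  failures <- list()
  answers <- character(0)
  asked_ids <- tr$asked$question_id
  for (q in bank$questions) {
    if (q$id %in% asked_ids) {
      if (!oracle_is_relevant(rs, answers, q$atom_id))
        failures[[length(failures) + 1L]] <-
          paste("asked but oracle-irrelevant:", q$id)
      i <- match(q$id, asked_ids)
      answers[tr$asked$atom_id[i]] <- tr$asked$answer[i]
    } else {
      if (oracle_is_relevant(rs, answers, q$atom_id))
        failures[[length(failures) + 1L]] <-
          paste("skipped but oracle-relevant:", q$id)
    }
  }
  failures
}
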