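test_that("threshold operators decide as early as the answers allow", {
  rs <- ruleset(lapply(paste0("a", 1:4), atom), list(
    rule("r", "lab", at_least(2, atom_eq("a1", "yes"), atom_eq("a2", "yes"),
                              atom_eq("a3", "yes"), atom_eq("a4", "yes")))))
  e <- rs$rules[["r"]]$expression
  # two TRUE children already suffice, one child still unanswered
  expect_true(evaluate(e, c(a1 = "yes", a2 = "yes", a3 = "no")))
  # at most one child can still become TRUE
  expect_false(evaluate(e, c(a1 = "no", a2 = "no", a3 = "no")))
  # undecided: the unknown children straddle the threshold
  expect_identical(evaluate(e, c(a1 = "yes", a2 = "no", a3 = "no")), NA)
})

test_that("exactly-one-false follows its three-valued table", {
  e <- exactly_one_false(atom_eq("a1", "yes"), atom_eq("a2", "yes"),
                         atom_eq("a3", "yes"))
  # one FALSE, one UNKNOWN: completions disagree (TRUE vs FALSE)
  expect_identical(evaluate(e, c(a1 = "yes", a2 = "no")), NA)
  expect_true(evaluate(e, c(a1 = "yes", a2 = "no", a3 = "yes")))
  # zero failures is a failure of the "all but one" reading
  expect_false(evaluate(e, c(a1 = "yes", a2 = "yes", a3 = "yes")))
  expect_false(evaluate(e, c(a1 = "no", a2 = "no")))
  # all TRUE but one child unknown: could end with zero or one FALSE
  expect_identical(evaluate(e, c(a1 = "yes", a2 = "yes")), NA)
})

test_that("a determined Kleene result agrees with every completion", {
  # soundness on arbitrary trees (atoms may repeat across leaves)
  set.seed(41)
  atoms <- paste0("a", 1:6)
  for (rep in 1:60) {
    e <- rand_expr(atoms)
    n_assigned <- sample(0:6, 1)
    partial <- stats::setNames(sample(c("yes", "no"), n_assigned, TRUE),
                               sample(atoms, n_assigned))
    got <- evaluate(e, partial)
    if (is.na(got)) next
    outcomes <- unique(vapply(bool_completions(atoms, partial),
                              function(full) classical_eval(e, full), NA))
    expect_identical(outcomes, got)
  }
})

test_that("on distinct-leaf trees Kleene evaluation is exactly completion logic", {
  # with each atom tested by at most one leaf there are no hidden
  # tautologies, and UNKNOWN holds exactly when completions disagree
  set.seed(45)
  atoms <- paste0("a", 1:8)
  for (rep in 1:60) {
    e <- rand_expr_distinct(atoms)
    n_assigned <- sample(0:8, 1)
    partial <- stats::setNames(sample(c("yes", "no"), n_assigned, TRUE),
                               sample(atoms, n_assigned))
    got <- evaluate(e, partial)
    outcomes <- unique(vapply(bool_completions(atoms, partial),
                              function(full) classical_eval(e, full), NA))
    if (length(outcomes) == 1L) {
      expect_identical(got, outcomes)
    } else {
      expect_identical(got, NA)
    }
  }
})

test_that("a determined result never changes under answer-set extension", {
  set.seed(42)
  atoms <- paste0("a", 1:6)
  for (rep in 1:60) {
    e <- rand_expr(atoms)
    n_assigned <- sample(0:5, 1)
    partial <- stats::setNames(sample(c("yes", "no"), n_assigned, TRUE),
                               sample(atoms, n_assigned))
    got <- evaluate(e, partial)
    if (is.na(got)) next
    ext <- partial
    for (a in setdiff(atoms, names(partial))) {
      ext[a] <- sample(c("yes", "no"), 1)
      expect_identical(evaluate(e, ext), got)
    }
  }
})

test_that("complete assignments never evaluate to UNKNOWN", {
  set.seed(43)
  atoms <- paste0("a", 1:6)
  for (rep in 1:40) {
    e <- rand_expr(atoms)
    full <- stats::setNames(sample(c("yes", "no"), 6, TRUE), atoms)
    expect_false(is.na(evaluate(e, full)))
  }
})

test_that("partial evaluation and compilation agree with direct evaluation", {
  set.seed(44)
  atoms <- paste0("a", 1:6)
  for (rep in 1:50) {
    e <- rand_expr(atoms)
    n_assigned <- sample(0:6, 1)
    partial <- stats::setNames(sample(c("yes", "no"), n_assigned, TRUE),
                               sample(atoms, n_assigned))
    resid <- simplify_expr(e, partial)
    for (full in bool_completions(atoms, partial)) {
      want <- evaluate(e, full)
      got <- if (is.logical(resid)) resid else evaluate(resid, full)
      expect_identical(got, want)
      # the vectorized compiler agrees on complete assignments
      expect_identical(unname(headachedx:::compile_expr(e)(as.list(full))),
                       want)
    }
  }
})

test_that("validation rejects malformed banks and answers", {
  expect_error(atom("x", c("yes")), "2-5 distinct")
  expect_error(at_least(3, atom_eq("a", "yes")), "k")
  expect_error(ruleset(list(atom("a")),
                       list(rule("r", "l", atom_eq("b", "yes")))),
               "unknown atom 'b'")
  expect_error(ruleset(list(atom("a")),
                       list(rule("r", "l", atom_eq("a", "maybe")))),
               "not in domain")
  rs <- ruleset(list(atom("a")), list(rule("r", "l", atom_eq("a", "yes"))))
  expect_error(validate_answers(c(zz = "yes"), rs), "unknown atoms")
  expect_error(validate_answers(c(a = "maybe"), rs), "not in domain")
})
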