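#' Would answering a question still change the diagnostic impression?
#'
#' A question is *irrelevant* when, for every complete extension of the
#' current answers, all possible answers to it lead to the same resolved
#' label set — in which case skipping it is sound. Relevance is decided
#' exactly by enumerating the question's "support cone": the unassigned
#' atoms that co-occur with the question's atom in rules whose status is
#' still UNKNOWN. Determined rules cannot change under any extension
#' (monotone refinement), so only those rules and atoms matter.
#'
#' When the cone exceeds the enumeration budget the check falls back to a
#' sound over-approximation — "the atom occurs in some UNKNOWN-status rule"
#' — which may ask an unnecessary question but never skips a necessary one;
#' the fallback is flagged via `exact = FALSE`.
#'
#' @param q A [question()] or an atom id.
#' @param rs The [ruleset()].
#' @param answers Current partial answers (named character vector).
#' @param budget Maximum cone size (number of unassigned atoms) enumerated
#'   exactly; default 14.
#' @param max_completions Cap on the number of enumerated completions
#'   (guards categorical domains).
#' @return List with `relevant` (logical) and `exact` (logical: whether the
#'   decision was certified by enumeration).
#' @export
is_relevant <- function(q, rs, answers, budget = 14L, max_completions = 20000L) {
  atom_id <- if (inherits(q, "hdx_question")) q$atom_id else q
  if (atom_id %in% names(answers))
    stop("question's atom '", atom_id, "' is already answered")
  # partial-evaluate the rules: a rule folded to a constant is determined
  # and cannot change; a residual that no longer mentions the atom provably
  # cannot be swung by it; enumeration then only walks small residual trees
  residuals <- lapply(rs$rules, function(r) {
    if (atom_id %in% r$atoms) simplify_expr(r$expression, answers) else FALSE
  })
  relevance_check(rs, residuals, atom_id, budget, max_completions)
}

# Core of the relevance decision, shared by is_relevant() (residuals from
# scratch) and the session loop (residuals maintained incrementally).
relevance_check <- function(rs, residuals, atom_id, budget, max_completions) {
  residuals <- Filter(function(e)
    !is.logical(e) && atom_id %in% expr_atoms(e), residuals)
  if (length(residuals) == 0L)
    return(list(relevant = FALSE, exact = TRUE))
  cone <- setdiff(unique(unlist(lapply(residuals, expr_atoms))), atom_id)
  ncomp <- prod(vapply(rs$atoms[cone], function(a) length(a$domain), 0))
  if (length(cone) > budget || ncomp > max_completions)
    return(list(relevant = TRUE, exact = FALSE))
  compiled <- lapply(residuals, compile_expr)
  env <- if (length(cone)) {
    as.list(expand.grid(lapply(rs$atoms[cone], `[[`, "domain"),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  } else list()
  names(env) <- cone
  ref <- NULL
  for (v in rs$atoms[[atom_id]]$domain) {
    env[[atom_id]] <- v
    vals <- lapply(compiled, function(f) f(env))
    if (is.null(ref)) ref <- vals
    else for (j in seq_along(vals))
      if (any(vals[[j]] != ref[[j]]))
        return(list(relevant = TRUE, exact = TRUE))
  }
  list(relevant = FALSE, exact = TRUE)
}

#' Start an adaptive interview session
#'
#' A session walks the bank's questions once, in order; at each question it
#' asks only if the answer can still change the final impression
#' ([is_relevant()]), otherwise records a skip. Because irrelevance is
#' monotone under answer-set extension, a single pass suffices and the final
#' label set equals the one the full questionnaire would produce.
#'
#' @param bank A [question_bank()].
#' @param budget Enumeration budget passed to [is_relevant()].
#' @return An environment of class `hdx_session`.
#' @seealso [next_question()], [answer_question()], [run_session()]
#' @export
new_session <- function(bank, budget = 14L) {
  s <- new.env(parent = emptyenv())
  s$bank <- bank
  s$rs <- bank$ruleset
  s$answers <- character(0)
  s$cursor <- 1L
  s$asked <- list()
  s$skipped <- character(0)
  s$exact <- TRUE
  s$resid <- lapply(bank$ruleset$rules, `[[`, "expression")
  s$status <- "in-progress"
  s$pending <- NULL
  s$budget <- as.integer(budget)
  class(s) <- "hdx_session"
  s
}

#' Advance a session to its next relevant question
#'
#' Moves the cursor past irrelevant questions (recording them as skipped)
#' and returns the first question whose answer can still matter, or `NULL`
#' once the pass is complete. On completion the resolved label set is
#' invariant across all completions of the final answer set, and no rule
#' status remains UNKNOWN.
#'
#' @param session A session from [new_session()].
#' @return An `hdx_question`, or `NULL` when the session is complete.
#' @export
next_question <- function(session) {
  if (!is.null(session$pending)) return(session$pending)
  if (session$status == "complete") return(NULL)
  qs <- session$bank$questions
  while (session$cursor <= length(qs)) {
    q <- qs[[session$cursor]]
    rel <- relevance_check(session$rs, session$resid, q$atom_id,
                           session$budget, 20000L)
    if (!rel$exact) session$exact <- FALSE
    if (rel$relevant) {
      session$pending <- q
      return(q)
    }
    session$skipped <- c(session$skipped, q$id)
    session$cursor <- session$cursor + 1L
  }
  session$status <- "complete"
  NULL
}

#' Record the answer to the pending question
#'
#' @param session A session with a pending question from [next_question()].
#' @param value An answer in the question atom's domain.
#' @return The session, invisibly.
#' @export
answer_question <- function(session, value) {
  q <- session$pending
  if (is.null(q)) stop("no pending question; call next_question() first")
  dom <- session$rs$atoms[[q$atom_id]]$domain
  if (!is.character(value) || length(value) != 1L || !value %in% dom)
    stop("answer '", value, "' not in domain of atom '", q$atom_id,
         "' (", paste(dom, collapse = "/"), ")")
  session$answers[q$atom_id] <- value
  upd <- stats::setNames(value, q$atom_id)
  session$resid <- lapply(session$resid, function(e)
    if (is.logical(e)) e else simplify_expr(e, upd))
  session$asked[[length(session$asked) + 1L]] <-
    list(question_id = q$id, atom_id = q$atom_id, answer = value)
  session$pending <- NULL
  session$cursor <- session$cursor + 1L
  invisible(session)
}

#' Run a complete adaptive session against a responder
#'
#' Drives [next_question()] to completion, querying `responder` for each
#' asked question. The central correctness contract: when the responder
#' answers from a fixed full latent assignment, the transcript's final
#' labels equal `resolve(ruleset, full assignment)$labels`.
#'
#' @param bank A [question_bank()].
#' @param responder Either a function `function(question) -> value` or a
#'   full named answer vector to replay.
#' @param budget Enumeration budget for the relevance check.
#' @return A list of class `hdx_transcript`: `asked` (data frame of
#'   question id, atom, answer in ask order), `skipped` (question ids),
#'   `labels` (final resolved labels), `question_count`, and `exact`
#'   (FALSE when any relevance decision fell back to the sound
#'   over-approximation).
#' @export
run_session <- function(bank, responder, budget = 14L) {
  if (is.character(responder)) {
    latent <- validate_answers(responder, bank$ruleset)
    responder <- function(q) {
      v <- latent[q$atom_id]
      if (is.na(v)) stop("responder has no value for atom '", q$atom_id, "'")
      unname(v)
    }
  }
  s <- new_session(bank, budget = budget)
  repeat {
    q <- next_question(s)
    if (is.null(q)) break
    answer_question(s, responder(q))
  }
  imp <- resolve(s$rs, s$answers, validate = FALSE)
  if (!anyNA(imp$status)) {
    labels <- imp$labels
  } else {
    # Kleene evaluation is sound but not complete: a rule whose tree reuses
    # atoms can stay UNKNOWN even though every completion agrees. The skip
    # logic guarantees label invariance across completions, so resolve one;
    # two opposite-corner completions guard the invariant at run time.
    free <- setdiff(names(s$rs$atoms), names(s$answers))
    lo <- vapply(s$rs$atoms[free], function(a) a$domain[1], "")
    hi <- vapply(s$rs$atoms[free], function(a) a$domain[length(a$domain)], "")
    l1 <- resolve(s$rs, c(s$answers, lo), validate = FALSE)$labels
    l2 <- resolve(s$rs, c(s$answers, hi), validate = FALSE)$labels
    if (!identical(sort(l1), sort(l2)))
      stop("internal error: label set not invariant at session completion")
    labels <- l1
  }
  asked <- if (length(s$asked)) {
    data.frame(question_id = vapply(s$asked, `[[`, "", "question_id"),
               atom_id = vapply(s$asked, `[[`, "", "atom_id"),
               answer = vapply(s$asked, `[[`, "", "answer"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(question_id = character(0), atom_id = character(0),
               answer = character(0))
  }
  structure(list(asked = asked, skipped = s$skipped, labels = labels,
                 answers = s$answers, question_count = nrow(asked),
                 exact = s$exact),
            class = "hdx_transcript")
}

#' @export
print.hdx_transcript <- function(x, ...) {
  cat("Adaptive interview transcript\n")
  cat("  asked:", x$question_count, "questions; skipped:",
      length(x$skipped), "\n")
  cat("  labels:", if (length(x$labels)) paste(x$labels, collapse = ", ")
      else "(none)", "\n")
  if (!x$exact)
    cat("  note: some relevance checks used the sound over-approximation\n")
  invisible(x)
}
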