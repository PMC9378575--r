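#' Criterion expressions over symptom atoms
#'
#' Diagnostic criteria are represented as finite operator trees whose leaves
#' test a single symptom atom against one value of its answer domain.
#' Supported operators:
#'
#' * `atom_eq(atom, value)` — leaf; TRUE/FALSE once the atom is answered,
#'   UNKNOWN while it is not.
#' * `e_not(x)`, `e_all(...)`, `e_any(...)` — strong-Kleene negation,
#'   conjunction and disjunction.
#' * `at_least(k, ...)` — at least `k` of the children TRUE; encodes the
#'   "at least 2 of 4 pain characteristics" style of ICHD-3 criterion.
#' * `exactly_one_false(...)` — exactly one child FALSE and all others TRUE;
#'   encodes the "fulfils all but one criterion" structure of probable
#'   migraine. Its three-valued table: TRUE when exactly one child is FALSE
#'   and none UNKNOWN; FALSE when two or more children are FALSE, or when
#'   all children are TRUE; UNKNOWN otherwise.
#'
#' Expressions are plain nested lists with an `op` discriminator, so they
#' serialize naturally to JSON (see [save_rulebank()]).
#'
#' @param atom Atom id (string).
#' @param value One value of the atom's domain (string).
#' @param x,... Child expressions.
#' @param k Integer threshold, `1 <= k <=` number of children.
#' @return An expression node (list with class `hdx_expr`).
#' @examples
#' e <- at_least(2, atom_eq("unilateral", "yes"), atom_eq("pulsating", "yes"),
#'               atom_eq("aggravation_activity", "yes"))
#' @name expressions
NULL

new_expr <- function(op, ...) {
  structure(list(op = op, ...), class = "hdx_expr")
}

#' @rdname expressions
#' @export
atom_eq <- function(atom, value) {
  stopifnot(is.character(atom), length(atom) == 1L,
            is.character(value), length(value) == 1L)
  new_expr("atom_equals", atom = atom, value = value)
}

#' @rdname expressions
#' @export
e_not <- function(x) new_expr("not", children = list(x))

#' @rdname expressions
#' @export
e_all <- function(...) new_expr("all", children = list(...))

#' @rdname expressions
#' @export
e_any <- function(...) new_expr("any", children = list(...))

#' @rdname expressions
#' @export
at_least <- function(k, ...) {
  children <- list(...)
  stopifnot(length(k) == 1L, k >= 1L, k <= length(children))
  new_expr("at_least", k = as.integer(k), children = children)
}

#' @rdname expressions
#' @export
exactly_one_false <- function(...) new_expr("exactly_one_false", children = list(...))

#' @export
print.hdx_expr <- function(x, ...) {
  cat(deparse_expr(x), "\n")
  invisible(x)
}

deparse_expr <- function(e) {
  switch(e$op,
    atom_equals = sprintf("%s == %s", e$atom, dQuote(e$value, FALSE)),
    not = sprintf("NOT(%s)", deparse_expr(e$children[[1]])),
    all = sprintf("ALL(%s)", paste(vapply(e$children, deparse_expr, ""), collapse = ", ")),
    any = sprintf("ANY(%s)", paste(vapply(e$children, deparse_expr, ""), collapse = ", ")),
    at_least = sprintf("AT_LEAST(%d; %s)", e$k,
                       paste(vapply(e$children, deparse_expr, ""), collapse = ", ")),
    exactly_one_false = sprintf("EXACTLY_ONE_FALSE(%s)",
                                paste(vapply(e$children, deparse_expr, ""), collapse = ", ")),
    stop("unknown op: ", e$op)
  )
}

#' Atoms referenced by an expression
#'
#' @param e An expression built with the [expressions] constructors.
#' @return Character vector of distinct atom ids appearing in `e`.
#' @export
expr_atoms <- function(e) {
  if (e$op == "atom_equals") return(e$atom)
  unique(unlist(lapply(e$children, expr_atoms), use.names = FALSE))
}

#' Evaluate an expression under a partial answer set
#'
#' Three-valued (strong Kleene) evaluation: unanswered atoms contribute
#' UNKNOWN, represented as `NA`. The result is `TRUE`, `FALSE`, or `NA`
#' (UNKNOWN). A complete answer set never yields `NA`.
#'
#' Threshold semantics: `at_least(k, ...)` is TRUE as soon as at least `k`
#' children are TRUE, FALSE once fewer than `k` children can still become
#' TRUE, and UNKNOWN otherwise. `exactly_one_false` follows the table
#' documented in [expressions].
#'
#' @param expr Expression node.
#' @param answers Named character vector mapping atom ids to answered values;
#'   atoms absent from the vector are UNKNOWN.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
evaluate <- function(expr, answers) {
  op <- expr$op
  if (op == "atom_equals") {
    v <- answers[expr$atom]
    if (is.na(v)) return(NA)
    return(unname(v == expr$value))
  }
  if (op == "not") return(!evaluate(expr$children[[1]], answers))
  kids <- expr$children
  nT <- 0L; nF <- 0L; nU <- 0L
  if (op == "all") {
    for (ch in kids) {
      v <- evaluate(ch, answers)
      if (isFALSE(v)) return(FALSE)
      if (is.na(v)) nU <- nU + 1L
    }
    return(if (nU > 0L) NA else TRUE)
  }
  if (op == "any") {
    for (ch in kids) {
      v <- evaluate(ch, answers)
      if (isTRUE(v)) return(TRUE)
      if (is.na(v)) nU <- nU + 1L
    }
    return(if (nU > 0L) NA else FALSE)
  }
  if (op == "at_least") {
    k <- expr$k
    left <- length(kids)
    for (ch in kids) {
      v <- evaluate(ch, answers)
      left <- left - 1L
      if (isTRUE(v)) {
        nT <- nT + 1L
        if (nT >= k) return(TRUE)
      } else if (is.na(v)) nU <- nU + 1L
      if (nT + nU + left < k) return(FALSE)
    }
    return(if (nT + nU < k) FALSE else NA)
  }
  if (op == "exactly_one_false") {
    for (ch in kids) {
      v <- evaluate(ch, answers)
      if (isFALSE(v)) {
        nF <- nF + 1L
        if (nF >= 2L) return(FALSE)
      } else if (is.na(v)) nU <- nU + 1L
    }
    if (nF == 0L && nU == 0L) return(FALSE)
    if (nF == 1L && nU == 0L) return(TRUE)
    return(NA)
  }
  stop("unknown op: ", op)
}

#' Partially evaluate an expression under the current answers
#'
#' Constant-folds every subtree whose value is already determined by the
#' answered atoms, returning either a bare logical (`TRUE`/`FALSE`) or a
#' reduced expression over unanswered atoms only. For every complete
#' extension of `answers`, evaluating the residual equals evaluating the
#' original — which is what lets the relevance check enumerate completions
#' over small residual trees instead of whole criterion trees.
#'
#' @inheritParams evaluate
#' @return `TRUE`, `FALSE`, or a reduced `hdx_expr`.
#' @export
simplify_expr <- function(expr, answers) {
  op <- expr$op
  if (op == "atom_equals") {
    v <- answers[expr$atom]
    if (is.na(v)) return(expr)
    return(unname(v == expr$value))
  }
  kids <- lapply(expr$children, simplify_expr, answers = answers)
  const <- vapply(kids, is.logical, NA)
  if (op == "not") {
    return(if (const[1]) !kids[[1]] else new_expr("not", children = kids))
  }
  vals <- rep(NA, length(kids))
  vals[const] <- unlist(kids[const])
  open <- kids[!const]
  if (op == "all") {
    if (any(vals %in% FALSE)) return(FALSE)
    if (length(open) == 0L) return(TRUE)
    if (length(open) == 1L) return(open[[1]])
    return(new_expr("all", children = open))
  }
  if (op == "any") {
    if (any(vals %in% TRUE)) return(TRUE)
    if (length(open) == 0L) return(FALSE)
    if (length(open) == 1L) return(open[[1]])
    return(new_expr("any", children = open))
  }
  if (op == "at_least") {
    k <- expr$k - sum(vals %in% TRUE)
    if (k <= 0L) return(TRUE)
    if (k > length(open)) return(FALSE)
    if (k == 1L && length(open) == 1L) return(open[[1]])
    return(new_expr("at_least", k = as.integer(k), children = open))
  }
  if (op == "exactly_one_false") {
    nF <- sum(vals %in% FALSE)
    if (nF >= 2L) return(FALSE)
    if (nF == 1L) {
      if (length(open) == 0L) return(TRUE)
      if (length(open) == 1L) return(open[[1]])
      return(new_expr("all", children = open))
    }
    if (length(open) == 0L) return(FALSE)  # every child TRUE
    if (length(open) == 1L) return(new_expr("not", children = open))
    return(new_expr("exactly_one_false", children = open))
  }
  stop("unknown op: ", op)
}

# Compile an expression to a vectorized evaluator over *complete*
# assignments: `env` maps each referenced atom to a character vector (or a
# length-1 constant), and the result is a logical vector. On complete
# assignments three-valued and classical semantics coincide, which is what
# makes the completion-enumeration paths vectorizable. Internal.
compile_expr <- function(e) {
  build <- function(e) {
    switch(e$op,
      atom_equals = bquote(.env[[.(e$atom)]] == .(e$value)),
      not = bquote(!.(build(e$children[[1]]))),
      all = Reduce(function(a, b) bquote(.(a) & .(b)),
                   lapply(e$children, build)),
      any = Reduce(function(a, b) bquote(.(a) | .(b)),
                   lapply(e$children, build)),
      at_least = {
        s <- Reduce(function(a, b) bquote(.(a) + .(b)),
                    lapply(e$children, function(ch) bquote((.(build(ch))))))
        bquote((.(s)) >= .(e$k))
      },
      exactly_one_false = {
        s <- Reduce(function(a, b) bquote(.(a) + .(b)),
                    lapply(e$children, function(ch) bquote((!.(build(ch))))))
        bquote((.(s)) == 1L)
      },
      stop("unknown op: ", e$op))
  }
  body <- build(e)
  function(env) eval(body, list(.env = env))
}
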