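#' Construct a symptom atom
#'
#' An atom is one elementary clinical observation (e.g. "headache is
#' unilateral", "usual attack duration") with a small finite answer domain —
#' boolean yes/no or an ordered categorical with at most 5 levels. Keeping
#' domains categorical keeps the space of complete answer sets finite, which
#' the completion oracle and the relevance check rely on.
#'
#' @param id Atom identifier, unique within a rule bank.
#' @param domain Character vector of 2–5 allowed answer values.
#' @param prompt_key Identifier linking the atom to its interview question
#'   (defaults to the atom id).
#' @return A list of class `hdx_atom`.
#' @export
atom <- function(id, domain = c("yes", "no"), prompt_key = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  domain <- as.character(domain)
  if (length(domain) < 2L || length(domain) > 5L || anyDuplicated(domain))
    stop("atom '", id, "': domain must hold 2-5 distinct values")
  structure(list(id = id, domain = domain, prompt_key = prompt_key),
            class = "hdx_atom")
}

#' Construct a diagnostic rule
#'
#' @param id Rule identifier.
#' @param label Diagnosis label emitted when the rule's expression is TRUE
#'   (labels are unique across a rule set).
#' @param expression Criterion expression (see [expressions]).
#' @param precedence Integer used only to order labels in reports.
#' @return A list of class `hdx_rule`.
#' @export
rule <- function(id, label, expression, precedence = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(label), length(label) == 1L,
            inherits(expression, "hdx_expr"))
  structure(list(id = id, label = label, expression = expression,
                 precedence = as.integer(precedence),
                 atoms = expr_atoms(expression)),
            class = "hdx_rule")
}

#' Assemble and validate a rule set
#'
#' A rule set bundles the atom bank and the diagnostic rules evaluated over
#' it. Construction validates that every referenced atom exists, every
#' `atom_eq` value lies in its atom's domain, `at_least` thresholds are in
#' range, and ids/labels are unique.
#'
#' @param atoms List of [atom()] objects.
#' @param rules List of [rule()] objects.
#' @param version Free-form version tag carried through serialization.
#' @return A list of class `hdx_ruleset` with named elements `atoms`,
#'   `rules`, `version`.
#' @export
ruleset <- function(atoms, rules, version = "0") {
  ids <- vapply(atoms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate atom ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(atoms) <- ids
  rids <- vapply(rules, `[[`, "", "id")
  labs <- vapply(rules, `[[`, "", "label")
  if (anyDuplicated(rids)) stop("duplicate rule ids")
  if (anyDuplicated(labs)) stop("duplicate rule labels")
  names(rules) <- rids
  rs <- structure(list(atoms = atoms, rules = rules, version = version),
                  class = "hdx_ruleset")
  for (r in rules) validate_expr(r$expression, rs, where = paste0("rule '", r$id, "'"))
  rs
}

validate_expr <- function(e, rs, where = "expression") {
  if (!is.list(e) || is.null(e$op))
    stop(where, ": malformed expression node")
  if (e$op == "atom_equals") {
    a <- rs$atoms[[e$atom]]
    if (is.null(a))
      stop(where, ": unknown atom '", e$atom, "'")
    if (!e$value %in% a$domain)
      stop(where, ": value '", e$value, "' not in domain of atom '", e$atom, "'")
    return(invisible(TRUE))
  }
  if (!e$op %in% c("not", "all", "any", "at_least", "exactly_one_false"))
    stop(where, ": unknown operator '", e$op, "'")
  if (length(e$children) == 0L)
    stop(where, ": operator '", e$op, "' requires children")
  if (e$op == "not" && length(e$children) != 1L)
    stop(where, ": NOT takes exactly one child")
  if (e$op == "at_least" &&
      (is.null(e$k) || e$k < 1L || e$k > length(e$children)))
    stop(where, ": at_least threshold k must satisfy 1 <= k <= #children")
  for (ch in e$children) validate_expr(ch, rs, where)
  invisible(TRUE)
}

#' Validate a (partial) answer set against a rule set
#'
#' @param answers Named character vector, atom id -> answered value.
#' @param rs A [ruleset()].
#' @return `answers`, invisibly, after validation.
#' @export
validate_answers <- function(answers, rs) {
  if (length(answers) == 0L) return(invisible(answers))
  stopifnot(is.character(answers), !is.null(names(answers)))
  bad <- setdiff(names(answers), names(rs$atoms))
  if (length(bad)) stop("answers reference unknown atoms: ",
                        paste(bad, collapse = ", "))
  for (id in names(answers)) {
    if (!answers[[id]] %in% rs$atoms[[id]]$domain)
      stop("answer '", answers[[id]], "' not in domain of atom '", id, "'")
  }
  invisible(answers)
}

#' Resolve the diagnostic impression under a (partial) answer set
#'
#' Evaluates every rule with three-valued logic and collects the labels of
#' rules that are already provably TRUE. Several labels can legitimately
#' co-occur (e.g. chronic migraine with medication overuse, or a primary
#' diagnosis alongside a secondary-headache red-flag alert). On a complete
#' answer set no rule status is UNKNOWN.
#'
#' @param rs A [ruleset()].
#' @param answers Named character vector of answers (may be partial).
#' @param validate Validate `answers` first (disable in hot loops).
#' @return A list of class `hdx_impression`: `status` (named logical, `NA`
#'   = UNKNOWN, one per rule) and `labels` (character vector of labels of
#'   TRUE rules, in report precedence order).
#' @export
resolve <- function(rs, answers, validate = TRUE) {
  if (validate) validate_answers(answers, rs)
  status <- vapply(rs$rules, function(r) evaluate(r$expression, answers), NA)
  names(status) <- names(rs$rules)
  tr <- rs$rules[!is.na(status) & status]
  ord <- order(vapply(tr, `[[`, 0L, "precedence"))
  structure(list(status = status,
                 labels = unname(vapply(tr[ord], `[[`, "", "label"))),
            class = "hdx_impression")
}

#' @export
print.hdx_impression <- function(x, ...) {
  cat("Diagnostic impression\n")
  cat("  labels:", if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)", "\n")
  nu <- sum(is.na(x$status))
  cat("  rules: ", sum(x$status %in% TRUE), "TRUE,",
      sum(x$status %in% FALSE), "FALSE,", nu, "UNKNOWN\n")
  invisible(x)
}

#' @export
print.hdx_ruleset <- function(x, ...) {
  cat("<hdx_ruleset> version", x$version, "—",
      length(x$atoms), "atoms,", length(x$rules), "rules\n")
  for (r in x$rules) cat("  ", r$id, "->", r$label, "\n")
  invisible(x)
}

# All complete extensions of `answers` over `free` atoms, as a list of named
# character vectors. Internal; callers must bound the product of domain sizes.
completions_grid <- function(rs, answers, free) {
  if (length(free) == 0L) return(list(answers))
  doms <- lapply(rs$atoms[free], `[[`, "domain")
  grid <- as.matrix(expand.grid(doms, stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- free
  lapply(seq_len(nrow(grid)), function(i) c(answers, grid[i, ]))
}
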