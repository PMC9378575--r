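#' Brute-force completion oracle
#'
#' Exhaustively enumerates every complete extension of a partial answer set
#' and records the distinct resolved label sets. Intended as an independent
#' ground truth for the adaptive engine's relevance logic on small
#' instances; it refuses (rather than silently truncates) instances above
#' its budget. Enumeration evaluates every rule on every completion — no
#' support-cone pruning, no partial evaluation — so it exercises none of
#' the engine's shortcuts.
#'
#' @param rs A [ruleset()].
#' @param answers Partial answers (named character vector).
#' @param budget Maximum number of unassigned atoms to enumerate (default 14).
#' @param max_completions Cap on the total number of completions.
#' @return `enumerate_label_sets()`: a list of distinct label sets (each a
#'   sorted character vector).
#' @export
enumerate_label_sets <- function(rs, answers = character(0), budget = 14L,
                                 max_completions = 200000L) {
  validate_answers(answers, rs)
  free <- setdiff(names(rs$atoms), names(answers))
  oracle_guard(rs, free, budget, max_completions)
  keys <- unique(label_keys_over_grid(rs, oracle_env(rs, answers, free)))
  lapply(strsplit(keys, "|", fixed = TRUE), function(x) x[nzchar(x)])
}

oracle_guard <- function(rs, free, budget, max_completions) {
  ncomp <- prod(vapply(rs$atoms[free], function(a) length(a$domain), 0))
  if (length(free) > budget)
    stop("completion oracle refused: ", length(free),
         " unassigned atoms exceed budget ", budget)
  if (ncomp > max_completions)
    stop("completion oracle refused: ", ncomp, " completions exceed cap ",
         max_completions)
  invisible(ncomp)
}

# Environment for vectorized evaluation: answered atoms as length-1
# constants, free atoms as the columns of the full completion grid.
oracle_env <- function(rs, answers, free) {
  env <- if (length(free)) {
    as.list(expand.grid(lapply(rs$atoms[free], `[[`, "domain"),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  } else list()
  c(env, as.list(answers))
}

# One label-set key per completion row, labels in sorted order within a key.
label_keys_over_grid <- function(rs, env) {
  n <- if (length(env)) max(lengths(env)) else 1L
  keys <- rep("", n)
  ord <- order(vapply(rs$rules, `[[`, "", "label"))
  for (r in rs$rules[ord]) {
    v <- compile_expr(r$expression)(env)
    if (length(v) == 1L) v <- rep(v, n)
    keys <- ifelse(v, paste(keys, r$label, sep = "|"), keys)
  }
  keys
}

#' @rdname enumerate_label_sets
#'
#' @details `oracle_is_relevant()` decides, by full enumeration over *all*
#' unassigned atoms (not just the support cone the engine inspects),
#' whether some complete extension exists on which two different answers to
#' `atom_id` yield different resolved label sets.
#'
#' @param atom_id Unanswered atom to test.
#' @return `oracle_is_relevant()`: logical.
#' @export
oracle_is_relevant <- function(rs, answers, atom_id, budget = 14L,
                               max_completions = 200000L) {
  if (atom_id %in% names(answers)) stop("atom already answered")
  free <- setdiff(names(rs$atoms), c(names(answers), atom_id))
  oracle_guard(rs, free, budget, max_completions)
  env <- oracle_env(rs, answers, free)
  ref <- NULL
  for (v in rs$atoms[[atom_id]]$domain) {
    env[[atom_id]] <- v
    keys <- label_keys_over_grid(rs, env)
    if (is.null(ref)) ref <- keys
    else if (any(keys != ref)) return(TRUE)
  }
  FALSE
}
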