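#' Save and load rule banks as JSON documents
#'
#' The rule-bank document carries a format version, the atom bank, the
#' question bank (with its ordering and answer display labels), the rules
#' as nested expression objects with an `"op"` discriminator, and the
#' outcome contrasts as label sets. `load_rulebank(save_rulebank(...))` is
#' the identity on documents; loading re-runs full validation, and
#' validation errors name the offending element.
#'
#' @param bank A [question_bank()] (which carries its rule set).
#' @param path File path for the JSON document.
#' @param contrasts List of [dx_contrast()] objects to embed (default: the
#'   three shipped contrasts).
#' @return `load_rulebank()`: a list with `ruleset`, `bank`, `contrasts`.
#' @export
save_rulebank <- function(bank, path,
                          contrasts = lapply(c("mpm_vs_nom", "m_vs_nom",
                                               "m_vs_nompm"), dx_contrast)) {
  rs <- bank$ruleset
  doc <- list(
    format_version = "1",
    version = rs$version,
    atoms = lapply(unname(rs$atoms), function(a)
      list(id = a$id, domain = as.list(a$domain), prompt_key = a$prompt_key)),
    questions = lapply(unname(bank$questions), function(q)
      list(id = q$id, atom_id = q$atom_id, order_index = q$order_index,
           text = q$text,
           answer_labels = if (is.null(q$answer_labels)) NULL
                           else as.list(q$answer_labels))),
    rules = lapply(unname(rs$rules), function(r)
      list(id = r$id, label = r$label, precedence = r$precedence,
           expression = expr_to_doc(r$expression))),
    contrasts = lapply(contrasts, function(ct)
      list(name = ct$name, positive_labels = as.list(ct$positive_labels),
           excluded_labels = as.list(ct$excluded_labels)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

expr_to_doc <- function(e) {
  if (e$op == "atom_equals")
    return(list(op = "atom_equals", atom = e$atom, value = e$value))
  out <- list(op = e$op)
  if (e$op == "at_least") out$k <- e$k
  out$children <- lapply(e$children, expr_to_doc)
  out
}

expr_from_doc <- function(d, where = "expression") {
  if (is.null(d$op)) stop(where, ": node without an \"op\" discriminator")
  if (d$op == "atom_equals") {
    if (is.null(d$atom) || is.null(d$value))
      stop(where, ": atom_equals needs \"atom\" and \"value\"")
    return(atom_eq(d$atom, d$value))
  }
  if (!d$op %in% c("not", "all", "any", "at_least", "exactly_one_false"))
    stop(where, ": unknown op \"", d$op, "\"")
  children <- lapply(seq_along(d$children), function(i)
    expr_from_doc(d$children[[i]], paste0(where, "/children/", i)))
  if (d$op == "at_least") {
    if (is.null(d$k)) stop(where, ": at_least needs \"k\"")
    return(do.call(at_least, c(list(k = d$k), children)))
  }
  new_expr(d$op, children = children)
}

#' @rdname save_rulebank
#' @export
load_rulebank <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format_version))
    stop(path, ": not a rule-bank document (no format_version)")
  atoms <- lapply(doc$atoms, function(a)
    atom(a$id, unlist(a$domain), a$prompt_key %||% a$id))
  rules <- lapply(seq_along(doc$rules), function(i) {
    r <- doc$rules[[i]]
    rule(r$id, r$label,
         expr_from_doc(r$expression, paste0("/rules/", i, "/expression")),
         r$precedence %||% 0L)
  })
  rs <- ruleset(atoms, rules, version = doc$version %||% "0")
  questions <- lapply(doc$questions, function(q)
    question(q$id, q$atom_id, q$text, q$order_index,
             if (is.null(q$answer_labels)) NULL else unlist(q$answer_labels)))
  bank <- question_bank(questions, rs)
  contrasts <- lapply(doc$contrasts, function(ct)
    dx_contrast(ct$name, positive_labels = unlist(ct$positive_labels),
                excluded_labels = as.character(unlist(ct$excluded_labels))))
  list(ruleset = rs, bank = bank, contrasts = contrasts)
}

#' Read and write answer sets as CSV
#'
#' Wide format: one row per respondent, an `id` column, then one column per
#' atom holding the answer's domain string verbatim (files stay
#' self-describing; no numeric coding). Readers accept arbitrary column
#' order; writers always emit a header.
#'
#' @param answers A named answer vector, or a list of them (named by id), or
#'   a data frame in the wide format.
#' @param path CSV path.
#' @param rs Rule set used to validate values on read.
#' @return `read_answers_csv()`: a named list of answer vectors.
#' @export
write_answers_csv <- function(answers, path) {
  if (is.character(answers)) answers <- list(R1 = answers)
  if (is.data.frame(answers)) {
    utils::write.csv(answers, path, row.names = FALSE)
    return(invisible(path))
  }
  atoms <- unique(unlist(lapply(answers, names)))
  rows <- lapply(names(answers), function(id) {
    v <- answers[[id]][atoms]
    as.data.frame(c(list(id = id), as.list(stats::setNames(v, atoms))),
                  stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_answers_csv
#' @export
read_answers_csv <- function(path, rs = default_ichd_ruleset()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"id" %in% names(df)) stop(path, ": answers CSV needs an 'id' column")
  atoms <- setdiff(names(df), "id")
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- unlist(df[i, atoms, drop = FALSE])
    v <- stats::setNames(as.character(v), atoms)
    v <- v[!is.na(v) & nzchar(v)]
    validate_answers(v, rs)
    v
  })
  names(out) <- df$id
  out
}

#' Write a simulated study to CSV
#'
#' Emits the paired-diagnosis table (`<stem>_diagnoses.csv`) and the
#' per-atom answer pairs (`<stem>_answers.csv`).
#'
#' @param study An `hdx_study` from [run_study()].
#' @param stem Path stem for the two files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_study_csv <- function(study, stem) {
  p1 <- paste0(stem, "_diagnoses.csv")
  p2 <- paste0(stem, "_answers.csv")
  utils::write.csv(study$diagnoses, p1, row.names = FALSE)
  utils::write.csv(study$answers, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a paired-diagnosis CSV
#'
#' @param path CSV with columns `reference_labels`, `index_labels` and
#'   optionally `id` (any column order).
#' @return Data frame suitable for [build_report()].
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("reference_labels", "index_labels")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop(path, ": missing columns: ",
                            paste(missing, collapse = ", "))
  df
}

#' Serialize an accuracy report to JSON
#'
#' Machine-readable counterpart of `print.dx_report()`; keys mirror the
#' summary table's row names (`accuracy`, `sensitivity`, ..., `lr_pos`,
#' `lr_neg`, `kappa`), each carrying point, bounds, confidence level and
#' method tag. Percentages are emitted on the 0-100 scale.
#'
#' @param report A `dx_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ci100 <- function(ci) if (is.null(ci)) NULL else
    list(estimate = 100 * ci$point, lower = 100 * ci$lower,
         upper = 100 * ci$upper, conf = ci$conf, method = ci$method)
  ci1 <- function(ci) if (is.null(ci)) NULL else
    list(estimate = ci$point, lower = ci$lower, upper = ci$upper,
         conf = ci$conf, method = ci$method)
  doc <- list(
    contrast = report$contrast,
    n = report$n,
    excluded = report$excluded,
    table = list(tp = report$table$tp, fp = report$table$fp,
                 fn = report$table$fn, tn = report$table$tn),
    accuracy = ci100(report$rates$accuracy),
    sensitivity = ci100(report$rates$sensitivity),
    specificity = ci100(report$rates$specificity),
    ppv = ci100(report$rates$ppv),
    npv = ci100(report$rates$npv),
    prevalence = ci100(report$rates$prevalence),
    predictive_at = lapply(report$predictive_at, function(pv)
      list(ppv = ci100(pv$ppv), npv = ci100(pv$npv))),
    lr_pos = ci1(report$likelihood_ratios$lr_pos),
    lr_neg = ci1(report$likelihood_ratios$lr_neg),
    kappa = if (is.na(report$kappa$kappa)) NULL else
      list(estimate = report$kappa$kappa, lower = report$kappa$ci$lower,
           upper = report$kappa$ci$upper, conf = report$kappa$ci$conf,
           p_o = report$kappa$p_o, p_e = report$kappa$p_e,
           interpretation = report$kappa$interpretation),
    fagan = lapply(report$fagan, function(f)
      list(pretest = f$pretest, lr = f$lr, posttest = f$posttest)),
    discordant_count = report$discordant_count,
    symptom_agreement = if (is.null(report$symptom_agreement)) NULL else
      as.list(report$symptom_agreement)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation study configuration (JSON)
#'
#' Fields: `n`, `class_weights`, `noise`, `seed`, `contrast`,
#' `extra_prevalences`, `conf`; all optional except `n`, with defaults
#' reproducing the study-like scenario (n = 202, ~67% migraine/probable
#' migraine mass, the default discordance gradient).
#'
#' @param path JSON path.
#' @return A list of validated configuration values.
#' @export
read_study_config <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$n)) stop(path, ": study config needs \"n\"")
  cfg <- list(
    n = as.integer(doc$n),
    class_weights = if (is.null(doc$class_weights)) default_class_mix()
                    else unlist(doc$class_weights),
    noise = if (is.null(doc$noise)) default_noise_model()
            else unlist(doc$noise),
    seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed),
    contrast = doc$contrast %||% "mpm_vs_nom",
    extra_prevalences = if (is.null(doc$extra_prevalences)) 0.10
                        else unlist(doc$extra_prevalences),
    conf = doc$conf %||% 0.95)
  if (abs(sum(cfg$class_weights) - 1) > 1e-6)
    stop(path, ": class_weights must sum to 1")
  if (any(cfg$noise < 0 | cfg$noise > 1))
    stop(path, ": noise probabilities must lie in [0,1]")
  cfg
}

#' Expand a printed 2x2 table into a paired-diagnosis data frame
#'
#' Convenience for re-analyzing a published contingency table with the
#' full report pipeline: builds `tp + fp + fn + tn` synthetic paired
#' records whose label sets realize the table's four cells under the given
#' contrast (positive records get the first positive label, negative
#' records `tension_type`).
#'
#' @param tp,fp,fn,tn Cell counts.
#' @param contrast A [dx_contrast()].
#' @return Paired-diagnosis data frame with `id`, `reference_labels`,
#'   `index_labels`.
#' @export
pairs_from_table <- function(tp, fp, fn, tn,
                             contrast = dx_contrast("mpm_vs_nom")) {
  pos <- contrast$positive_labels[1]
  neg <- "tension_type"
  if (neg %in% contrast$positive_labels) neg <- "no_headache"
  ref <- c(rep(pos, tp), rep(neg, fp), rep(pos, fn), rep(neg, tn))
  idx <- c(rep(pos, tp), rep(pos, fp), rep(neg, fn), rep(neg, tn))
  data.frame(id = sprintf("P%03d", seq_along(ref)),
             reference_labels = ref, index_labels = idx,
             stringsAsFactors = FALSE)
}
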