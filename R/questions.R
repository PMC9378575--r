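#' Construct a question and a question bank
#'
#' Each question binds exactly one atom; the bank's order is the session's
#' fixed initial ordering. Question text targets roughly a 6th-grade reading
#' level. The ordering is part of the bank (and of its JSON serialization):
#' different orderings may ask different numbers of questions but never
#' change the final labels.
#'
#' @param id Question identifier.
#' @param atom_id Atom the question binds.
#' @param text Display text shown to the respondent.
#' @param order_index Position in the initial ordering (unique).
#' @param answer_labels Optional named character vector mapping domain values
#'   to display strings.
#' @return `question()`: a list of class `hdx_question`.
#' @export
question <- function(id, atom_id, text, order_index, answer_labels = NULL) {
  structure(list(id = id, atom_id = atom_id, text = text,
                 order_index = as.integer(order_index),
                 answer_labels = answer_labels),
            class = "hdx_question")
}

#' @rdname question
#' @param questions List of [question()] objects.
#' @param rs The [ruleset()] the bank is bound to; every atom referenced by a
#'   rule must be covered by exactly one question.
#' @return `question_bank()`: a list of class `hdx_bank` with questions
#'   sorted by `order_index`.
#' @export
question_bank <- function(questions, rs) {
  qa <- vapply(questions, `[[`, "", "atom_id")
  if (anyDuplicated(qa)) stop("more than one question binds atom: ",
                              paste(unique(qa[duplicated(qa)]), collapse = ", "))
  oi <- vapply(questions, `[[`, 0L, "order_index")
  if (anyDuplicated(oi)) stop("order indices must be unique")
  need <- unique(unlist(lapply(rs$rules, `[[`, "atoms")))
  missing <- setdiff(need, qa)
  if (length(missing)) stop("bank does not cover atoms: ",
                            paste(missing, collapse = ", "))
  unknown <- setdiff(qa, names(rs$atoms))
  if (length(unknown)) stop("questions bind unknown atoms: ",
                            paste(unknown, collapse = ", "))
  questions <- questions[order(oi)]
  names(questions) <- vapply(questions, `[[`, "", "id")
  structure(list(questions = questions, ruleset = rs), class = "hdx_bank")
}

#' @export
print.hdx_bank <- function(x, ...) {
  cat("<hdx_bank>", length(x$questions), "questions over ruleset",
      x$ruleset$version, "\n")
  invisible(x)
}

#' The default interview question bank
#'
#' Covers all 26 atoms of [default_ichd_ruleset()] in a conversational
#' ordering: screening, red flags, attack frequency and duration, pain
#' characteristics, associated symptoms, the aura block, then chronicity and
#' medication use.
#'
#' @param rs Rule set to bind (defaults to the shipped ICHD-3 bank).
#' @return An [question_bank()].
#' @export
default_question_bank <- function(rs = default_ichd_ruleset()) {
  yn <- c(yes = "Yes", no = "No")
  spec <- list(
    list("has_headache", "Do you get headaches?", yn),
    list("rf_thunderclap", "Have you ever had a headache that reached its worst within one minute?", yn),
    list("rf_systemic", "With your headaches, have you had fever, weight loss, or a stiff neck?", yn),
    list("rf_neuro_deficit", "With your headaches, have you had weakness, numbness, or trouble speaking that did not go away?", yn),
    list("rf_onset_after_50", "Did your headaches first start after age 50?", yn),
    list("rf_pattern_change", "Have your headaches changed a lot recently, or become much more frequent?", yn),
    list("attack_count", "How many headache attacks like this have you had in your life?",
         c("0-1" = "One or none", "2-4" = "Two to four", ">=5" = "Five or more")),
    list("duration", "If you take no medicine, how long does a headache attack usually last?",
         c("<30min" = "Under 30 minutes", "30min-4h" = "30 minutes to 4 hours",
           "4-72h" = "4 hours to 3 days", "72h-7d" = "3 days to a week",
           ">7d" = "More than a week")),
    list("unilateral", "Is the pain usually on one side of your head?", yn),
    list("pulsating", "Does the pain pound, throb, or pulse?", yn),
    list("intensity", "How bad is the pain, usually?",
         c(mild = "Mild", moderate = "Moderate", severe = "Severe")),
    list("aggravation_activity", "Does normal activity like walking or climbing stairs make the pain worse, or do you avoid it?", yn),
    list("nausea_vomiting", "Do you feel sick to your stomach or throw up with the headache?", yn),
    list("photophobia", "Does light bother you during the headache?", yn),
    list("phonophobia", "Does noise bother you during the headache?", yn),
    list("aura_present", "Before or during some headaches, do you see spots, flashing lights or zigzag lines, or get numbness or trouble speaking?", yn),
    list("aura_reversible", "Do these symptoms go away completely afterwards?", yn),
    list("aura_gradual_spread", "Do these symptoms spread or grow slowly over 5 minutes or more?", yn),
    list("aura_succession", "Do two or more of these symptoms come one after another?", yn),
    list("aura_duration_5_60", "Does each of these symptoms last between 5 minutes and an hour?", yn),
    list("aura_unilateral_symptom", "Is at least one of these symptoms only on one side?", yn),
    list("aura_positive_phenomenon", "Do you see or feel something extra, like flickering lights or tingling (not just loss)?", yn),
    list("aura_headache_within_60", "Does a headache start during these symptoms or within an hour after them?", yn),
    list("headache_days", "On how many days each month do you have a headache?",
         c("<15" = "Fewer than 15 days", ">=15" = "15 days or more")),
    list("months_ge3", "Has this pattern lasted for more than 3 months?", yn),
    list("acute_med_days", "On how many days each month do you take a pain or migraine medicine for headache?",
         c("<10" = "Fewer than 10 days", ">=10" = "10 days or more"))
  )
  qs <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    question(paste0("Q", sprintf("%02d", i)), s[[1]], s[[2]], i, s[[3]])
  })
  question_bank(qs, rs)
}
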