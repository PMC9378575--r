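#' Default latent headache-class mixture
#'
#' Mixture weights for the synthetic cohort's latent classes. The defaults
#' emulate a tertiary headache-clinic population in which migraine or
#' probable migraine account for about 67% of respondents; the remainder
#' split between tension-type headache, other/unclassified headache, and
#' headache-free respondents.
#'
#' @return Named numeric vector of mixture weights summing to 1.
#' @export
default_class_mix <- function() {
  c(migraine_without_aura = 0.32,
    migraine_with_aura    = 0.08,
    probable_migraine     = 0.27,
    tension_type          = 0.20,
    other_headache        = 0.07,
    no_headache           = 0.06)
}

#' Default per-symptom discordance model
#'
#' Probability, per atom, that the self-administered (index) channel
#' reports a value different from the respondent's true assignment; for
#' categorical atoms the discordant value is drawn uniformly from the
#' remaining domain. Atoms absent from the map never flip.
#'
#' The defaults are a *qualitative* calibration to the observed
#' symptom-agreement gradient between interview and self-report: discordance
#' is largest for phonophobia, aggravation by activity and photophobia,
#' moderate for pulsating quality and duration, small for intensity and
#' nausea/vomiting, and zero for aura and unilateral pain. They are not
#' estimates of any real cohort's per-symptom discordance probabilities,
#' which the diagnosis-level data alone cannot identify.
#'
#' @return Named numeric vector of flip probabilities in `[0, 1]`.
#' @export
default_noise_model <- function() {
  c(phonophobia          = 0.30,
    aggravation_activity = 0.25,
    photophobia          = 0.22,
    pulsating            = 0.15,
    duration             = 0.10,
    intensity            = 0.07,
    nausea_vomiting      = 0.04)
}

# Expected resolved label set per latent class (the red-flag screen is off
# and chronic/medication-overuse features are suppressed in every sampler).
class_expected_labels <- function(class) {
  switch(class,
    no_headache = "no_headache",
    secondary_headache_suspected = c("other_headache",
                                     "secondary_headache_suspected"),
    class)
}

r_pick <- function(x, n = 1L) x[sample.int(length(x), n)]

# Start from a fully random assignment, then constrain per class.
random_full_assignment <- function(rs) {
  vapply(rs$atoms, function(a) r_pick(a$domain), "")
}

# Common envelope for every headache-positive class: no red flags, episodic
# (<15 headache days), no medication overuse.
base_headache_assignment <- function(rs) {
  x <- random_full_assignment(rs)
  x["has_headache"] <- "yes"
  x[c("rf_thunderclap", "rf_systemic", "rf_neuro_deficit",
      "rf_onset_after_50", "rf_pattern_change")] <- "no"
  x["headache_days"] <- "<15"
  x["acute_med_days"] <- "<10"
  x
}

# Satisfy 1.1 C (>=2 of 4 pain characteristics) with a random subset of
# size k; unselected characteristics get their negation.
fill_pain_block <- function(x, k) {
  feats <- c("unilateral", "pulsating", "intensity", "aggravation_activity")
  on <- r_pick(feats, k)
  x["unilateral"] <- if ("unilateral" %in% on) "yes" else "no"
  x["pulsating"] <- if ("pulsating" %in% on) "yes" else "no"
  x["intensity"] <- if ("intensity" %in% on) r_pick(c("moderate", "severe")) else "mild"
  x["aggravation_activity"] <- if ("aggravation_activity" %in% on) "yes" else "no"
  x
}

# Satisfy 1.1 D: nausea/vomiting, or photophobia-and-phonophobia, or both.
fill_assoc_block <- function(x) {
  route <- r_pick(c("nausea", "photophono", "both"))
  x["nausea_vomiting"] <- if (route %in% c("nausea", "both")) "yes" else "no"
  if (route %in% c("photophono", "both")) {
    x["photophobia"] <- "yes"
    x["phonophobia"] <- "yes"
  } else {
    # keep D satisfied via nausea; photo/phono free
    x["photophobia"] <- r_pick(c("yes", "no"))
    x["phonophobia"] <- r_pick(c("yes", "no"))
  }
  x
}

aura_atoms <- c("aura_gradual_spread", "aura_succession", "aura_duration_5_60",
                "aura_unilateral_symptom", "aura_positive_phenomenon",
                "aura_headache_within_60")

class_samplers <- list(
  no_headache = function(rs) {
    x <- random_full_assignment(rs)
    x["has_headache"] <- "no"
    x
  },
  migraine_without_aura = function(rs) {
    x <- base_headache_assignment(rs)
    x["attack_count"] <- ">=5"
    x["duration"] <- "4-72h"
    x["aura_present"] <- "no"
    x <- fill_pain_block(x, r_pick(2:4))
    fill_assoc_block(x)
  },
  migraine_with_aura = function(rs) {
    x <- base_headache_assignment(rs)
    x["attack_count"] <- r_pick(c("2-4", ">=5"))
    x["aura_present"] <- "yes"
    x["aura_reversible"] <- "yes"
    on <- r_pick(aura_atoms, r_pick(3:6))
    x[aura_atoms] <- "no"
    x[on] <- "yes"
    # keep 1.1 D false (no MwoA co-label) and tension-type excluded
    x["nausea_vomiting"] <- "no"
    x["phonophobia"] <- "no"
    x[c("unilateral", "pulsating", "aggravation_activity")] <- "yes"
    x
  },
  probable_migraine = function(rs) {
    x <- base_headache_assignment(rs)
    x["aura_present"] <- "no"
    fail <- r_pick(c("A", "B", "C", "D"))
    x["attack_count"] <- if (fail == "A") r_pick(c("0-1", "2-4")) else ">=5"
    x["duration"] <- if (fail == "B") r_pick(c("<30min", "30min-4h", "72h-7d", ">7d")) else "4-72h"
    if (fail == "C") {
      x <- fill_pain_block(x, r_pick(0:1))
    } else if (fail == "D") {
      # failing D makes tension-type's associated-symptom block TRUE, so pin
      # >=3 pain characteristics to keep the tension-type pain block FALSE
      x <- fill_pain_block(x, 3L)
      x[c("unilateral", "pulsating", "aggravation_activity")] <- "yes"
    } else {
      x <- fill_pain_block(x, r_pick(2:4))
    }
    if (fail == "D") {
      x["nausea_vomiting"] <- "no"
      x["phonophobia"] <- "no"
      x["photophobia"] <- r_pick(c("yes", "no"))
    } else {
      x <- fill_assoc_block(x)
    }
    x
  },
  tension_type = function(rs) {
    x <- base_headache_assignment(rs)
    x["attack_count"] <- r_pick(c("0-1", "2-4"))
    x["duration"] <- r_pick(c("30min-4h", "4-72h", "72h-7d"))
    x["aura_present"] <- "no"
    feats <- r_pick(c("unilateral", "pulsating", "intensity",
                      "aggravation_activity"), r_pick(2:4))
    x["unilateral"] <- if ("unilateral" %in% feats) "no" else "yes"
    x["pulsating"] <- if ("pulsating" %in% feats) "no" else "yes"
    x["intensity"] <- if ("intensity" %in% feats) r_pick(c("mild", "moderate")) else "severe"
    x["aggravation_activity"] <- if ("aggravation_activity" %in% feats) "no" else "yes"
    x["nausea_vomiting"] <- "no"
    pp <- r_pick(c("none", "photo", "phono"))
    x["photophobia"] <- if (pp == "photo") "yes" else "no"
    x["phonophobia"] <- if (pp == "phono") "yes" else "no"
    x
  },
  other_headache = function(rs) {
    x <- base_headache_assignment(rs)
    x["attack_count"] <- "0-1"
    x["duration"] <- ">7d"
    x["aura_present"] <- "no"
    x
  },
  secondary_headache_suspected = function(rs) {
    x <- class_samplers$other_headache(rs)
    flags <- c("rf_thunderclap", "rf_systemic", "rf_neuro_deficit",
               "rf_onset_after_50", "rf_pattern_change")
    x[r_pick(flags)] <- "yes"
    x
  }
)

#' Sample a synthetic respondent profile
#'
#' Draws a latent headache class from the mixture, then constructs a full
#' true symptom assignment whose resolved labels are exactly the class's
#' expected labels. Construction is by documented per-class constructive
#' shortcuts (randomized within each class's satisfying envelope) followed
#' by an explicit invariant check; a bounded number of resamples guards
#' against an unsatisfiable class.
#'
#' @param classes Named mixture weights (see [default_class_mix()]); must
#'   sum to 1 and name only supported classes.
#' @param rs The [ruleset()] (defaults to the shipped ICHD-3 bank).
#' @param max_tries Resampling bound before erroring.
#' @return A list of class `hdx_profile`: `class`, `assignment` (full named
#'   answer vector), `labels`.
#' @export
sample_profile <- function(classes = default_class_mix(),
                           rs = default_ichd_ruleset(), max_tries = 100L) {
  stopifnot(abs(sum(classes) - 1) < 1e-8)
  unknown <- setdiff(names(classes), names(class_samplers))
  if (length(unknown)) stop("no sampler for class: ",
                            paste(unknown, collapse = ", "))
  cls <- names(classes)[sample.int(length(classes), 1L, prob = classes)]
  expected <- sort(class_expected_labels(cls))
  for (i in seq_len(max_tries)) {
    x <- class_samplers[[cls]](rs)
    labs <- sort(resolve(rs, x, validate = FALSE)$labels)
    if (identical(labs, expected))
      return(structure(list(class = cls, assignment = x, labels = labs),
                       class = "hdx_profile"))
  }
  stop("could not construct a profile for class '", cls, "' in ",
       max_tries, " tries (got labels: ", paste(labs, collapse = ", "), ")")
}

#' Perturb a true assignment through the discordance channel
#'
#' Independently, per atom, replaces the true value with probability given
#' by the noise model; the replacement is uniform over the remaining domain
#' values. Models the inconsistency between interview responses and
#' self-administered questionnaire responses to the same questions.
#'
#' @param profile An `hdx_profile` (or a full named answer vector).
#' @param noise Named flip probabilities (see [default_noise_model()]).
#' @param rs The rule set supplying atom domains.
#' @return A full named answer vector (the index channel's answers).
#' @export
perturb <- function(profile, noise = default_noise_model(),
                    rs = default_ichd_ruleset()) {
  x <- if (inherits(profile, "hdx_profile")) profile$assignment else profile
  if (any(noise < 0 | noise > 1)) stop("noise probabilities must be in [0,1]")
  bad <- setdiff(names(noise), names(rs$atoms))
  if (length(bad)) stop("noise names unknown atoms: ", paste(bad, collapse = ", "))
  for (id in names(noise)) {
    p <- noise[[id]]
    if (p > 0 && stats::runif(1) < p) {
      others <- setdiff(rs$atoms[[id]]$domain, x[[id]])
      x[id] <- r_pick(others)
    }
  }
  x
}

#' Simulate a two-channel diagnostic-accuracy study
#'
#' For each synthetic respondent: the *reference* channel diagnoses the true
#' assignment directly, and the *index* channel diagnoses the
#' noise-perturbed assignment — by default replaying it through the
#' adaptive interview engine ([run_session()]); `method = "direct"`
#' resolves the perturbed assignment against the full rule set instead,
#' which yields identical labels (the engine's correctness contract) at a
#' fraction of the cost for large Monte-Carlo runs.
#'
#' @param n Number of respondents.
#' @param classes Latent class mixture weights.
#' @param noise Per-atom discordance probabilities.
#' @param rs Rule set.
#' @param bank Question bank (required for `method = "adaptive"`).
#' @param seed Optional integer seed controlling all randomness.
#' @param method `"adaptive"` (replay through the engine) or `"direct"`.
#' @return A list of class `hdx_study`: `diagnoses` (data frame with
#'   `id`, `class`, `reference_labels`, `index_labels`, labels joined by
#'   `";"`), `answers` (long data frame with `id`, `atom`, `reference`,
#'   `index`), and `config`.
#' @export
run_study <- function(n, classes = default_class_mix(),
                      noise = default_noise_model(),
                      rs = default_ichd_ruleset(),
                      bank = default_question_bank(rs),
                      seed = NULL,
                      method = c("adaptive", "direct")) {
  stopifnot(n >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  cls <- character(n); refl <- character(n); idxl <- character(n)
  atoms <- names(rs$atoms)
  ref_mat <- matrix("", n, length(atoms))
  idx_mat <- matrix("", n, length(atoms))
  for (i in seq_len(n)) {
    pr <- sample_profile(classes, rs)
    pert <- perturb(pr, noise, rs)
    idx_labels <- if (method == "adaptive") run_session(bank, pert)$labels
                  else resolve(rs, pert, validate = FALSE)$labels
    cls[i] <- pr$class
    refl[i] <- paste(sort(pr$labels), collapse = ";")
    idxl[i] <- paste(sort(idx_labels), collapse = ";")
    ref_mat[i, ] <- pr$assignment[atoms]
    idx_mat[i, ] <- pert[atoms]
  }
  structure(list(
    diagnoses = data.frame(id = ids, class = cls, reference_labels = refl,
                           index_labels = idxl, stringsAsFactors = FALSE),
    answers = data.frame(id = rep(ids, each = length(atoms)),
                         atom = rep(atoms, times = n),
                         reference = as.vector(t(ref_mat)),
                         index = as.vector(t(idx_mat)),
                         stringsAsFactors = FALSE),
    config = list(n = n, classes = classes, noise = noise,
                  seed = seed, method = method,
                  ruleset_version = rs$version)),
    class = "hdx_study")
}

#' @export
print.hdx_study <- function(x, ...) {
  cat("<hdx_study>", nrow(x$diagnoses), "paired respondents (method:",
      x$config$method, ")\n")
  print(table(x$diagnoses$class))
  invisible(x)
}
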