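#' The default ICHD-3 rule bank
#'
#' A reduced encoding of the ICHD-3 criteria for the common primary headache
#' disorders, over 26 categorical symptom atoms. The bank is data, not code:
#' it serializes to the rule-bank JSON format ([save_rulebank()]) and users
#' may load alternative banks.
#'
#' Rules shipped (labels in parentheses):
#' * `R-NoHeadache` (`no_headache`) — the screening atom answered "no".
#' * `R-RedFlag` (`secondary_headache_suspected`) — any of five red-flag
#'   screens positive; a referral alert that can co-occur with a primary
#'   diagnosis rather than a differential that suppresses one.
#' * `R-MwoA` (`migraine_without_aura`) — ICHD-3 1.1: >=5 attacks (A),
#'   duration 4–72 h (B), >=2 of 4 pain characteristics (C), >=1 of
#'   nausea/vomiting or photophobia-and-phonophobia (D).
#' * `R-MwA` (`migraine_with_aura`) — ICHD-3 1.2: >=2 attacks, fully
#'   reversible aura, >=3 of 6 aura characteristics.
#' * `R-Probable` (`probable_migraine`) — ICHD-3 1.5: all but exactly one of
#'   the criterion blocks of 1.1 or of 1.2, not fulfilling tension-type
#'   criteria nor full 1.1/1.2.
#' * `R-TTH` (`tension_type`) — ICHD-3 2.x: duration 30 min – 7 d, >=2 of 4
#'   tension-type pain characteristics, no nausea/vomiting, not both
#'   photophobia and phonophobia.
#' * `R-Chronic` (`chronic_migraine`) — ICHD-3 1.3: headache on >=15
#'   days/month for >3 months with migrainous features (1.1 C and D).
#' * `R-MOH` (`medication_overuse`) — ICHD-3 8.2: headache >=15 days/month
#'   with acute-medication intake >=10 days/month for >3 months.
#' * `R-Other` (`other_headache`) — headache present but no primary rule
#'   fulfilled.
#'
#' "Not better accounted for by another ICHD-3 diagnosis" (criterion E) is
#' approximated by the red-flag screen plus the explicit exclusions inside
#' `R-Probable`; full cross-rule differential subsumption is out of scope,
#' as are cluster headache and the other TACs.
#'
#' @return A validated [ruleset()].
#' @export
default_ichd_ruleset <- function() {
  yn <- c("yes", "no")
  atoms <- list(
    atom("has_headache", yn),
    # red-flag screens for secondary headache
    atom("rf_thunderclap", yn),
    atom("rf_systemic", yn),
    atom("rf_neuro_deficit", yn),
    atom("rf_onset_after_50", yn),
    atom("rf_pattern_change", yn),
    # attack profile
    atom("attack_count", c("0-1", "2-4", ">=5")),
    atom("duration", c("<30min", "30min-4h", "4-72h", "72h-7d", ">7d")),
    # pain characteristics
    atom("unilateral", yn),
    atom("pulsating", yn),
    atom("intensity", c("mild", "moderate", "severe")),
    atom("aggravation_activity", yn),
    # associated symptoms
    atom("nausea_vomiting", yn),
    atom("photophobia", yn),
    atom("phonophobia", yn),
    # aura block
    atom("aura_present", yn),
    atom("aura_reversible", yn),
    atom("aura_gradual_spread", yn),
    atom("aura_succession", yn),
    atom("aura_duration_5_60", yn),
    atom("aura_unilateral_symptom", yn),
    atom("aura_positive_phenomenon", yn),
    atom("aura_headache_within_60", yn),
    # chronicity and medication
    atom("headache_days", c("<15", ">=15")),
    atom("months_ge3", yn),
    atom("acute_med_days", c("<10", ">=10"))
  )

  hh <- atom_eq("has_headache", "yes")

  red_any <- e_any(atom_eq("rf_thunderclap", "yes"),
                   atom_eq("rf_systemic", "yes"),
                   atom_eq("rf_neuro_deficit", "yes"),
                   atom_eq("rf_onset_after_50", "yes"),
                   atom_eq("rf_pattern_change", "yes"))

  # --- migraine without aura (1.1) criterion blocks -------------------------
  mwoa_a <- atom_eq("attack_count", ">=5")
  mwoa_b <- atom_eq("duration", "4-72h")
  mod_sev <- e_any(atom_eq("intensity", "moderate"), atom_eq("intensity", "severe"))
  mwoa_c <- at_least(2,
    atom_eq("unilateral", "yes"),
    atom_eq("pulsating", "yes"),
    mod_sev,
    atom_eq("aggravation_activity", "yes"))
  photophono <- e_all(atom_eq("photophobia", "yes"), atom_eq("phonophobia", "yes"))
  mwoa_d <- e_any(atom_eq("nausea_vomiting", "yes"), photophono)
  mwoa_core <- e_all(mwoa_a, mwoa_b, mwoa_c, mwoa_d)

  # --- migraine with aura (1.2) criterion blocks ----------------------------
  mwa_a <- e_any(atom_eq("attack_count", "2-4"), atom_eq("attack_count", ">=5"))
  mwa_b <- e_all(atom_eq("aura_present", "yes"), atom_eq("aura_reversible", "yes"))
  # gated by aura_present so aura-detail questions are irrelevant without aura
  mwa_c <- e_all(atom_eq("aura_present", "yes"),
                 at_least(3,
                   atom_eq("aura_gradual_spread", "yes"),
                   atom_eq("aura_succession", "yes"),
                   atom_eq("aura_duration_5_60", "yes"),
                   atom_eq("aura_unilateral_symptom", "yes"),
                   atom_eq("aura_positive_phenomenon", "yes"),
                   atom_eq("aura_headache_within_60", "yes")))
  mwa_core <- e_all(mwa_a, mwa_b, mwa_c)

  # --- tension-type (2.x) ---------------------------------------------------
  tth_dur <- e_any(atom_eq("duration", "30min-4h"),
                   atom_eq("duration", "4-72h"),
                   atom_eq("duration", "72h-7d"))
  tth_c <- at_least(2,
    atom_eq("unilateral", "no"),
    atom_eq("pulsating", "no"),
    e_any(atom_eq("intensity", "mild"), atom_eq("intensity", "moderate")),
    atom_eq("aggravation_activity", "no"))
  tth_d <- e_all(atom_eq("nausea_vomiting", "no"), e_not(photophono))
  tth_core <- e_all(tth_dur, tth_c, tth_d)

  # --- probable migraine (1.5): all but one block of 1.1 or 1.2, and not
  # --- fulfilling tension-type or the full migraine criteria ----------------
  probable_core <- e_all(
    e_any(exactly_one_false(mwoa_a, mwoa_b, mwoa_c, mwoa_d),
          exactly_one_false(mwa_a, mwa_b, mwa_c)),
    e_not(mwoa_core), e_not(mwa_core), e_not(tth_core))

  # --- chronic migraine (1.3) and medication overuse (8.2) ------------------
  chronic_core <- e_all(atom_eq("headache_days", ">=15"),
                        atom_eq("months_ge3", "yes"),
                        mwoa_c, mwoa_d)
  moh_core <- e_all(atom_eq("headache_days", ">=15"),
                    atom_eq("acute_med_days", ">=10"),
                    atom_eq("months_ge3", "yes"))

  other_core <- e_all(e_not(mwoa_core), e_not(mwa_core), e_not(probable_core),
                      e_not(tth_core), e_not(chronic_core))

  rules <- list(
    rule("R-NoHeadache", "no_headache", atom_eq("has_headache", "no"), 90L),
    rule("R-RedFlag", "secondary_headache_suspected", e_all(hh, red_any), 5L),
    rule("R-MwA", "migraine_with_aura", e_all(hh, mwa_core), 10L),
    rule("R-MwoA", "migraine_without_aura", e_all(hh, mwoa_core), 20L),
    rule("R-Chronic", "chronic_migraine", e_all(hh, chronic_core), 25L),
    rule("R-Probable", "probable_migraine", e_all(hh, probable_core), 30L),
    rule("R-TTH", "tension_type", e_all(hh, tth_core), 40L),
    rule("R-MOH", "medication_overuse", e_all(hh, moh_core), 50L),
    rule("R-Other", "other_headache", e_all(hh, other_core), 80L)
  )

  ruleset(atoms, rules, version = "ichd3-default-1")
}

#' Migraine-related diagnosis labels
#'
#' Label groups used by the shipped outcome contrasts: `migraine` covers
#' definitive migraine diagnoses (with/without aura, chronic), `mpm` adds
#' probable migraine.
#'
#' @return Character vector of labels.
#' @export
migraine_labels <- function() c("migraine_with_aura", "migraine_without_aura",
                                "chronic_migraine")

#' @rdname migraine_labels
#' @export
mpm_labels <- function() c(migraine_labels(), "probable_migraine")

#' The nine migraine-related symptom atoms tracked for agreement analysis
#'
#' Unilateral pain, moderate/severe intensity, aura, nausea/vomiting,
#' 4–72 h duration, pulsating quality, photophobia, phonophobia, and
#' aggravation by routine physical activity.
#'
#' @return Character vector of nine atom ids from the default bank.
#' @export
tracked_symptoms <- function() c("unilateral", "intensity", "aura_present",
                                 "nausea_vomiting", "duration", "pulsating",
                                 "photophobia", "phonophobia",
                                 "aggravation_activity")
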