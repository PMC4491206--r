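# Synthetic pediatric claims generator with planted ground truth.
#
# Emulates a pediatric Medicaid-like population: children aged 2-17 filling
# opioid prescriptions, ED/inpatient encounters carrying screening codes
# planted inside known risk windows at known early/late positions, decoy
# encounters that must never screen in, paired-reviewer abstractions, and a
# truth table recording what was planted so every pipeline stage can be
# checked end-to-end.

#' Simulation parameters
#'
#' Defaults emulate the development-study population: mean age 11.3 y
#' (SD 5.0, truncated to the eligible range), 57% female, 59% Caucasian,
#' per-category confirmation probabilities equal to the validated PPVs
#' (intentional 15/30, unintentional 25/31, therapeutic adverse effect
#' 33/58, CNS symptoms 9/32, respiratory symptoms 3/15, death 0/2), an
#' early:late planting split of 121:47, record availability 168:4:23
#' (adjudicable : insufficient information : not found) and reviewer
#' agreement 0.917. Planted-case rates are per qualifying fill and default
#' to sparse, claims-like values; raise them for calibration studies that
#' need large realized case counts.
#'
#' @param n_children Number of children to simulate.
#' @param rng_seed Integer seed; mandatory — one seed drives every draw.
#' @param age_mean_years,age_sd_years Age distribution at first fill,
#'   truncated to the eligible range.
#' @param p_female,p_caucasian Demographic proportions.
#' @param fills_per_child_lambda Fills per child are `1 + Poisson(lambda)`.
#' @param days_supply_choices,days_supply_probs Days-supply distribution.
#' @param case_rates Named per-fill probabilities of planting a case of each
#'   category (`intentional_overdose`, `unintentional_overdose`,
#'   `adverse_effect_therapeutic`, `symptom_cns`, `symptom_respiratory`,
#'   `death_any_cause`); at most one case is planted per fill.
#' @param confirmation_probs Named per-category probabilities that a planted
#'   case is confirmed (adjudicated Group 1/2) on review.
#' @param p_early Probability a planted case sits in the early stratum
#'   (event on or before 7 days after end of supply).
#' @param p_group1_given_confirmed Split of confirmed cases between
#'   Group 1 and Group 2 abstraction patterns.
#' @param availability_probs Named probabilities over record status
#'   (`adjudicable`, `no_information`, `not_found`).
#' @param severity_probs Severity mix (high/intermediate/low) for confirmed
#'   non-fatal cases.
#' @param rater_agreement Probability the second reviewer reproduces the
#'   first reviewer's group.
#' @param p_excluded_child Fraction of children given a lookback
#'   exclusion-code encounter (they must fall out of the cohort).
#' @param p_decoy_outside,p_decoy_benign,p_decoy_outpatient Per-fill decoy
#'   rates: a triggering encounter outside every risk window, a benign
#'   in-window encounter, and an outpatient encounter with a triggering
#'   code — none may ever become a potential case.
#' @param study_start,study_end Study window for fill dates.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_children = 500L,
                       rng_seed,
                       age_mean_years = 11.3, age_sd_years = 5.0,
                       p_female = 0.57, p_caucasian = 0.59,
                       fills_per_child_lambda = 0.8,
                       days_supply_choices = c(3L, 5L, 7L, 10L, 14L, 30L),
                       days_supply_probs = c(.20, .25, .25, .15, .10, .05),
                       case_rates = c(intentional_overdose = 0.002,
                                      unintentional_overdose = 0.002,
                                      adverse_effect_therapeutic = 0.004,
                                      symptom_cns = 0.0022,
                                      symptom_respiratory = 0.001,
                                      death_any_cause = 0.00015),
                       confirmation_probs = c(
                         intentional_overdose = 15 / 30,
                         unintentional_overdose = 25 / 31,
                         adverse_effect_therapeutic = 33 / 58,
                         symptom_cns = 9 / 32,
                         symptom_respiratory = 3 / 15,
                         death_any_cause = 0),
                       p_early = 121 / 168,
                       p_group1_given_confirmed = 0.6,
                       availability_probs = c(adjudicable = 168 / 195,
                                              no_information = 4 / 195,
                                              not_found = 23 / 195),
                       severity_probs = c(high = 27 / 85,
                                          intermediate = 52 / 85,
                                          low = 6 / 85),
                       rater_agreement = 0.917,
                       p_excluded_child = 0.05,
                       p_decoy_outside = 0.10,
                       p_decoy_benign = 0.15,
                       p_decoy_outpatient = 0.05,
                       study_start = as.Date("2005-01-01"),
                       study_end = as.Date("2010-12-31")) {
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  p <- as.list(environment())
  p$study_start <- as.Date(p$study_start)
  p$study_end <- as.Date(p$study_end)
  probs <- c(p$case_rates, p$confirmation_probs, p$availability_probs,
             p$severity_probs, p$p_early, p$p_group1_given_confirmed,
             p$rater_agreement, p$p_excluded_child, p$p_decoy_outside,
             p$p_decoy_benign, p$p_decoy_outpatient, p$p_female,
             p$p_caucasian)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(p$case_rates) > 1) stop("case_rates must sum to <= 1", call. = FALSE)
  need <- c("intentional_overdose", "unintentional_overdose",
            "adverse_effect_therapeutic", "symptom_cns",
            "symptom_respiratory", "death_any_cause")
  if (!all(need %in% names(p$case_rates)) ||
      !all(need %in% names(p$confirmation_probs))) {
    stop("case_rates and confirmation_probs must name all six categories",
         call. = FALSE)
  }
  stopifnot(p$n_children >= 1,
            abs(sum(p$availability_probs) - 1) < 1e-8,
            length(p$days_supply_choices) == length(p$days_supply_probs))
  structure(p, class = "sim_params")
}

PLANT_CATEGORIES <- c("intentional_overdose", "unintentional_overdose",
                      "adverse_effect_therapeutic", "symptom_cns",
                      "symptom_respiratory", "death_any_cause")

# Concrete codes drawn from a registry group: a prefix pattern is itself a
# valid code of its family, so planted codes always match the active
# registry even when the registry is user-supplied.
sample_group_code <- function(group, n) {
  stopifnot(length(group$patterns) > 0)
  group$patterns[sample.int(length(group$patterns), n, replace = TRUE)]
}

#' Generate a synthetic claims bundle with planted ground truth
#'
#' Children are simulated with opioid fills spaced 60 days apart inside the
#' study window; each fill may plant at most one toxicity case whose
#' encounter (or death record) falls at a known early/late position inside
#' that fill's risk window and whose codes are drawn from the active
#' registry's triggering groups, so screening must recover exactly the
#' planted cases. Decoy encounters — triggering codes outside every window,
#' benign codes inside windows, outpatient encounters — are interleaved and
#' must never screen in. A fraction of children receive a lookback
#' exclusion code and must drop out of the cohort. For every planted case a
#' chart abstraction is generated whose deterministic adjudication
#' reproduces the drawn truth group, and a second reviewer's label is
#' simulated at the configured agreement.
#'
#' @param params A `sim_params`.
#' @param registry Code-set registry supplying the planted and exclusion
#'   codes (default: the bundled registry).
#' @return List with `bundle` (a validated `claims_bundle`),
#'   `abstractions` (one row per planted case, keyed by `child_id` +
#'   `event_date`, with `record_status` and reviewer-2 labels), and `truth`
#'   (planted category, subtype, stratum, confirmation status and group).
#'   Deterministic given `params$rng_seed`.
#' @export
generate_claims <- function(params, registry = load_registry()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  n <- params$n_children
  child_id <- sprintf("C%06d", seq_len(n))

  # demographics; ages truncated so every fill in a child's 6-month fill
  # horizon stays inside the eligible 2-17 completed years
  age <- stats::rnorm(n, params$age_mean_years, params$age_sd_years)
  while (any(bad <- age < 2.05 | age > 17.4)) {
    age[bad] <- stats::rnorm(sum(bad), params$age_mean_years,
                             params$age_sd_years)
  }
  sex <- ifelse(stats::runif(n) < params$p_female, "F", "M")
  race <- ifelse(stats::runif(n) < params$p_caucasian, "Caucasian", "other")

  horizon <- 225L  # max fill offset (3 extra fills x 60 d) + max window 45 d
  first_fill <- params$study_start +
    floor(stats::runif(n) *
            (as.integer(params$study_end - params$study_start) - horizon + 1L))
  birth_date <- first_fill - round(age * 365.25)
  excluded <- stats::runif(n) < params$p_excluded_child

  n_fills <- 1L + stats::rpois(n, params$fills_per_child_lambda)
  n_fills <- pmin(n_fills, 4L)
  ci <- rep(seq_len(n), n_fills)             # child index per fill
  fill_seq <- sequence(n_fills)
  fill_date <- first_fill[ci] + (fill_seq - 1L) * 60L
  days_supply <- sample(params$days_supply_choices, length(ci),
                        replace = TRUE, prob = params$days_supply_probs)
  supply_end <- fill_date + days_supply - 1L
  is_last <- fill_seq == n_fills[ci]

  # plant at most one case per fill of a non-excluded child
  rates <- params$case_rates[PLANT_CATEGORIES]
  cuts <- cumsum(rates)
  u <- stats::runif(length(ci))
  cat_idx <- findInterval(u, c(0, cuts), rightmost.closed = FALSE)
  cat_idx[u >= cuts[length(cuts)]] <- 0L
  planted_cat <- ifelse(cat_idx > 0, PLANT_CATEGORIES[pmax(cat_idx, 1L)],
                        NA_character_)
  planted_cat[excluded[ci]] <- NA_character_
  # deaths only on a child's last fill (a death ends follow-up)
  planted_cat[planted_cat == "death_any_cause" & !is_last] <- NA_character_
  planted <- !is.na(planted_cat)

  # event position: early stratum is fill day through supply_end + 7
  # (days_supply + 7 possible days), late is supply_end + 8 .. + 14 (7 days)
  early <- stats::runif(length(ci)) < params$p_early
  off_early <- floor(stats::runif(length(ci)) * (days_supply + 7L))
  off_late <- days_supply + 7L + floor(stats::runif(length(ci)) * 7L)
  event_offset <- ifelse(early, off_early, off_late)
  event_date <- fill_date + event_offset

  # truth draws
  conf_p <- params$confirmation_probs[planted_cat[planted]]
  confirmed <- stats::runif(sum(planted)) < conf_p
  group <- ifelse(
    confirmed,
    ifelse(stats::runif(sum(planted)) < params$p_group1_given_confirmed,
           ADJ_GROUPS[1], ADJ_GROUPS[2]),
    ADJ_GROUPS[3])
  record_status <- sample(names(params$availability_probs), sum(planted),
                          replace = TRUE, prob = params$availability_probs)

  truth <- data.frame(
    child_id = child_id[ci[planted]],
    event_date = event_date[planted],
    category = ifelse(planted_cat[planted] %in%
                        c("symptom_cns", "symptom_respiratory"),
                      "symptom_only", planted_cat[planted]),
    symptom_subtype = ifelse(planted_cat[planted] == "symptom_cns", "cns",
                             ifelse(planted_cat[planted] ==
                                      "symptom_respiratory", "respiratory",
                                    NA_character_)),
    time_stratum = ifelse(early[planted], "early", "late"),
    confirmed = confirmed,
    group = group,
    record_status = record_status,
    stringsAsFactors = FALSE)

  # claims tables ----------------------------------------------------------
  children <- data.frame(child_id = child_id, birth_date = birth_date,
                         sex = sex, race = race, stringsAsFactors = FALSE)
  last_fill_by_child <- first_fill + (n_fills - 1L) * 60L
  enrollment <- data.frame(
    child_id = child_id,
    start_date = pmax(birth_date, first_fill - 400L),
    end_date = last_fill_by_child + 60L, stringsAsFactors = FALSE)
  fills <- data.frame(child_id = child_id[ci], fill_date = fill_date,
                      drug_class = "opioid", days_supply = days_supply,
                      stringsAsFactors = FALSE)

  enc <- list()
  add_enc <- function(child, date, setting, dx, ecode) {
    enc[[length(enc) + 1L]] <<- data.frame(
      child_id = child, date = date, setting = setting, dx_codes = dx,
      ecodes = ecode, stringsAsFactors = FALSE)
  }

  is_death <- planted & planted_cat == "death_any_cause"
  enc_case <- planted & !is_death
  if (any(enc_case)) {
    cats <- planted_cat[enc_case]
    n_case <- sum(enc_case)
    dx <- rep("78900", n_case)   # benign filler primary diagnosis
    ecode <- rep("", n_case)
    for (cat in c("intentional_overdose", "unintentional_overdose",
                  "adverse_effect_therapeutic")) {
      sel <- cats == cat
      if (!any(sel)) next
      codes <- sample_group_code(registry$categories[[cat]]$A, sum(sel))
      is_e <- startsWith(codes, "E")
      ecode[sel][is_e] <- codes[is_e]
      dx[sel][!is_e] <- paste(dx[sel][!is_e], codes[!is_e], sep = ";")
    }
    for (cat in c("symptom_cns", "symptom_respiratory")) {
      sel <- cats == cat
      if (!any(sel)) next
      dx[sel] <- sample_group_code(registry$categories[[cat]]$dx, sum(sel))
    }
    add_enc(child_id[ci[enc_case]], event_date[enc_case],
            ifelse(stats::runif(n_case) < 0.7, "emergency", "inpatient"),
            dx, ecode)
  }
  deaths <- data.frame(child_id = character(0),
                       death_date = as.Date(character(0)),
                       cause_codes = character(0), stringsAsFactors = FALSE)
  if (any(is_death)) {
    deaths <- data.frame(child_id = child_id[ci[is_death]],
                         death_date = event_date[is_death],
                         cause_codes = "", stringsAsFactors = FALSE)
  }

  # lookback exclusion encounters for excluded children
  if (any(excluded)) {
    ex_names <- names(registry$exclusions)
    pick <- sample(ex_names, sum(excluded), replace = TRUE)
    ex_code <- vapply(pick, function(g) {
      sample_group_code(registry$exclusions[[g]], 1L)
    }, character(1))
    add_enc(child_id[excluded], first_fill[excluded] - 100L, "outpatient",
            ex_code, "")
  }

  # decoys: must never become potential cases
  window_end <- supply_end + 14L
  decoy_out <- stats::runif(length(ci)) < params$p_decoy_outside & !is_death
  if (any(decoy_out)) {
    add_enc(child_id[ci[decoy_out]], window_end[decoy_out] + 5L,
            "emergency", "78900", "E9350")
  }
  decoy_benign <- stats::runif(length(ci)) < params$p_decoy_benign
  if (any(decoy_benign)) {
    add_enc(child_id[ci[decoy_benign]], fill_date[decoy_benign] + 1L,
            "emergency", "4660", "")
  }
  decoy_outp <- stats::runif(length(ci)) < params$p_decoy_outpatient
  if (any(decoy_outp)) {
    add_enc(child_id[ci[decoy_outp]], fill_date[decoy_outp] + 2L,
            "outpatient", "78900", "E9500")
  }

  encounters <- if (length(enc)) do.call(rbind, enc) else NULL
  if (!is.null(encounters)) {
    encounters <- encounters[order(encounters$child_id, encounters$date), ,
                             drop = FALSE]
    encounters <- data.frame(
      encounter_id = sprintf("E%06d", seq_len(nrow(encounters))),
      encounters, stringsAsFactors = FALSE)
  }

  bundle <- claims_bundle(children = children, enrollment = enrollment,
                          fills = fills, encounters = encounters,
                          deaths = deaths)

  abstractions <- make_abstractions(truth, params)
  r2 <- perturb_rater(truth$group, params$rater_agreement)
  abstractions$group_r2 <- r2
  abstractions$record_status <- truth$record_status

  list(bundle = bundle, abstractions = abstractions, truth = truth,
       registry_version = registry$version)
}

# Abstraction rows whose deterministic adjudication reproduces the truth
# group, with severity/intent/source dressing for confirmed cases.
make_abstractions <- function(truth, params) {
  n <- nrow(truth)
  ab <- data.frame(
    child_id = truth$child_id, event_date = truth$event_date,
    stringsAsFactors = FALSE)
  for (f in ABSTRACTION_FLAGS) ab[[f]] <- rep(FALSE, n)
  ab$intent_evidence <- "unspecified"
  ab$source_evidence <- "unspecified"
  if (n == 0L) return(ab)

  g1 <- truth$group == ADJ_GROUPS[1]
  g2 <- truth$group == ADJ_GROUPS[2]
  g3 <- truth$group == ADJ_GROUPS[3]
  # Group 1: attributed toxicity, or the escalation arm (~25%)
  esc <- g1 & stats::runif(n) < 0.25
  ab$escalation_for_opioid_toxicity[esc] <- TRUE
  attr_arm <- g1 & !esc
  ab$signs_symptoms_compatible[attr_arm | g2] <- TRUE
  ab$physician_attributed_to_opioid[attr_arm] <- TRUE
  ab$temporal_sequence_consistent[g2] <- TRUE
  # Group 3: half attributed to another cause, half nothing compatible
  other <- g3 & stats::runif(n) < 0.5
  ab$signs_symptoms_compatible[other] <- TRUE
  ab$other_cause_implicated[other] <- TRUE
  ab$other_cause_attributed[other] <- TRUE

  conf <- truth$confirmed
  death_case <- conf & truth$category == "death_any_cause"
  ab$death[death_case] <- TRUE
  sev <- sample(names(params$severity_probs), n, replace = TRUE,
                prob = params$severity_probs)
  ab$hospitalization_or_escalation[conf & !death_case & sev == "high"] <- TRUE
  ab$ed_primary_reason[conf & !death_case & sev == "intermediate"] <- TRUE
  ab$incidental_mention[conf & !death_case & sev == "low"] <- TRUE
  # escalation-arm Group 1 cases escalated care by definition
  ab$hospitalization_or_escalation[esc] <- TRUE

  intent_map <- c(intentional_overdose = "self_harm",
                  unintentional_overdose = "unintentional_overdose",
                  adverse_effect_therapeutic = "therapeutic",
                  symptom_only = "therapeutic",
                  death_any_cause = "unspecified")
  ab$intent_evidence[conf] <- intent_map[truth$category[conf]]
  ab$source_evidence[conf] <- sample(
    c("own_prescription", "other_person", "unspecified"), sum(conf),
    replace = TRUE, prob = c(0.9, 0.05, 0.05))
  ab
}

perturb_rater <- function(groups, agreement) {
  n <- length(groups)
  if (n == 0L) return(character(0))
  keep <- stats::runif(n) < agreement
  out <- groups
  flip <- which(!keep)
  if (length(flip)) {
    out[flip] <- vapply(groups[flip], function(g) {
      sample(setdiff(ADJ_GROUPS, g), 1L)
    }, character(1))
  }
  out
}

#' Simulate a second reviewer at a target agreement level
#'
#' Reviewer 1 reproduces the truth groups; reviewer 2 agrees with
#' probability `agreement` and otherwise picks uniformly among the other
#' two groups.
#'
#' @param truth_groups Character vector of adjudication groups.
#' @param agreement Agreement probability in `[0, 1]`.
#' @param seed Optional seed for this draw alone.
#' @return List with `r1` and `r2` label vectors.
#' @export
generate_rater_pair <- function(truth_groups, agreement, seed = NULL) {
  stopifnot(agreement >= 0, agreement <= 1)
  if (!is.null(seed)) set.seed(seed)
  list(r1 = truth_groups, r2 = perturb_rater(truth_groups, agreement))
}
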