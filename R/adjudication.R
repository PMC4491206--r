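# Adjudication rule engine: deterministic mapping from a structured chart
# abstraction to the mutually exclusive outcome groups, severity, and the
# circumstances/source of the opioid exposure, plus the two-reviewer
# consensus bookkeeping.

ADJ_GROUPS <- c("group1_definite_probable", "group2_possible",
                "group3_excluded")
SEVERITY_LEVELS <- c("death", "high", "intermediate", "low")
INTENT_LEVELS <- c("self_harm", "recreational", "unintentional_overdose",
                   "therapeutic", "withdrawal", "unspecified")
SOURCE_LEVELS <- c("own_prescription", "other_person", "illegal",
                   "unspecified")

ABSTRACTION_FLAGS <- c(
  "signs_symptoms_compatible", "physician_attributed_to_opioid",
  "other_cause_implicated", "other_cause_attributed",
  "escalation_for_opioid_toxicity", "temporal_sequence_consistent",
  "hospitalization_or_escalation", "ed_primary_reason",
  "incidental_mention", "death"
)

#' Construct a chart-abstraction record
#'
#' The minimal structured summary of a medical-record review sufficient to
#' drive the adjudication rules: whether signs/symptoms compatible with
#' opioid toxicity were present and whether the treating physician
#' attributed them to an opioid or to another cause; whether care was
#' escalated because of potential opioid toxicity; whether the temporal
#' sequence made opioid causation plausible; the severity markers
#' (hospitalization/escalation, primary reason for an ED visit, incidental
#' mention, death); and the documented exposure circumstances and opioid
#' source. Subjective judgment lives in producing these fields; everything
#' downstream is deterministic.
#'
#' @param ... Logical flags from `ABSTRACTION_FLAGS` (all default `FALSE`)
#'   plus `intent_evidence` (default `"unspecified"`) and `source_evidence`
#'   (default `"unspecified"`).
#' @return A one-row data frame of class `chart_abstraction`.
#' @export
chart_abstraction <- function(...) {
  args <- list(...)
  unknown <- setdiff(names(args),
                     c(ABSTRACTION_FLAGS, "intent_evidence", "source_evidence",
                       "case_id"))
  if (length(unknown)) {
    stop("unknown abstraction field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  a <- as.list(setNames(rep(FALSE, length(ABSTRACTION_FLAGS)),
                        ABSTRACTION_FLAGS))
  a$case_id <- NA_character_
  a$intent_evidence <- "unspecified"
  a$source_evidence <- "unspecified"
  a[names(args)] <- args
  df <- as.data.frame(a, stringsAsFactors = FALSE)
  class(df) <- c("chart_abstraction", class(df))
  df
}

#' Adjudicate chart abstractions into outcome groups
#'
#' Encodes the mutually exclusive outcome definitions. Group 1
#' (definite/probable): signs and symptoms compatible with opioid toxicity,
#' attributed by the treating physician to the opioid, with no other drug or
#' disease process implicated — or direct intervention/escalation of care
#' because of potential opioid toxicity (e.g. ICU admission after an
#' inadvertent hydrocodone overdose). Group 2 (possible): compatible signs
#' or symptoms not clearly attributed to the opioid but not attributed to
#' another cause, with a temporal sequence consistent with opioid causation.
#' Group 3 (excluded): everything else — symptoms attributed to another
#' cause, an inconsistent temporal sequence, or no compatible findings at
#' all. Exactly one group applies to every abstraction.
#'
#' @param a A `chart_abstraction` or a data frame of abstraction rows.
#' @return Character vector of groups, one per row.
#' @export
adjudicate <- function(a) {
  g1 <- (a$signs_symptoms_compatible & a$physician_attributed_to_opioid &
           !a$other_cause_implicated) | a$escalation_for_opioid_toxicity
  g2 <- a$signs_symptoms_compatible & !a$physician_attributed_to_opioid &
    !a$other_cause_attributed & a$temporal_sequence_consistent
  ifelse(g1, ADJ_GROUPS[1], ifelse(g2, ADJ_GROUPS[2], ADJ_GROUPS[3]))
}

#' Severity of a confirmed case
#'
#' Total on confirmed (Group 1/2) cases, with strict dominance
#' death > high > intermediate > low: death attributed to the opioid; high
#' if the adverse effect led to hospitalization or escalation of care;
#' intermediate if the opioid-related symptoms were the primary reason for
#' an ED visit; low if they were an incidental or minor part of the
#' encounter.
#'
#' @param a Abstraction row(s).
#' @param group Adjudicated group(s), from [adjudicate()].
#' @return Character vector of severities.
#' @export
classify_severity <- function(a, group) {
  if (any(group == ADJ_GROUPS[3])) {
    stop("severity is only defined for confirmed (Group 1/2) cases",
         call. = FALSE)
  }
  ifelse(a$death, "death",
         ifelse(a$hospitalization_or_escalation, "high",
                ifelse(a$ed_primary_reason, "intermediate", "low")))
}

#' Circumstances and source of the opioid exposure
#'
#' Passes the documented labels through unchanged after validating them
#' against the closed vocabularies; `"unspecified"` is retained, never
#' imputed.
#'
#' @param a Abstraction row(s).
#' @return Data frame with `intent` and `source` columns.
#' @export
classify_exposure <- function(a) {
  bad_i <- setdiff(unique(a$intent_evidence), INTENT_LEVELS)
  bad_s <- setdiff(unique(a$source_evidence), SOURCE_LEVELS)
  if (length(bad_i)) stop("unknown intent label(s): ",
                          paste(bad_i, collapse = ", "), call. = FALSE)
  if (length(bad_s)) stop("unknown source label(s): ",
                          paste(bad_s, collapse = ", "), call. = FALSE)
  data.frame(intent = a$intent_evidence, source = a$source_evidence,
             stringsAsFactors = FALSE)
}

#' Full adjudication of abstraction records
#'
#' @param abstractions Data frame of abstraction rows (one per case).
#' @return Data frame with `case_id`, `group`, and — for confirmed cases —
#'   `severity`, `intent`, `source` (NA for Group 3).
#' @export
adjudicate_cases <- function(abstractions) {
  group <- adjudicate(abstractions)
  confirmed <- group != ADJ_GROUPS[3]
  severity <- rep(NA_character_, length(group))
  intent <- rep(NA_character_, length(group))
  source <- rep(NA_character_, length(group))
  if (any(confirmed)) {
    ac <- abstractions[confirmed, , drop = FALSE]
    severity[confirmed] <- classify_severity(ac, group[confirmed])
    exp <- classify_exposure(ac)
    intent[confirmed] <- exp$intent
    source[confirmed] <- exp$source
  }
  data.frame(case_id = abstractions$case_id, group = group,
             severity = severity, intent = intent, source = source,
             stringsAsFactors = FALSE)
}

#' Two-reviewer consensus
#'
#' When the independent reviewers agree, their common group stands. When
#' they disagree the case is flagged and the final group is taken from the
#' supplied committee label — the engine never auto-resolves disagreements,
#' mirroring adjudication by the full investigator panel.
#'
#' @param group_r1,group_r2 Equal-length character vectors of groups.
#' @param committee Committee labels; required (non-NA) wherever the
#'   reviewers disagree.
#' @return Data frame with `final_group` and `disagreement` (logical).
#' @export
consensus <- function(group_r1, group_r2, committee = NULL) {
  stopifnot(length(group_r1) == length(group_r2))
  check_groups <- function(g, what) {
    bad <- setdiff(unique(g[!is.na(g)]), ADJ_GROUPS)
    if (length(bad)) stop("unknown ", what, " group label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  check_groups(group_r1, "reviewer-1"); check_groups(group_r2, "reviewer-2")
  if (is.null(committee)) committee <- rep(NA_character_, length(group_r1))
  check_groups(committee, "committee")
  disagreement <- group_r1 != group_r2
  need <- disagreement & is.na(committee)
  if (any(need)) {
    stop("committee label required for ", sum(need),
         " disagreeing case(s)", call. = FALSE)
  }
  data.frame(final_group = ifelse(disagreement, committee, group_r1),
             disagreement = disagreement, stringsAsFactors = FALSE)
}
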