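# Case screening: prescription-anchored risk windows, screening-code
# classification of ED/inpatient encounters, death review, and emission of
# potential cases with early/late time strata.

CATEGORY_LEVELS <- c("intentional_overdose", "unintentional_overdose",
                     "adverse_effect_therapeutic", "symptom_only",
                     "death_any_cause")

#' Build per-prescription risk windows
#'
#' The fill day counts as supply day 1, so the supplied period ends at
#' `fill_date + days_supply - 1`; follow-up extends 14 further days. The
#' early/late cut for time-stratified analyses falls 7 days after the end of
#' supply: events through `supply_end + 7` are "early", events on
#' `supply_end + 8` through `supply_end + 14` are "late". All endpoints
#' inclusive. Overlapping windows from overlapping fills are all retained.
#'
#' @param fills Data frame with `child_id`, `fill_date`, `days_supply`
#'   (e.g. the output of [build_cohort()]).
#' @return Data frame with `child_id`, `fill_date`, `supply_end`,
#'   `early_cutoff`, `window_end`, one row per fill.
#' @export
build_windows <- function(fills) {
  if (any(is.na(fills$days_supply) | fills$days_supply < 1L)) {
    stop("days_supply must be >= 1", call. = FALSE)
  }
  fill_date <- as.Date(fills$fill_date)
  supply_end <- fill_date + (as.integer(fills$days_supply) - 1L)
  data.frame(
    child_id = fills$child_id,
    fill_date = fill_date,
    supply_end = supply_end,
    early_cutoff = supply_end + 7L,
    window_end = supply_end + 14L,
    stringsAsFactors = FALSE
  )
}

#' Classify one encounter into a screening category
#'
#' Applies the screening-code logic to an emergency-department or inpatient
#' encounter. Categories are evaluated in precedence order (most specific
#' intent first): self-harm overdose, then unintentional overdose, then
#' adverse effect in therapeutic use, then CNS/respiratory symptoms. For the
#' three external-cause categories a Group A code (opioid or unspecified
#' analgesic) always triggers, while a Group C code (unspecified medication)
#' triggers only when no Group B code (a specific non-opioid drug) appears
#' anywhere on the encounter — an encounter attributed to another named drug
#' is not pulled in via the unspecified-medication route. Set
#' `b_veto = "AC"` to let a Group B code veto Group A matches as well.
#' Symptom codes are matched against diagnosis codes only, and only when no
#' external-cause category fired.
#'
#' @param dx_codes,ecodes Character vectors of ICD-9-CM codes (normalized
#'   internally); `dx_codes` non-empty, first entry primary.
#' @param setting `"emergency"` or `"inpatient"`; outpatient encounters are
#'   not screened and raise an error.
#' @param registry A `codeset_registry`.
#' @param b_veto Scope of the Group-B veto: `"C"` (default) or `"AC"`.
#' @param precedence Category evaluation order; default most-specific first.
#' @return `NULL` if no category fires, else a list with `category` and
#'   (for `symptom_only`) `subtype` in `{"cns", "respiratory", "both"}`.
#' @export
classify_encounter <- function(dx_codes, ecodes, setting, registry,
                               b_veto = c("C", "AC"),
                               precedence = c("intentional_overdose",
                                              "unintentional_overdose",
                                              "adverse_effect_therapeutic",
                                              "symptom_only")) {
  b_veto <- match.arg(b_veto)
  if (!setting %in% c("emergency", "inpatient")) {
    stop("only emergency or inpatient encounters are screened; got '",
         setting, "'", call. = FALSE)
  }
  dx <- if (length(dx_codes)) normalize_code(dx_codes) else character(0)
  ec <- if (length(ecodes)) normalize_code(ecodes) else character(0)
  all_codes <- c(dx, ec)
  for (cat in precedence) {
    if (cat == "symptom_only") {
      cns <- match_code(dx, registry$categories$symptom_cns$dx)
      resp <- match_code(dx, registry$categories$symptom_respiratory$dx)
      if (cns || resp) {
        subtype <- if (cns && resp) "both" else if (cns) "cns" else "respiratory"
        return(list(category = "symptom_only", subtype = subtype))
      }
    } else {
      groups <- registry$categories[[cat]]
      a_hit <- match_code(all_codes, groups$A)
      c_hit <- match_code(all_codes, groups$C)
      b_hit <- if (a_hit || c_hit) match_code(all_codes, groups$B) else FALSE
      fired <- if (b_veto == "AC") (a_hit || c_hit) && !b_hit
               else a_hit || (c_hit && !b_hit)
      if (fired) return(list(category = cat, subtype = NA_character_))
    }
  }
  NULL
}

#' Screen a cohort for potential opioid-toxicity cases
#'
#' Classifies every emergency/inpatient encounter of a cohort child that
#' falls inside at least one of the child's risk windows, and flags every
#' death whose date falls inside a window for record review regardless of
#' its cause-of-death codes. Each window-qualifying event date yields at
#' most one potential case per child: a death supersedes a same-day
#' encounter, otherwise ties resolve by category precedence and then
#' encounter id. An event covered by several overlapping windows is
#' attributed to the most recent qualifying fill on or before it; the
#' early/late time stratum is read off the attributed window.
#'
#' @param cohort Qualifying fills from [build_cohort()].
#' @param bundle The `claims_bundle`.
#' @param registry A `codeset_registry`.
#' @param b_veto Passed through to [classify_encounter()].
#' @return Data frame of potential cases: `case_id`, `child_id`,
#'   `event_date`, `category`, `symptom_subtype`, `encounter_id` (NA for
#'   deaths), the attributed window anchors (`fill_date`, `supply_end`,
#'   `early_cutoff`, `window_end`) and `time_stratum` (`"early"`/`"late"`),
#'   sorted by child then event date.
#' @export
screen <- function(cohort, bundle, registry, b_veto = "C") {
  windows <- build_windows(cohort)
  empty <- data.frame(
    case_id = character(0), child_id = character(0),
    event_date = as.Date(character(0)), category = character(0),
    symptom_subtype = character(0), encounter_id = character(0),
    fill_date = as.Date(character(0)), supply_end = as.Date(character(0)),
    early_cutoff = as.Date(character(0)), window_end = as.Date(character(0)),
    time_stratum = character(0), stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  win_by_child <- split(seq_len(nrow(windows)), windows$child_id)

  attribute_window <- function(child_id, event_date) {
    idx <- win_by_child[[child_id]]
    if (is.null(idx)) return(NA_integer_)
    idx <- idx[windows$fill_date[idx] <= event_date &
                 event_date <= windows$window_end[idx]]
    if (!length(idx)) return(NA_integer_)
    idx[which.max(as.integer(windows$fill_date[idx]))]
  }

  rows <- list()
  enc <- bundle$encounters
  if (nrow(enc)) {
    scr <- enc[enc$setting %in% c("emergency", "inpatient") &
                 enc$child_id %in% names(win_by_child), , drop = FALSE]
    if (nrow(scr)) {
      dx <- split_codes(scr$dx_codes)
      ec <- split_codes(scr$ecodes)
      for (i in seq_len(nrow(scr))) {
        w <- attribute_window(scr$child_id[i], scr$date[i])
        if (is.na(w)) next
        cls <- classify_encounter(dx[[i]], ec[[i]], scr$setting[i], registry,
                                  b_veto = b_veto)
        if (is.null(cls)) next
        rows[[length(rows) + 1L]] <- data.frame(
          child_id = scr$child_id[i], event_date = scr$date[i],
          category = cls$category, symptom_subtype = cls$subtype,
          encounter_id = scr$encounter_id[i], window = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  de <- bundle$deaths
  if (nrow(de)) {
    for (i in seq_len(nrow(de))) {
      w <- attribute_window(de$child_id[i], de$death_date[i])
      if (is.na(w)) next
      rows[[length(rows) + 1L]] <- data.frame(
        child_id = de$child_id[i], event_date = de$death_date[i],
        category = "death_any_cause", symptom_subtype = NA_character_,
        encounter_id = NA_character_, window = w, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  cases <- do.call(rbind, rows)

  # one potential case per (child, event date): death first, then category
  # precedence, then encounter id for determinism
  prio <- match(cases$category,
                c("death_any_cause", "intentional_overdose",
                  "unintentional_overdose", "adverse_effect_therapeutic",
                  "symptom_only"))
  ord <- order(cases$child_id, cases$event_date, prio, cases$encounter_id,
               na.last = TRUE)
  cases <- cases[ord, , drop = FALSE]
  cases <- cases[!duplicated(cases[c("child_id", "event_date")]), ,
                 drop = FALSE]

  w <- cases$window
  cases$fill_date <- windows$fill_date[w]
  cases$supply_end <- windows$supply_end[w]
  cases$early_cutoff <- windows$early_cutoff[w]
  cases$window_end <- windows$window_end[w]
  cases$time_stratum <- ifelse(cases$event_date <= cases$early_cutoff,
                               "early", "late")
  cases$window <- NULL
  cases <- cases[order(cases$child_id, cases$event_date), , drop = FALSE]
  cases$case_id <- sprintf("case%04d", seq_len(nrow(cases)))
  rownames(cases) <- NULL
  cases[, names(empty)]
}
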