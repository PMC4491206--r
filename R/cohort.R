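# Cohort eligibility: age bounds at fill, study window, and the 12-month
# lookback exclusions for serious illness, transplant, institutional
# residence and drug abuse.

#' Completed age in years
#'
#' Birthday-based: the count of whole years elapsed, incrementing on the
#' anniversary of the birth date.
#'
#' @param birth_date,on_date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @examples
#' age_at(as.Date("2000-06-15"), as.Date("2010-06-14"))  # 9
#' @export
age_at <- function(birth_date, on_date) {
  birth_date <- as.Date(birth_date)
  on_date <- as.Date(on_date)
  if (any(on_date < birth_date)) {
    stop("on_date precedes birth_date", call. = FALSE)
  }
  b <- as.POSIXlt(birth_date)
  o <- as.POSIXlt(on_date)
  yrs <- o$year - b$year
  before_bday <- (o$mon < b$mon) | (o$mon == b$mon & o$mday < b$mday)
  as.integer(yrs - before_bday)
}

#' Cohort eligibility specification
#'
#' @param study_start,study_end Calendar bounds on qualifying fill dates.
#' @param min_age_years,max_age_years Inclusive age bounds evaluated at each
#'   fill date (defaults 2 and 17).
#' @param lookback_days History window, in days before the fill, scanned for
#'   exclusionary codes (default 365; 0 disables history exclusions).
#' @param require_continuous_enrollment If `TRUE`, the whole lookback window
#'   must be covered by enrollment spans (default `FALSE`).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(study_start, study_end,
                        min_age_years = 2L, max_age_years = 17L,
                        lookback_days = 365L,
                        require_continuous_enrollment = FALSE) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(min_age_years < max_age_years, lookback_days >= 0,
            study_start <= study_end)
  structure(
    list(study_start = study_start, study_end = study_end,
         min_age_years = as.integer(min_age_years),
         max_age_years = as.integer(max_age_years),
         lookback_days = as.integer(lookback_days),
         require_continuous_enrollment = require_continuous_enrollment),
    class = "cohort_spec")
}

#' Build the study cohort of qualifying opioid fills
#'
#' Eligibility is evaluated per fill, since each fill anchors its own
#' follow-up window: the fill must be an opioid fill, dated inside the study
#' window, with the child aged within the inclusive age bounds on the fill
#' date, and with no encounter carrying an exclusion-group code (serious
#' illness, transplant, institutional residence, drug abuse) in the
#' `lookback_days` strictly before the fill date. Children whose fills all
#' fail are dropped. Naloxone receipt is deliberately not an exclusion.
#'
#' @param bundle A validated `claims_bundle`.
#' @param spec A `cohort_spec`.
#' @param registry A `codeset_registry` whose `exclusions` supply the
#'   lookback code groups (may be empty, disabling history exclusions).
#' @return Data frame of qualifying fills (`child_id`, `fill_date`,
#'   `days_supply`), one row per retained fill, sorted by child then date;
#'   attribute `exclusion_counts` tallies fills removed per reason.
#' @export
build_cohort <- function(bundle, spec, registry) {
  stopifnot(inherits(bundle, "claims_bundle"), inherits(spec, "cohort_spec"),
            inherits(registry, "codeset_registry"))
  fl <- bundle$fills
  counts <- c(non_opioid = 0L, outside_study_window = 0L, age = 0L,
              no_enrollment_coverage = 0L,
              setNames(integer(length(registry$exclusions)),
                       names(registry$exclusions)))
  out <- empty_cohort()
  if (!nrow(fl)) {
    attr(out, "exclusion_counts") <- counts
    return(out)
  }
  bd <- setNames(bundle$children$birth_date, bundle$children$child_id)
  keep <- fl$drug_class == "opioid"
  counts["non_opioid"] <- sum(!keep)
  in_window <- fl$fill_date >= spec$study_start & fl$fill_date <= spec$study_end
  counts["outside_study_window"] <- sum(keep & !in_window)
  keep <- keep & in_window
  age_ok <- rep(FALSE, nrow(fl))
  age_ok[keep] <- {
    a <- age_at(bd[fl$child_id[keep]], fl$fill_date[keep])
    a >= spec$min_age_years & a <= spec$max_age_years
  }
  counts["age"] <- sum(keep & !age_ok)
  keep <- keep & age_ok

  if (spec$require_continuous_enrollment && any(keep)) {
    cov <- covered_by_enrollment(fl, bundle$enrollment, spec$lookback_days)
    counts["no_enrollment_coverage"] <- sum(keep & !cov)
    keep <- keep & cov
  }

  if (spec$lookback_days > 0L && length(registry$exclusions) && any(keep)) {
    enc <- bundle$encounters
    enc_codes <- split_codes(enc$dx_codes)
    enc_ecodes <- split_codes(enc$ecodes)
    enc_by_child <- split(seq_len(nrow(enc)), enc$child_id)
    for (i in which(keep)) {
      idx <- enc_by_child[[fl$child_id[i]]]
      if (is.null(idx)) next
      lb_start <- fl$fill_date[i] - spec$lookback_days
      idx <- idx[enc$date[idx] >= lb_start & enc$date[idx] < fl$fill_date[i]]
      if (!length(idx)) next
      for (ex in names(registry$exclusions)) {
        grp <- registry$exclusions[[ex]]
        hit <- any(vapply(idx, function(j) {
          match_code(c(enc_codes[[j]], enc_ecodes[[j]]), grp)
        }, logical(1)))
        if (hit) {
          counts[ex] <- counts[ex] + 1L
          keep[i] <- FALSE
          break
        }
      }
    }
  }

  out <- fl[keep, c("child_id", "fill_date", "days_supply"), drop = FALSE]
  out <- out[order(out$child_id, out$fill_date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_counts") <- counts
  out
}

empty_cohort <- function() {
  data.frame(child_id = character(0), fill_date = as.Date(character(0)),
             days_supply = integer(0), stringsAsFactors = FALSE)
}

covered_by_enrollment <- function(fills, enrollment, lookback_days) {
  ok <- logical(nrow(fills))
  by_child <- split(seq_len(nrow(enrollment)), enrollment$child_id)
  for (i in seq_len(nrow(fills))) {
    idx <- by_child[[fills$child_id[i]]]
    if (is.null(idx)) next
    lb_start <- fills$fill_date[i] - lookback_days
    # require one span covering the whole lookback (spans are not merged;
    # synthetic data uses one span per child)
    ok[i] <- any(enrollment$start_date[idx] <= lb_start &
                   enrollment$end_date[idx] >= fills$fill_date[i])
  }
  ok
}
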