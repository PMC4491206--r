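# Validation statistics for the screening algorithm: record-availability
# accounting, overall and stratified positive predictive values with exact
# binomial confidence intervals, percent agreement, and Cohen's kappa.

#' Positive predictive value with an exact binomial confidence interval
#'
#' PPV is the fraction of adjudicable screened cases confirmed as true
#' toxicity (Group 1 or Group 2) on record review. The 95% interval is the
#' Clopper-Pearson exact interval. A cell with zero adjudicable cases is
#' undefined (all-NA), never zero.
#'
#' @param n_confirmed,n_total Non-negative counts, `n_confirmed <= n_total`.
#' @param stratum Optional stratum label carried into the output.
#' @return One-row data frame: `stratum`, `n_total`, `n_confirmed`,
#'   `ppv_percent` (unrounded), `ci_lower_percent`, `ci_upper_percent`.
#' @examples
#' ppv(85, 168)   # 50.6% overall
#' @export
ppv <- function(n_confirmed, n_total, stratum = NA_character_) {
  stopifnot(length(n_confirmed) == 1L, length(n_total) == 1L,
            n_confirmed >= 0, n_total >= 0, n_confirmed <= n_total)
  if (n_total == 0L) {
    return(data.frame(stratum = stratum, n_total = 0L, n_confirmed = 0L,
                      ppv_percent = NA_real_, ci_lower_percent = NA_real_,
                      ci_upper_percent = NA_real_, stringsAsFactors = FALSE))
  }
  ci <- clopper_pearson(n_confirmed, n_total)
  data.frame(stratum = stratum, n_total = as.integer(n_total),
             n_confirmed = as.integer(n_confirmed),
             ppv_percent = 100 * n_confirmed / n_total,
             ci_lower_percent = 100 * ci[1], ci_upper_percent = 100 * ci[2],
             stringsAsFactors = FALSE)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Closed form via beta quantiles: lower bound `qbeta(a/2, x, n-x+1)` (0
#' when x = 0), upper bound `qbeta(1-a/2, x+1, n-x)` (1 when x = n).
#'
#' @param x Successes; `n` trials; `conf_level` coverage (default 0.95).
#' @return Length-2 numeric vector (lower, upper) on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

#' Kappa from observed and expected agreement
#'
#' `(po - pe) / (1 - pe)`: the amount of agreement achieved beyond chance,
#' as a fraction of the agreement achievable beyond chance.
#'
#' @param po Observed agreement proportion in `[0, 1]`.
#' @param pe Expected (chance) agreement proportion in `[0, 1)`.
#' @return Kappa.
#' @examples
#' kappa_from_agreement(0.917, 0.506)  # 0.832
#' @export
kappa_from_agreement <- function(po, pe) {
  stopifnot(po >= 0, po <= 1, pe >= 0)
  if (any(pe >= 1)) stop("expected agreement must be < 1", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Cohen's kappa for two raters
#'
#' Unweighted multi-category kappa: observed agreement is the fraction of
#' identically labelled cases; expected agreement is the sum over labels of
#' the product of the two raters' marginal proportions.
#'
#' @param labels_r1,labels_r2 Equal-length non-empty label vectors.
#' @return List with `n`, `observed_agreement`, `expected_agreement`,
#'   `kappa` (NA with a warning when both raters are constant and
#'   identical, where chance agreement is 1 and kappa undefined).
#' @export
cohens_kappa <- function(labels_r1, labels_r2) {
  n <- length(labels_r1)
  stopifnot(n >= 1L, length(labels_r2) == n)
  labs <- sort(unique(c(labels_r1, labels_r2)))
  po <- mean(labels_r1 == labels_r2)
  p1 <- table(factor(labels_r1, levels = labs)) / n
  p2 <- table(factor(labels_r2, levels = labs)) / n
  pe <- sum(as.numeric(p1) * as.numeric(p2))
  kappa <- if (pe >= 1) {
    warning("both raters constant and identical; kappa undefined",
            call. = FALSE)
    NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  list(n = n, observed_agreement = po, expected_agreement = pe, kappa = kappa)
}

#' Build the full validation report
#'
#' Assembles the validation statistics from screened potential cases, their
#' record availability, and the final adjudications: the screening funnel
#' (screened, records with insufficient information, records not found,
#' adjudicable), the overall PPV, PPVs stratified by screening category,
#' symptom subtype and early/late time stratum, severity/intent/source
#' frequency tables over confirmed cases, and (optionally) inter-rater
#' reliability.
#'
#' @param cases Potential cases from [screen()], plus a `record_status`
#'   column in `{"adjudicable", "no_information", "not_found"}` (a missing
#'   column means all adjudicable).
#' @param adjudications Data frame with `case_id`, `group` and, for
#'   confirmed cases, `severity`, `intent`, `source` — the final (consensus)
#'   adjudication of every adjudicable case.
#' @param raters Optional data frame with `group_r1`, `group_r2` for the
#'   reliability statistics.
#' @param registry_version Code-set version string recorded in the report.
#' @return An object of class `validation_report`.
#' @export
build_report <- function(cases, adjudications, raters = NULL,
                         registry_version = NA_character_) {
  if (!"record_status" %in% names(cases)) {
    cases$record_status <- rep("adjudicable", nrow(cases))
  }
  bad <- setdiff(unique(cases$record_status),
                 c("adjudicable", "no_information", "not_found"))
  if (length(bad)) {
    stop("unknown record_status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  adj <- cases[cases$record_status == "adjudicable", , drop = FALSE]
  availability <- list(
    n_screened = nrow(cases),
    n_no_information = sum(cases$record_status == "no_information"),
    n_not_found = sum(cases$record_status == "not_found"),
    n_adjudicable = nrow(adj)
  )
  m <- match(adj$case_id, adjudications$case_id)
  if (anyNA(m)) {
    stop("adjudicable case(s) without a final adjudication: ",
         paste(adj$case_id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  group <- adjudications$group[m]
  bad_g <- setdiff(unique(group), ADJ_GROUPS)
  if (length(bad_g)) {
    stop("unknown adjudication group(s): ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  confirmed <- group %in% ADJ_GROUPS[1:2]

  cell <- function(mask, label) {
    ppv(sum(confirmed & mask), sum(mask), stratum = label)
  }
  overall <- cell(rep(TRUE, nrow(adj)), "overall")
  by_category <- do.call(rbind, lapply(CATEGORY_LEVELS, function(cat) {
    cell(adj$category == cat, cat)
  }))
  subtype_mask <- function(s) {
    adj$category == "symptom_only" &
      adj$symptom_subtype %in% c(s, "both")
  }
  by_subtype <- rbind(cell(adj$category == "symptom_only", "all_symptoms"),
                      cell(subtype_mask("cns"), "cns"),
                      cell(subtype_mask("respiratory"), "respiratory"))
  by_stratum <- rbind(cell(adj$time_stratum == "early", "early"),
                      cell(adj$time_stratum == "late", "late"))

  freq_table <- function(values, levels) {
    tab <- table(factor(values, levels = levels))
    data.frame(level = levels, n = as.integer(tab),
               percent = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab)
                         else rep(NA_real_, length(levels)),
               stringsAsFactors = FALSE)
  }
  conf_rows <- adjudications[m, , drop = FALSE][confirmed, , drop = FALSE]
  severity <- freq_table(conf_rows$severity, SEVERITY_LEVELS)
  intent <- freq_table(conf_rows$intent, INTENT_LEVELS)
  source <- freq_table(conf_rows$source, SOURCE_LEVELS)

  reliability <- NULL
  if (!is.null(raters) && nrow(raters) > 0) {
    reliability <- cohens_kappa(raters$group_r1, raters$group_r2)
  }

  report <- structure(
    list(registry_version = registry_version, availability = availability,
         overall = overall, by_category = by_category,
         by_subtype = by_subtype, by_stratum = by_stratum,
         severity = severity, intent = intent, source = source,
         reliability = reliability),
    class = "validation_report")
  check_report_additivity(report)
  report
}

check_report_additivity <- function(report) {
  stopifnot(
    report$availability$n_adjudicable ==
      report$availability$n_screened - report$availability$n_no_information -
      report$availability$n_not_found,
    sum(report$by_category$n_total) == report$overall$n_total,
    sum(report$by_category$n_confirmed) == report$overall$n_confirmed,
    sum(report$by_stratum$n_total) == report$overall$n_total,
    sum(report$by_stratum$n_confirmed) == report$overall$n_confirmed
  )
  invisible(report)
}

#' Write a validation report as JSON
#' @param report A `validation_report`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  av <- x$availability
  cat("Validation report (code set ", x$registry_version, ")\n", sep = "")
  cat(sprintf(
    "  screened %d | no information %d | not found %d | adjudicable %d\n",
    av$n_screened, av$n_no_information, av$n_not_found, av$n_adjudicable))
  fmt_cell <- function(cell) {
    sprintf("  %-28s %4d %4d  %s", cell$stratum, cell$n_total,
            cell$n_confirmed,
            ifelse(is.na(cell$ppv_percent), "   --",
                   sprintf("%5.1f (%4.1f-%5.1f)", cell$ppv_percent,
                           cell$ci_lower_percent, cell$ci_upper_percent)))
  }
  cat("  stratum                         n conf  PPV% (95% CI)\n")
  for (tab in list(x$overall, x$by_category, x$by_subtype, x$by_stratum)) {
    for (i in seq_len(nrow(tab))) cat(fmt_cell(tab[i, ]), "\n")
  }
  if (!is.null(x$reliability)) {
    r <- x$reliability
    cat(sprintf(
      "  reliability: n=%d, observed=%.1f%%, expected=%.1f%%, kappa=%.2f\n",
      r$n, 100 * r$observed_agreement, 100 * r$expected_agreement, r$kappa))
  }
  invisible(x)
}
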