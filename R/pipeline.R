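# Stage orchestration: simulate | screen | adjudicate | validate, each
# communicating through plain CSV/JSON artifacts in an output directory so
# any stage can be replaced by real-data inputs.

#' Simulate stage: write a synthetic bundle plus truth and abstractions
#'
#' @param params A `sim_params`.
#' @param out_dir Output directory.
#' @param registry A `codeset_registry`.
#' @return Paths of the written artifacts, invisibly.
#' @export
stage_simulate <- function(params, out_dir, registry = load_registry()) {
  sim <- generate_claims(params, registry)
  write_bundle(sim$bundle, out_dir)
  write_stage_csv(sim$truth, file.path(out_dir, "truth.csv"))
  write_stage_csv(sim$abstractions, file.path(out_dir, "abstractions.csv"))
  log_line(out_dir, sprintf(
    "simulate: %d children, %d fills, %d encounters, %d planted cases",
    nrow(sim$bundle$children), nrow(sim$bundle$fills),
    nrow(sim$bundle$encounters), nrow(sim$truth)))
  invisible(file.path(out_dir, c("children.csv", "truth.csv",
                                 "abstractions.csv")))
}

#' Screen stage: cohort + risk windows + screening codes -> potential cases
#'
#' @param bundle_dir Directory holding the five claims CSVs.
#' @param spec A `cohort_spec`.
#' @param registry A `codeset_registry`.
#' @param out_dir Output directory for `potential_cases.csv`.
#' @return The potential-case data frame, invisibly.
#' @export
stage_screen <- function(bundle_dir, spec, registry = load_registry(),
                         out_dir = bundle_dir) {
  bundle <- read_bundle(bundle_dir)
  cohort <- build_cohort(bundle, spec, registry)
  cases <- screen(cohort, bundle, registry)
  write_stage_csv(cases, file.path(out_dir, "potential_cases.csv"))
  log_line(out_dir, sprintf(
    "screen: %d qualifying fills, %d potential cases (code set %s)",
    nrow(cohort), nrow(cases), registry$version))
  invisible(cases)
}

#' Adjudicate stage: rule engine over abstraction records
#'
#' Joins abstractions to screened cases by `child_id` + `event_date`,
#' adjudicates reviewer 1 deterministically from the abstraction, and —
#' when a reviewer-2 label column is present — applies the consensus rule
#' with the engine's own group as committee label for disagreements.
#'
#' @param out_dir Directory holding `potential_cases.csv` and
#'   `abstractions.csv`; receives `adjudications.csv`.
#' @return The adjudication data frame, invisibly.
#' @export
stage_adjudicate <- function(out_dir) {
  cases <- read_stage_csv(file.path(out_dir, "potential_cases.csv"),
                          date_cols = c("event_date", "fill_date",
                                        "supply_end", "early_cutoff",
                                        "window_end"))
  ab <- read_stage_csv(file.path(out_dir, "abstractions.csv"),
                       date_cols = "event_date")
  m <- match(paste(cases$child_id, cases$event_date),
             paste(ab$child_id, ab$event_date))
  matched <- !is.na(m)
  ab_m <- ab[m[matched], , drop = FALSE]
  ab_m$case_id <- cases$case_id[matched]
  adj <- adjudicate_cases(ab_m)
  if ("group_r2" %in% names(ab_m)) {
    cons <- consensus(adj$group, ab_m$group_r2, committee = adj$group)
    adj$group_r1 <- adj$group
    adj$group_r2 <- ab_m$group_r2
    adj$disagreement <- cons$disagreement
    adj$group <- cons$final_group
  }
  if ("record_status" %in% names(ab_m)) adj$record_status <- ab_m$record_status
  write_stage_csv(adj, file.path(out_dir, "adjudications.csv"))
  log_line(out_dir, sprintf(
    "adjudicate: %d of %d cases had abstraction records; %d confirmed",
    sum(matched), nrow(cases), sum(adj$group %in% ADJ_GROUPS[1:2])))
  invisible(adj)
}

#' Validate stage: assemble the validation report
#'
#' @param out_dir Directory holding `potential_cases.csv` and
#'   `adjudications.csv`; receives `validation_report.json` and
#'   `validation_report.txt`.
#' @param registry_version Version string stamped into the report.
#' @return The `validation_report`, invisibly.
#' @export
stage_validate <- function(out_dir, registry_version = NA_character_) {
  cases_path <- file.path(out_dir, "potential_cases.csv")
  adj_path <- file.path(out_dir, "adjudications.csv")
  for (p in c(cases_path, adj_path)) {
    if (!file.exists(p)) stop("missing stage artifact: ", p, call. = FALSE)
  }
  cases <- read_stage_csv(cases_path,
                          date_cols = c("event_date", "fill_date",
                                        "supply_end", "early_cutoff",
                                        "window_end"))
  adj <- read_stage_csv(adj_path, date_cols = character(0))
  if ("record_status" %in% names(adj) && nrow(cases)) {
    m <- match(cases$case_id, adj$case_id)
    cases$record_status <- ifelse(is.na(m), "not_found",
                                  adj$record_status[m])
  }
  raters <- NULL
  if (all(c("group_r1", "group_r2") %in% names(adj)) && nrow(adj)) {
    keep <- if ("record_status" %in% names(adj)) {
      adj$record_status == "adjudicable"
    } else rep(TRUE, nrow(adj))
    raters <- adj[keep, c("group_r1", "group_r2")]
  }
  report <- build_report(cases, adj, raters = raters,
                         registry_version = registry_version)
  write_report(report, file.path(out_dir, "validation_report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "validation_report.txt"))
  av <- report$availability
  log_line(out_dir, sprintf(
    "validate: screened %d -> no information %d, not found %d, adjudicable %d, confirmed %d",
    av$n_screened, av$n_no_information, av$n_not_found, av$n_adjudicable,
    report$overall$n_confirmed))
  invisible(report)
}

#' Run the whole pipeline on synthetic data
#'
#' simulate -> screen -> adjudicate -> validate, with every inter-stage
#' artifact written to `out_dir`, plus a timestamped log and a
#' `run_manifest.json` recording the seed and code-set version. Re-running
#' with the same parameters and seed reproduces identical artifacts.
#'
#' @param params A `sim_params`.
#' @param spec A `cohort_spec`; default covers the simulated study window.
#' @param registry A `codeset_registry`.
#' @param out_dir Output directory.
#' @return The final `validation_report`, invisibly.
#' @export
run_pipeline <- function(params, spec = NULL, registry = load_registry(),
                         out_dir) {
  if (is.null(spec)) {
    spec <- cohort_spec(params$study_start, params$study_end)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_simulate(params, out_dir, registry)
  stage_screen(out_dir, spec, registry, out_dir)
  stage_adjudicate(out_dir)
  report <- stage_validate(out_dir, registry_version = registry$version)
  manifest <- list(seed = params$rng_seed, n_children = params$n_children,
                   codeset_version = registry$version,
                   artifacts = c("potential_cases.csv", "adjudications.csv",
                                 "validation_report.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

write_stage_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stage_csv <- function(path, date_cols = character(0)) {
  if (!file.exists(path)) stop("missing stage artifact: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  for (col in intersect(date_cols, names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  df
}

log_line <- function(out_dir, msg) {
  path <- file.path(out_dir, "pipeline.log")
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", msg, "\n", sep = "",
      file = path, append = TRUE)
  invisible(path)
}
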