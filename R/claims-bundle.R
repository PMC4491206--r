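# Claims bundle: the five linked tables (children, enrollment, fills,
# encounters, deaths) for one study population, with validation and
# deterministic CSV round-trip I/O.

BUNDLE_TABLES <- c("children", "enrollment", "fills", "encounters", "deaths")

BUNDLE_SCHEMAS <- list(
  children   = c("child_id", "birth_date", "sex", "race"),
  enrollment = c("child_id", "start_date", "end_date"),
  fills      = c("child_id", "fill_date", "drug_class", "days_supply"),
  encounters = c("encounter_id", "child_id", "date", "setting",
                 "dx_codes", "ecodes"),
  deaths     = c("child_id", "death_date", "cause_codes")
)

#' Assemble and validate a claims bundle
#'
#' Binds the five claims tables into one validated object. Multi-code fields
#' (`dx_codes`, `ecodes`, `cause_codes`) are semicolon-joined strings of
#' ICD-9-CM codes, first diagnosis code primary. Dates are `Date`s (or
#' ISO-8601 strings, coerced).
#'
#' @param children,enrollment,fills,encounters,deaths Data frames with the
#'   documented columns (see README); missing arguments default to empty
#'   tables.
#' @param validate Run full invariant validation (default `TRUE`).
#' @return An object of class `claims_bundle` (a named list of the five
#'   data frames).
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
claims_bundle <- function(children = NULL, enrollment = NULL, fills = NULL,
                          encounters = NULL, deaths = NULL, validate = TRUE) {
  tabs <- list(children = children, enrollment = enrollment, fills = fills,
               encounters = encounters, deaths = deaths)
  for (nm in BUNDLE_TABLES) {
    tabs[[nm]] <- coerce_table(tabs[[nm]], nm)
  }
  bundle <- structure(tabs, class = "claims_bundle")
  if (validate) validate_bundle(bundle)
  bundle
}

empty_table <- function(name) {
  cols <- BUNDLE_SCHEMAS[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (col in intersect(c("birth_date", "start_date", "end_date", "fill_date",
                          "date", "death_date"), cols)) {
    df[[col]] <- as.Date(character(0))
  }
  if ("days_supply" %in% cols) df$days_supply <- integer(0)
  df
}

coerce_table <- function(df, name) {
  if (is.null(df)) return(empty_table(name))
  cols <- BUNDLE_SCHEMAS[[name]]
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("table '", name, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, cols, drop = FALSE]
  for (col in intersect(c("birth_date", "start_date", "end_date", "fill_date",
                          "date", "death_date"), cols)) {
    df[[col]] <- parse_bundle_date(df[[col]], name, col)
  }
  if ("days_supply" %in% cols) df$days_supply <- as.integer(df$days_supply)
  for (col in setdiff(cols, c(names(df)[vapply(df, inherits, TRUE,
                                               what = "Date")],
                              "days_supply"))) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in intersect(c("dx_codes", "ecodes", "cause_codes"), cols)) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  rownames(df) <- NULL
  df
}

parse_bundle_date <- function(x, table, col) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & as.character(x) != "")
  if (length(bad)) {
    stop("table '", table, "', column '", col, "': unparseable date at row ",
         bad[1], " ('", as.character(x)[bad[1]], "')", call. = FALSE)
  }
  out
}

split_codes <- function(x) {
  if (length(x) == 0L) return(list())
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) normalize_code(v[nzchar(v)]))
}

join_codes <- function(lst) vapply(lst, paste, character(1), collapse = ";")

#' Validate a claims bundle
#'
#' Checks the structural invariants: unique child ids; referential integrity
#' of every `child_id`; enrollment spans with `start_date <= end_date`;
#' `days_supply >= 1`; fills dated inside an enrollment span of the child;
#' encounters with a non-empty, normalizable diagnosis list and a known
#' setting; at most one death per child; all event dates on or after the
#' child's birth date.
#'
#' @param bundle A `claims_bundle`.
#' @return The bundle, invisibly; stops with an informative error on the
#'   first violated invariant.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  ch <- bundle$children
  dup <- ch$child_id[duplicated(ch$child_id)]
  if (length(dup)) {
    stop("duplicate child_id in children: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(ch$sex), c("F", "M", "unknown"))
  if (length(bad_sex)) {
    stop("children: sex must be F, M or unknown; saw: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  for (nm in setdiff(BUNDLE_TABLES, "children")) {
    unknown <- setdiff(unique(bundle[[nm]]$child_id), ch$child_id)
    if (length(unknown)) {
      stop("table '", nm, "' references unknown child_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  en <- bundle$enrollment
  if (nrow(en) && any(en$start_date > en$end_date)) {
    stop("enrollment: start_date after end_date for child(ren) ",
         paste(unique(en$child_id[en$start_date > en$end_date]),
               collapse = ", "), call. = FALSE)
  }
  fl <- bundle$fills
  if (nrow(fl)) {
    if (any(is.na(fl$days_supply) | fl$days_supply < 1L)) {
      stop("fills: days_supply must be >= 1", call. = FALSE)
    }
    bad_class <- setdiff(unique(fl$drug_class), c("opioid", "other"))
    if (length(bad_class)) {
      stop("fills: drug_class must be opioid/other; saw: ",
           paste(bad_class, collapse = ", "), call. = FALSE)
    }
    uncovered <- !fill_in_enrollment(fl, en)
    if (any(uncovered)) {
      stop("fills: fill_date outside all enrollment spans for child(ren) ",
           paste(unique(fl$child_id[uncovered]), collapse = ", "),
           call. = FALSE)
    }
  }
  enc <- bundle$encounters
  if (nrow(enc)) {
    if (anyDuplicated(enc$encounter_id)) {
      stop("encounters: duplicate encounter_id", call. = FALSE)
    }
    bad_setting <- setdiff(unique(enc$setting),
                           c("emergency", "inpatient", "outpatient"))
    if (length(bad_setting)) {
      stop("encounters: setting must be emergency/inpatient/outpatient; saw: ",
           paste(bad_setting, collapse = ", "), call. = FALSE)
    }
    dx <- split_codes(enc$dx_codes)   # errors on unnormalizable codes
    split_codes(enc$ecodes)
    empty <- lengths(dx) == 0L
    if (any(empty)) {
      stop("encounters: empty dx_codes for encounter(s) ",
           paste(enc$encounter_id[empty], collapse = ", "), call. = FALSE)
    }
  }
  de <- bundle$deaths
  if (nrow(de)) {
    split_codes(de$cause_codes)
    if (anyDuplicated(de$child_id)) {
      stop("deaths: more than one death record for child(ren) ",
           paste(unique(de$child_id[duplicated(de$child_id)]), collapse = ", "),
           call. = FALSE)
    }
  }
  # birth date precedes all event dates
  bd <- setNames(ch$birth_date, ch$child_id)
  check_after_birth <- function(df, col, what) {
    if (!nrow(df)) return(invisible())
    bad <- df[[col]] < bd[df$child_id]
    if (any(bad, na.rm = TRUE)) {
      stop(what, " before birth_date for child(ren) ",
           paste(unique(df$child_id[which(bad)]), collapse = ", "),
           call. = FALSE)
    }
  }
  check_after_birth(en, "start_date", "enrollment start")
  check_after_birth(fl, "fill_date", "fill date")
  check_after_birth(enc, "date", "encounter date")
  check_after_birth(de, "death_date", "death date")
  invisible(bundle)
}

fill_in_enrollment <- function(fills, enrollment) {
  if (!nrow(fills)) return(logical(0))
  ok <- logical(nrow(fills))
  if (!nrow(enrollment)) return(ok)
  by_child <- split(seq_len(nrow(enrollment)), enrollment$child_id)
  for (i in seq_len(nrow(fills))) {
    idx <- by_child[[fills$child_id[i]]]
    if (is.null(idx)) next
    ok[i] <- any(enrollment$start_date[idx] <= fills$fill_date[i] &
                   fills$fill_date[i] <= enrollment$end_date[idx])
  }
  ok
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects `children.csv`, `enrollment.csv`, `fills.csv`, `encounters.csv`
#' and `deaths.csv` (comma-delimited, UTF-8, header row, ISO-8601 dates).
#'
#' @param directory Path containing the five files.
#' @return A validated `claims_bundle`.
#' @export
read_bundle <- function(directory) {
  tabs <- list()
  for (nm in BUNDLE_TABLES) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop("missing claims file: ", path, call. = FALSE)
    }
    tabs[[nm]] <- utils::read.csv(path, colClasses = "character",
                                  na.strings = character(0))
  }
  do.call(claims_bundle, tabs)
}

#' Write a claims bundle to a directory of CSV files
#'
#' Output is deterministic: fixed column order, rows sorted by `child_id`
#' then date (then encounter id), so writing the same bundle twice is
#' byte-identical and `read_bundle(write_bundle(b))` returns `b`.
#'
#' @param bundle A valid `claims_bundle`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  validate_bundle(bundle)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  sort_keys <- list(
    children   = c("child_id"),
    enrollment = c("child_id", "start_date"),
    fills      = c("child_id", "fill_date"),
    encounters = c("child_id", "date", "encounter_id"),
    deaths     = c("child_id")
  )
  for (nm in BUNDLE_TABLES) {
    df <- bundle[[nm]]
    if (nrow(df)) {
      df <- df[do.call(order, df[sort_keys[[nm]]]), , drop = FALSE]
    }
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    utils::write.csv(df, file.path(directory, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(directory)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in BUNDLE_TABLES) {
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
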