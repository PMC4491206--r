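# ICD-9-CM code patterns, groups and the screening-category registry.

SCREENING_CATEGORIES <- c(
  "intentional_overdose", "unintentional_overdose",
  "adverse_effect_therapeutic", "symptom_cns", "symptom_respiratory"
)

EXCLUSION_GROUPS <- c(
  "serious_illness", "transplant", "institutional_residence", "drug_abuse"
)

#' Normalize an ICD-9-CM code
#'
#' Canonical form used throughout the package: upper case, whitespace
#' stripped, decimal point removed (claims extracts are inconsistent about
#' dots). `"965.00"` becomes `"96500"`, `" e850.2 "` becomes `"E8502"`.
#'
#' @param raw Character vector of raw codes.
#' @return Character vector of normalized codes, same length as `raw`.
#'   Idempotent: normalizing a normalized code is a no-op.
#' @examples
#' normalize_code(c("965.00", " e850.2 "))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  x <- toupper(gsub("[[:space:]]", "", raw))
  x <- gsub(".", "", x, fixed = TRUE)
  bad <- is.na(x) | x == "" | grepl("[^0-9EV]", x)
  if (any(bad)) {
    stop("cannot normalize ICD-9 code(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Create a code group
#'
#' A named list of ICD-9-CM patterns. Patterns match normalized codes by
#' prefix (the default, since ICD-9 families are hierarchical) or exactly;
#' prefix a pattern with `"="` to request exact matching, e.g. `"=96500"`.
#'
#' @param label Group label (e.g. `"A"`, `"B"`, `"C"`, or an exclusion name).
#' @param patterns Character vector of patterns; may be empty (a group that
#'   never matches, e.g. an empty Group B).
#' @return An object of class `code_group`.
#' @export
code_group <- function(label, patterns = character(0)) {
  patterns <- as.character(patterns)
  exact <- startsWith(patterns, "=")
  stripped <- sub("^=", "", patterns)
  stripped <- if (length(stripped)) normalize_code(stripped) else character(0)
  dup <- duplicated(paste0(ifelse(exact, "=", ""), stripped))
  if (any(dup)) {
    warning("duplicate pattern(s) in code group '", label, "': ",
            paste(unique(stripped[dup]), collapse = ", "),
            "; deduplicated", call. = FALSE)
  }
  structure(
    list(label = label, patterns = stripped[!dup], exact = exact[!dup]),
    class = "code_group"
  )
}

#' Match normalized codes against a code group
#'
#' @param codes Character vector of normalized ICD-9-CM codes.
#' @param group A `code_group`.
#' @return `TRUE` if any code matches any pattern of the group (exact
#'   equality or prefix containment, per pattern mode); `FALSE` otherwise,
#'   including for an empty group or empty code vector. Order-independent.
#' @export
match_code <- function(codes, group) {
  stopifnot(inherits(group, "code_group"))
  if (length(codes) == 0L || length(group$patterns) == 0L) return(FALSE)
  for (i in seq_along(group$patterns)) {
    p <- group$patterns[i]
    hit <- if (group$exact[i]) any(codes == p) else any(startsWith(codes, p))
    if (hit) return(TRUE)
  }
  FALSE
}

#' Load a screening code-set registry from a YAML configuration
#'
#' The registry holds, for each of the five screening categories, the code
#' groups the classifier consults: the two overdose categories and the
#' therapeutic-adverse-effect category carry external-cause/poisoning groups
#' A (opioid or unspecified analgesic), B (specific non-opioid drug) and C
#' (unspecified medication); the two symptom categories carry diagnosis-code
#' patterns only. An `exclusions` section names the cohort-exclusion groups
#' (serious illness, transplant, institutional residence, drug abuse).
#'
#' The bundled default (`system.file("extdata", "codesets.yaml",
#' package = "opitox")`) is a reconstruction from standard ICD-9-CM families
#' (opiate poisoning 965.0x; E850/E858/E980 accidental and undetermined
#' poisoning; E950 self-inflicted; E935/E947 adverse effects in therapeutic
#' use; altered-consciousness and respiratory-failure symptom families); it
#' is a usable, documented default, not an authoritative published list, and
#' is versioned so downstream reports record which registry produced them.
#'
#' @param config Path to a YAML file; default the bundled registry.
#' @return An object of class `codeset_registry`: `version` string,
#'   `categories` (named list; overdose/adverse categories have `$A`, `$B`,
#'   `$C` code groups, symptom categories a single `$dx` group) and
#'   `exclusions` (named list of code groups).
#' @export
load_registry <- function(config = default_codeset_path()) {
  if (!file.exists(config)) {
    stop("code-set config not found: ", config, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg$version)) stop("code-set config lacks a 'version' tag", call. = FALSE)
  if (is.null(cfg$categories)) stop("code-set config lacks 'categories'", call. = FALSE)
  missing <- setdiff(SCREENING_CATEGORIES, names(cfg$categories))
  if (length(missing)) {
    stop("code-set config missing categor",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  abc_cats <- c("intentional_overdose", "unintentional_overdose",
                "adverse_effect_therapeutic")
  categories <- list()
  for (cat in SCREENING_CATEGORIES) {
    entry <- cfg$categories[[cat]]
    if (cat %in% abc_cats) {
      if (is.null(entry$A) || length(entry$A) == 0L) {
        stop("category '", cat, "': group A must be non-empty", call. = FALSE)
      }
      categories[[cat]] <- list(
        A = code_group("A", unlist(entry$A)),
        B = code_group("B", unlist(entry$B)),
        C = code_group("C", unlist(entry$C))
      )
    } else {
      pats <- unlist(entry$dx %||% entry)
      if (length(pats) == 0L) {
        stop("category '", cat, "': diagnosis pattern list must be non-empty",
             call. = FALSE)
      }
      categories[[cat]] <- list(dx = code_group("dx", pats))
    }
  }
  exclusions <- list()
  for (ex in names(cfg$exclusions %||% list())) {
    exclusions[[ex]] <- code_group(ex, unlist(cfg$exclusions[[ex]]))
  }
  structure(
    list(version = as.character(cfg$version), categories = categories,
         exclusions = exclusions),
    class = "codeset_registry"
  )
}

#' Path to the bundled default code-set configuration
#' @return File path of the packaged `codesets.yaml`.
#' @export
default_codeset_path <- function() {
  system.file("extdata", "codesets.yaml", package = "opitox", mustWork = TRUE)
}

#' @export
print.codeset_registry <- function(x, ...) {
  cat("<codeset_registry> version", x$version, "\n")
  for (cat_ in names(x$categories)) {
    groups <- x$categories[[cat_]]
    n <- vapply(groups, function(g) length(g$patterns), integer(1))
    cat("  ", cat_, ": ", paste(names(n), n, sep = "=", collapse = " "), "\n",
        sep = "")
  }
  if (length(x$exclusions)) {
    cat("  exclusions:", paste(names(x$exclusions), collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
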