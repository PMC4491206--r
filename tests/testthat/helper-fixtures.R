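# Shared fixtures and small independent oracles used across the test files.

default_registry <- load_registry()

# Canonical row order used by write_bundle, for bundle equality checks.
sort_bundle <- function(b) {
  keys <- list(children = "child_id", enrollment = c("child_id", "start_date"),
               fills = c("child_id", "fill_date"),
               encounters = c("child_id", "date", "encounter_id"),
               deaths = "child_id")
  for (nm in names(keys)) {
    df <- b[[nm]]
    if (nrow(df)) df <- df[do.call(order, df[keys[[nm]]]), , drop = FALSE]
    rownames(df) <- NULL
    b[[nm]] <- df
  }
  b
}

# A small hand-built valid bundle: two children, opioid fills, one
# in-window poisoning encounter, one death.
tiny_bundle <- function() {
  claims_bundle(
    children = data.frame(
      child_id = c("A1", "A2"), birth_date = as.Date(c("1998-05-01", "2001-02-10")),
      sex = c("F", "M"), race = c("Caucasian", "other")),
    enrollment = data.frame(
      child_id = c("A1", "A2"),
      start_date = as.Date(c("2004-01-01", "2004-01-01")),
      end_date = as.Date(c("2008-12-31", "2008-12-31"))),
    fills = data.frame(
      child_id = c("A1", "A1", "A2"),
      fill_date = as.Date(c("2005-03-01", "2005-06-01", "2006-02-01")),
      drug_class = c("opioid", "opioid", "opioid"),
      days_supply = c(7L, 10L, 5L)),
    encounters = data.frame(
      encounter_id = c("E1", "E2"),
      child_id = c("A1", "A2"),
      date = as.Date(c("2005-03-05", "2006-02-03")),
      setting = c("emergency", "inpatient"),
      dx_codes = c("78900;96500", "78001"),
      ecodes = c("E8502", "")),
    deaths = data.frame(
      child_id = "A2", death_date = as.Date("2006-02-10"),
      cause_codes = ""))
}

# Random valid bundles for round-trip property tests.
random_bundle <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  ids <- sprintf("R%02d", seq_len(n))
  birth <- as.Date("1999-01-01") + sample(0:2000, n, replace = TRUE)
  first_fill <- birth + 365 * 3 + sample(0:1000, n, replace = TRUE)
  children <- data.frame(child_id = ids, birth_date = birth,
                         sex = sample(c("F", "M", "unknown"), n, TRUE),
                         race = sample(c("Caucasian", "other"), n, TRUE))
  enrollment <- data.frame(child_id = ids, start_date = first_fill - 500,
                           end_date = first_fill + 500)
  nf <- sample(0:3, n, replace = TRUE)
  ci <- rep(seq_len(n), nf)
  fills <- data.frame(
    child_id = ids[ci],
    fill_date = first_fill[ci] + sample(0:400, length(ci), TRUE),
    drug_class = sample(c("opioid", "other"), length(ci), TRUE,
                        prob = c(.8, .2)),
    days_supply = sample(1:30, length(ci), TRUE))
  ne <- sample(0:3, n, replace = TRUE)
  ei <- rep(seq_len(n), ne)
  encounters <- if (length(ei)) data.frame(
    encounter_id = sprintf("EN%03d", seq_along(ei)),
    child_id = ids[ei],
    date = first_fill[ei] + sample(-100:100, length(ei), TRUE),
    setting = sample(c("emergency", "inpatient", "outpatient"),
                     length(ei), TRUE),
    dx_codes = sample(c("78900", "96500;E8502", "4660;78001"),
                      length(ei), TRUE),
    ecodes = sample(c("", "E9352"), length(ei), TRUE)) else NULL
  deaths <- if (runif(1) < .4) data.frame(
    child_id = ids[1], death_date = first_fill[1] + 450,
    cause_codes = sample(c("", "96500"), 1)) else NULL
  claims_bundle(children, enrollment, fills, encounters, deaths)
}

# Independent scenario-by-scenario oracle for the adjudication groups,
# written as the prose decision list rather than boolean algebra.
adjudicate_oracle <- function(a) {
  if (a$escalation_for_opioid_toxicity) return("group1_definite_probable")
  if (a$signs_symptoms_compatible &&
      a$physician_attributed_to_opioid &&
      !a$other_cause_implicated) return("group1_definite_probable")
  if (a$signs_symptoms_compatible && !a$physician_attributed_to_opioid) {
    if (!a$other_cause_attributed && a$temporal_sequence_consistent) {
      return("group2_possible")
    }
  }
  "group3_excluded"
}

# All combinations of the six adjudication decision flags.
adjudication_grid <- function() {
  flags <- c("signs_symptoms_compatible", "physician_attributed_to_opioid",
             "other_cause_implicated", "other_cause_attributed",
             "escalation_for_opioid_toxicity", "temporal_sequence_consistent")
  g <- expand.grid(rep(list(c(FALSE, TRUE)), length(flags)))
  names(g) <- flags
  g
}
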