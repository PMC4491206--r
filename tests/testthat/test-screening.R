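test_that("risk-window arithmetic: fill day is supply day 1, 14 days of follow-up", {
  w <- build_windows(data.frame(child_id = "A", fill_date = as.Date("2005-03-01"),
                                days_supply = 1L))
  expect_equal(w$supply_end, as.Date("2005-03-01"))
  expect_equal(w$window_end, as.Date("2005-03-15"))
  w10 <- build_windows(data.frame(child_id = "A",
                                  fill_date = as.Date("2005-03-01"),
                                  days_supply = 10L))
  expect_equal(w10$supply_end, as.Date("2005-03-10"))
  expect_equal(w10$early_cutoff, as.Date("2005-03-17"))
  expect_equal(w10$window_end, as.Date("2005-03-24"))
  # overlapping fills keep both windows, no merging
  two <- build_windows(data.frame(child_id = "A",
                                  fill_date = as.Date(c("2005-03-01", "2005-03-05")),
                                  days_supply = c(10L, 10L)))
  expect_equal(nrow(two), 2L)
  expect_error(build_windows(data.frame(child_id = "A",
                                        fill_date = as.Date("2005-03-01"),
                                        days_supply = 0L)),
               "days_supply")
})

test_that("single-trigger encounters classify into their category", {
  cls <- classify_encounter("96500", character(0), "emergency",
                            default_registry)
  expect_equal(cls$category, "unintentional_overdose")
  expect_equal(classify_encounter("78900", "E9500", "inpatient",
                                  default_registry)$category,
               "intentional_overdose")
  expect_equal(classify_encounter("78900", "E9352", "emergency",
                                  default_registry)$category,
               "adverse_effect_therapeutic")
  sym <- classify_encounter(c("78001", "51881"), character(0), "emergency",
                            default_registry)
  expect_equal(sym$category, "symptom_only")
  expect_equal(sym$subtype, "both")
  expect_null(classify_encounter("4660", character(0), "emergency",
                                 default_registry))
  expect_error(classify_encounter("96500", character(0), "outpatient",
                                  default_registry),
               "outpatient")
})

test_that("an unspecified-medication code is vetoed by a specific non-opioid drug code", {
  # Group C (unspecified drug, accidental) alone triggers
  expect_equal(classify_encounter("78900", "E8589", "emergency",
                                  default_registry)$category,
               "unintentional_overdose")
  # ... but not in the presence of a Group B specific non-opioid (salicylate)
  expect_null(classify_encounter(c("78900", "9651"), "E8589", "emergency",
                                 default_registry))
  # a coded opioid is never vetoed under the default scope
  expect_equal(classify_encounter(c("96500", "9651"), character(0),
                                  "emergency", default_registry)$category,
               "unintentional_overdose")
  # ... and is vetoed when the veto scope is widened to A and C
  expect_null(classify_encounter(c("96500", "9651"), character(0),
                                 "emergency", default_registry,
                                 b_veto = "AC"))
})

test_that("classification agrees with a brute-force precedence oracle over all trigger subsets", {
  trigger_codes <- list(
    int_A = list(dx = NULL, e = "E9500"),
    int_C = list(dx = NULL, e = "E9505"),
    unint_A = list(dx = "96500", e = NULL),
    unint_C = list(dx = NULL, e = "E9805"),
    adv_A = list(dx = NULL, e = "E9359"),
    adv_C = list(dx = NULL, e = "E9479"),
    b_poison = list(dx = "9611", e = NULL),   # Group B of both overdose categories
    adv_B = list(dx = NULL, e = "E9320"),     # Group B of the adverse-effect category
    cns = list(dx = "78001", e = NULL),
    resp = list(dx = "51881", e = NULL))
  bits <- expand.grid(rep(list(c(FALSE, TRUE)), length(trigger_codes)))
  names(bits) <- names(trigger_codes)

  oracle <- function(z, veto) {
    fired <- function(a, c, b) if (veto == "AC") (a || c) && !b else a || (c && !b)
    if (fired(z$int_A, z$int_C, z$b_poison)) return("intentional_overdose")
    if (fired(z$unint_A, z$unint_C, z$b_poison)) return("unintentional_overdose")
    if (fired(z$adv_A, z$adv_C, z$adv_B)) return("adverse_effect_therapeutic")
    if (z$cns || z$resp) return("symptom_only")
    NA_character_
  }
  for (veto in c("C", "AC")) {
    for (i in seq_len(nrow(bits))) {
      z <- bits[i, ]
      on <- names(trigger_codes)[unlist(z)]
      dx <- c("78900", unlist(lapply(trigger_codes[on], `[[`, "dx")))
      ec <- unlist(lapply(trigger_codes[on], `[[`, "e"))
      got <- classify_encounter(dx, ec %||% character(0), "emergency",
                                default_registry, b_veto = veto)
      want <- oracle(z, veto)
      if (is.na(want)) expect_null(got) else expect_equal(got$category, want)
    }
  }
})

test_that("screening honors windows, deduplicates, and reviews in-window deaths", {
  b <- tiny_bundle()
  spec <- cohort_spec("2005-01-01", "2006-12-31")
  cohort <- build_cohort(b, spec, default_registry)
  cases <- screen(cohort, b, default_registry)
  # A1: poisoning encounter inside the March window; A2: symptom encounter
  # plus an in-window death on a later date
  expect_equal(sort(cases$child_id), c("A1", "A2", "A2"))
  a1 <- cases[cases$child_id == "A1", ]
  expect_equal(a1$category, "unintentional_overdose")
  expect_equal(a1$time_stratum, "early")
  a2 <- cases[cases$child_id == "A2", ]
  expect_setequal(a2$category, c("symptom_only", "death_any_cause"))
  death <- a2[a2$category == "death_any_cause", ]
  expect_true(is.na(death$encounter_id))
  expect_equal(death$time_stratum, "early")  # death on supply day 5 + 5

  # an encounter the day before the fill is no case
  before <- unclass(b)
  before$encounters$date[1] <- as.Date("2005-02-28")
  b2 <- claims_bundle(before$children, before$enrollment, before$fills,
                      before$encounters, before$deaths)
  cases2 <- screen(build_cohort(b2, spec, default_registry), b2,
                   default_registry)
  expect_false("A1" %in% cases2$child_id)
})

test_that("an event in two overlapping windows is attributed to the most recent fill", {
  fill <- as.Date(c("2005-03-01", "2005-03-08"))
  b <- claims_bundle(
    children = data.frame(child_id = "O1", birth_date = as.Date("1997-01-01"),
                          sex = "F", race = "other"),
    enrollment = data.frame(child_id = "O1", start_date = as.Date("2004-01-01"),
                            end_date = as.Date("2005-12-31")),
    fills = data.frame(child_id = "O1", fill_date = fill,
                       drug_class = "opioid", days_supply = c(14L, 14L)),
    encounters = data.frame(encounter_id = "E1", child_id = "O1",
                            date = as.Date("2005-03-10"), setting = "emergency",
                            dx_codes = "96500", ecodes = ""))
  spec <- cohort_spec("2005-01-01", "2005-12-31")
  cases <- screen(build_cohort(b, spec, default_registry), b, default_registry)
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$fill_date, as.Date("2005-03-08"))
  expect_equal(cases$time_stratum, "early")
})

test_that("every case carries exactly one category and stratum; removing fills never adds cases", {
  p <- sim_params(n_children = 400, rng_seed = 17,
                  case_rates = c(intentional_overdose = .03,
                                 unintentional_overdose = .03,
                                 adverse_effect_therapeutic = .03,
                                 symptom_cns = .02, symptom_respiratory = .01,
                                 death_any_cause = .003))
  sim <- generate_claims(p, default_registry)
  spec <- cohort_spec(p$study_start, p$study_end)
  cohort <- build_cohort(sim$bundle, spec, default_registry)
  cases <- screen(cohort, sim$bundle, default_registry)
  expect_gt(nrow(cases), 20)
  expect_true(all(cases$category %in%
                    c("intentional_overdose", "unintentional_overdose",
                      "adverse_effect_therapeutic", "symptom_only",
                      "death_any_cause")))
  expect_true(all(cases$time_stratum %in% c("early", "late")))
  expect_equal(anyDuplicated(cases[c("child_id", "event_date")]), 0L)
  expect_true(all(is.na(cases$symptom_subtype) ==
                    (cases$category != "symptom_only")))
  # category and stratum counts partition the total
  expect_equal(sum(table(cases$category)), nrow(cases))
  expect_equal(sum(table(cases$time_stratum)), nrow(cases))

  set.seed(1)
  sub <- cohort[sample(nrow(cohort), floor(nrow(cohort) * 0.6)), ]
  cases_sub <- screen(sub, sim$bundle, default_registry)
  key <- function(df) paste(df$child_id, df$event_date)
  expect_true(all(key(cases_sub) %in% key(cases)))
})
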