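test_that("age_at counts completed, birthday-based years", {
  b <- as.Date("2000-06-15")
  expect_equal(age_at(b, as.Date("2010-06-14")), 9L)
  expect_equal(age_at(b, as.Date("2010-06-15")), 10L)
  expect_equal(age_at(b, b), 0L)
  expect_error(age_at(b, as.Date("1999-01-01")), "precedes")
  # leap-day birth: anniversary taken as Mar 1 in common years
  expect_equal(age_at(as.Date("2004-02-29"), as.Date("2010-02-28")), 5L)
  expect_equal(age_at(as.Date("2004-02-29"), as.Date("2010-03-01")), 6L)
})

# One child, one opioid fill, with an exclusion-code encounter placed at a
# controlled distance before the fill.
lookback_bundle <- function(gap_days, code = "2826") {
  fill <- as.Date("2007-06-01")
  claims_bundle(
    children = data.frame(child_id = "L1", birth_date = as.Date("1999-01-01"),
                          sex = "F", race = "other"),
    enrollment = data.frame(child_id = "L1",
                            start_date = fill - 600, end_date = fill + 100),
    fills = data.frame(child_id = "L1", fill_date = fill,
                       drug_class = "opioid", days_supply = 5L),
    encounters = data.frame(encounter_id = "E1", child_id = "L1",
                            date = fill - gap_days, setting = "outpatient",
                            dx_codes = code, ecodes = ""))
}

test_that("history exclusions respect the 12-month lookback boundary", {
  spec <- cohort_spec("2007-01-01", "2007-12-31")
  inside <- build_cohort(lookback_bundle(200), spec, default_registry)
  expect_equal(nrow(inside), 0L)
  expect_equal(attr(inside, "exclusion_counts")[["serious_illness"]], 1L)
  outside <- build_cohort(lookback_bundle(400), spec, default_registry)
  expect_equal(nrow(outside), 1L)
  # lookback_days = 0 disables history exclusions entirely
  spec0 <- cohort_spec("2007-01-01", "2007-12-31", lookback_days = 0)
  expect_equal(nrow(build_cohort(lookback_bundle(10), spec0,
                                 default_registry)), 1L)
})

test_that("each exclusion reason triggers from its configured code group", {
  spec <- cohort_spec("2007-01-01", "2007-12-31")
  for (case in list(c("V420", "transplant"),
                    c("V606", "institutional_residence"),
                    c("30400", "drug_abuse"),
                    c("1629", "serious_illness"))) {
    ch <- build_cohort(lookback_bundle(100, code = case[1]), spec,
                       default_registry)
    expect_equal(nrow(ch), 0L)
    expect_equal(attr(ch, "exclusion_counts")[[case[2]]], 1L)
  }
  # naloxone receipt and benign diagnoses are no-ops
  expect_equal(nrow(build_cohort(lookback_bundle(100, code = "4660"), spec,
                                 default_registry)), 1L)
})

test_that("age bounds are inclusive at 2 and 17, evaluated on the fill date", {
  fill <- as.Date("2007-06-01")
  mk <- function(birth) claims_bundle(
    children = data.frame(child_id = "K", birth_date = as.Date(birth),
                          sex = "M", race = "other"),
    enrollment = data.frame(child_id = "K",
                            start_date = max(as.Date(birth), fill - 600),
                            end_date = fill + 100),
    fills = data.frame(child_id = "K", fill_date = fill,
                       drug_class = "opioid", days_supply = 3L))
  spec <- cohort_spec("2007-01-01", "2007-12-31")
  expect_equal(nrow(build_cohort(mk("2006-01-01"), spec, default_registry)), 0L)  # age 1
  expect_equal(nrow(build_cohort(mk("2005-06-01"), spec, default_registry)), 1L)  # age 2
  expect_equal(nrow(build_cohort(mk("1989-08-01"), spec, default_registry)), 1L)  # age 17
  expect_equal(nrow(build_cohort(mk("1989-05-01"), spec, default_registry)), 0L)  # age 18
})

test_that("non-opioid fills and fills outside the study window are dropped", {
  b <- tiny_bundle()
  spec <- cohort_spec("2005-01-01", "2005-12-31")
  ch <- build_cohort(b, spec, default_registry)
  expect_equal(nrow(ch), 2L)             # A2's 2006 fill is outside the window
  expect_setequal(unique(ch$child_id), "A1")
})

test_that("enlarging the exclusion code set never enlarges the cohort,
           and output is independent of input row order", {
  p <- sim_params(n_children = 150, rng_seed = 91, p_excluded_child = 0.2,
                  case_rates = c(intentional_overdose = .02,
                                 unintentional_overdose = .02,
                                 adverse_effect_therapeutic = .02,
                                 symptom_cns = .02, symptom_respiratory = .01,
                                 death_any_cause = .002))
  sim <- generate_claims(p, default_registry)
  spec <- cohort_spec(p$study_start, p$study_end)
  base <- build_cohort(sim$bundle, spec, default_registry)
  bigger <- default_registry
  bigger$exclusions$everything <- code_group("everything", c("7", "E", "V", "4", "5", "9"))
  smaller_cohort <- build_cohort(sim$bundle, spec, bigger)
  expect_lte(nrow(smaller_cohort), nrow(base))
  key <- function(df) sort(paste(df$child_id, df$fill_date))
  expect_true(all(key(smaller_cohort) %in% key(base)))

  shuf <- unclass(sim$bundle)
  set.seed(5)
  for (nm in names(shuf)) {
    shuf[[nm]] <- shuf[[nm]][sample(nrow(shuf[[nm]])), , drop = FALSE]
  }
  b2 <- claims_bundle(shuf$children, shuf$enrollment, shuf$fills,
                      shuf$encounters, shuf$deaths)
  perm <- build_cohort(b2, spec, default_registry)
  expect_equal(perm, base, ignore_attr = TRUE)
})
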