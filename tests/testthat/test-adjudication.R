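test_that("adjudication matches the scenario oracle on the full truth table and partitions it", {
  g <- adjudication_grid()
  got <- adjudicate(g)
  want <- vapply(seq_len(nrow(g)), function(i) adjudicate_oracle(g[i, ]),
                 character(1))
  expect_identical(got, want)
  expect_true(all(got %in% c("group1_definite_probable", "group2_possible",
                             "group3_excluded")))
  # monotone in the confirmatory direction: forcing the escalation arm never
  # moves a case out of Group 1
  esc <- g
  esc$escalation_for_opioid_toxicity <- TRUE
  was_g1 <- got == "group1_definite_probable"
  expect_true(all(adjudicate(esc)[was_g1] == "group1_definite_probable"))
})

test_that("the worked adjudication scenarios come out as documented", {
  expect_equal(adjudicate(chart_abstraction()), "group3_excluded")
  expect_equal(adjudicate(chart_abstraction(escalation_for_opioid_toxicity = TRUE)),
               "group1_definite_probable")
  # compatible vomiting attributed to gastroenteritis by the treating physician
  expect_equal(adjudicate(chart_abstraction(signs_symptoms_compatible = TRUE,
                                            other_cause_attributed = TRUE)),
               "group3_excluded")
  # compatible signs, no attribution either way, temporal sequence inconsistent
  expect_equal(adjudicate(chart_abstraction(signs_symptoms_compatible = TRUE,
                                            temporal_sequence_consistent = FALSE)),
               "group3_excluded")
  expect_equal(adjudicate(chart_abstraction(signs_symptoms_compatible = TRUE,
                                            temporal_sequence_consistent = TRUE)),
               "group2_possible")
})

test_that("severity is total on confirmed cases with strict dominance", {
  expect_equal(classify_severity(chart_abstraction(death = TRUE,
                                                   hospitalization_or_escalation = TRUE),
                                 "group1_definite_probable"), "death")
  expect_equal(classify_severity(chart_abstraction(hospitalization_or_escalation = TRUE,
                                                   ed_primary_reason = TRUE),
                                 "group1_definite_probable"), "high")
  expect_equal(classify_severity(chart_abstraction(ed_primary_reason = TRUE),
                                 "group2_possible"), "intermediate")
  expect_equal(classify_severity(chart_abstraction(incidental_mention = TRUE),
                                 "group2_possible"), "low")
  expect_equal(classify_severity(chart_abstraction(), "group2_possible"), "low")
  expect_error(classify_severity(chart_abstraction(), "group3_excluded"),
               "Group 1/2")
  # exhaustively: severity defined for every flag combination
  flags <- expand.grid(death = c(FALSE, TRUE),
                       hospitalization_or_escalation = c(FALSE, TRUE),
                       ed_primary_reason = c(FALSE, TRUE),
                       incidental_mention = c(FALSE, TRUE))
  sev <- classify_severity(flags, rep("group1_definite_probable", nrow(flags)))
  expect_true(all(sev %in% c("death", "high", "intermediate", "low")))
  expect_true(all(sev[flags$death] == "death"))
  expect_true(all(sev[!flags$death & flags$hospitalization_or_escalation] == "high"))
})

test_that("exposure labels pass through unchanged and unknown labels error", {
  e <- classify_exposure(chart_abstraction(intent_evidence = "therapeutic",
                                           source_evidence = "own_prescription"))
  expect_equal(e$intent, "therapeutic")
  expect_equal(e$source, "own_prescription")
  expect_equal(classify_exposure(chart_abstraction())$intent, "unspecified")
  expect_equal(classify_exposure(
    chart_abstraction(source_evidence = "illegal"))$source, "illegal")
  expect_error(classify_exposure(chart_abstraction(intent_evidence = "accident")),
               "intent")
  expect_error(chart_abstraction(sign_compatible = TRUE), "unknown")
})

test_that("consensus keeps agreements, defers disagreements to the committee", {
  both <- consensus(rep("group2_possible", 2), rep("group2_possible", 2))
  expect_false(any(both$disagreement))
  expect_equal(both$final_group, rep("group2_possible", 2))
  split <- consensus("group2_possible", "group3_excluded",
                     committee = "group3_excluded")
  expect_true(split$disagreement)
  expect_equal(split$final_group, "group3_excluded")
  expect_error(consensus("group1_definite_probable", "group3_excluded"),
               "committee")
  expect_error(consensus("group1_definite_probable", "groupX"), "unknown")
})
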