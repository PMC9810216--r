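test_that("the scenario enumeration reproduces the study design table", {
  sc <- enumerate_scenarios()
  expect_length(sc, 49)
  labels <- vapply(sc, function(s) s$label, character(1))
  expect_false(any(duplicated(labels)))
  expect_true(all(c("U50 | C@65", "U70 | C@75", "f60 | U", "F70 | U",
                    "C60 | F18m", "C70 | F9m", "f60 | F3m") %in% labels))
  # no switch-to-FIT rows for the FIT cohorts, no discontinuation for the
  # unscreened, no long-term delay for the FIT cohorts
  kinds <- vapply(sc, function(s) s$disruption$kind, character(1))
  cohorts <- vapply(sc, function(s) s$cohort$label, character(1))
  expect_false(any(kinds == "switch_to_fit" &
                     cohorts %in% c("F60", "F70", "f60")))
  expect_false(any(kinds == "discontinue" &
                     cohorts %in% c("U50", "U60", "U70")))
  i <- which(labels == "U50 | C@65")
  expect_equal(sc[[i]]$disruption$resume_ages, c(65, 75))
  i <- which(labels == "C70 | C@75")
  expect_equal(sc[[i]]$disruption$resume_ages, 75)
})

test_that("the printed scenario listing matches its golden file", {
  got <- capture.output(list_scenarios())
  want <- readLines(test_path("scenarios-golden.txt"))
  expect_identical(got, want)
})

test_that("counterfactual schedules match the cohort definitions", {
  expect_equal(counterfactual_schedule(cohort_spec("C70")),
               data.frame(age = 70, modality = "colonoscopy"))
  expect_equal(counterfactual_schedule(cohort_spec("U50"))$age,
               c(50, 60, 70))
  expect_equal(counterfactual_schedule(cohort_spec("F70"))$age, 70:75)
  expect_equal(counterfactual_schedule(cohort_spec("U60"))$age, c(60, 70))
  expect_equal(counterfactual_schedule(cohort_spec("U70"))$age, 70)
  f60 <- cohort_spec("f60")
  expect_equal(counterfactual_schedule(f60)$age, 60:75)  # annual after 60
  expect_equal(f60$pre_pandemic_exams$age, c(50, 52, 54, 56))
  expect_equal(cohort_spec("F60")$pre_pandemic_exams$age, 50:59)
  expect_equal(cohort_spec("C70")$pre_pandemic_exams$age, c(50, 60))
  expect_error(cohort_spec("X50"), "unknown cohort")
  expect_error(cohort_spec("F60", "colonoscopy"), "adherent")
})

test_that("disruptions transform the schedule as specified", {
  c60 <- cohort_spec("C60")
  d9 <- disrupted_schedule(c60, disruption_spec("delay_months", d = 9))
  expect_equal(d9$age, c(60.75, 70.75))  # carried forward past the stop age
  u70 <- cohort_spec("U70")
  long <- disrupted_schedule(u70, disruption_spec("long_delay",
                                                  resume_ages = 75))
  expect_equal(long, data.frame(age = 75, modality = "colonoscopy"))
  sw <- disrupted_schedule(c60, disruption_spec("switch_to_fit", d = 18))
  expect_equal(sw$age, seq(61.5, 74.5, by = 1))
  expect_true(all(sw$modality == "fit"))
  f60 <- cohort_spec("F60")
  expect_equal(nrow(disrupted_schedule(f60, disruption_spec("discontinue"))),
               0)
  expect_error(disruption_spec("delay_months", d = 6), "3, 9 or 18")
  expect_error(scenario_spec(f60, disruption_spec("switch_to_fit", d = 3)),
               "colonoscopy cohorts")
})

test_that("delayed schedules shift every exam by exactly d/12", {
  for (s in enumerate_scenarios()) {
    if (s$disruption$kind != "delay_months") next
    cf <- counterfactual_schedule(s$cohort)
    ds <- disrupted_schedule(s$cohort, s$disruption)
    expect_equal(ds$age, cf$age + s$disruption$d / 12)
    expect_identical(ds$modality, cf$modality)
  }
})

test_that("scenario labels round-trip through the parser", {
  for (s in enumerate_scenarios()) {
    p <- parse_label(s$label)
    expect_identical(p$label, s$label)
    expect_identical(p$disruption$kind, s$disruption$kind)
    expect_identical(p$disruption$d, s$disruption$d)
    expect_identical(p$disruption$resume_ages, s$disruption$resume_ages)
    expect_identical(p$cohort$label, s$cohort$label)
    expect_identical(p$cohort$counterfactual_modality,
                     s$cohort$counterfactual_modality)
  }
  expect_error(parse_label("Q60 | C3m"), "label")
})

test_that("schedules are pure functions of cohort and disruption", {
  s <- parse_label("C60 | F18m")
  a <- disrupted_schedule(s$cohort, s$disruption)
  b <- disrupted_schedule(s$cohort, s$disruption)
  expect_identical(a, b)
})
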