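test_that("certain detection removes every adenoma; zero leaves all", {
  params <- const_intensity_params(1e-300)
  nh <- synthetic_history(large_lesion_row(3), params, 1, 5)
  out <- perform_colonoscopy(nh, 60, perfect_chars("colonoscopy"))
  expect_equal(out$result$n_detected, 3)
  expect_setequal(out$result$detected_adenoma_ids, 1:3)
  expect_true(all(out$history$lesions$removed_age == 60))
  expect_identical(out$result$max_detected_size_class, "large")

  blind <- test_characteristics("colonoscopy", 0, 0, 0, 0, 1)
  out0 <- perform_colonoscopy(nh, 60, blind)
  expect_equal(out0$result$n_detected, 0)
  expect_true(all(is.na(out0$history$lesions$removed_age)))
})

test_that("multi-lesion detection matches the binomial closed form", {
  # two large adenomas, sens_large = 0.75: P(both detected) = 0.5625
  params <- const_intensity_params(1e-300)
  chars <- test_characteristics("colonoscopy", 0.75, 0.75, 0.75, 0.80, 1)
  n <- 1e5
  nh <- synthetic_history(large_lesion_row(2), params, 1, 77)
  both <- logical(n)
  for (i in seq_len(n)) {
    nh$stream$person_id <- i
    both[i] <- perform_colonoscopy(nh, 60, chars)$result$n_detected == 2
  }
  p <- 0.75^2
  expect_lt(abs(mean(both) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("FIT false-positive rate equals one minus specificity", {
  params <- const_intensity_params(1e-300)
  chars_fit <- test_characteristics("fit", 0.05, 0.10, 0.22, 0.74, 0.96)
  chars_col <- default_cfg$test_characteristics$high_sensitivity$colonoscopy
  n <- 1e5
  fp <- logical(n)
  cascaded <- logical(n)
  nh <- synthetic_history(large_lesion_row(0), params, 1, 31)
  for (i in seq_len(n)) {
    nh$stream$person_id <- i
    out <- perform_fit(nh, 60, chars_fit, chars_col)
    fp[i] <- out$result$false_positive
    cascaded[i] <- !is.null(out$colonoscopy)
  }
  expect_lt(abs(mean(fp) - 0.04), 3 * sqrt(0.04 * 0.96 / n))
  # every positive FIT cascades to exactly one diagnostic colonoscopy
  expect_identical(fp, cascaded)

  # perfect specificity: never positive on a lesion-free person
  perfect <- test_characteristics("fit", 0.05, 0.10, 0.22, 0.74, 1)
  nh <- synthetic_history(large_lesion_row(0), params, 1, 31)
  out <- perform_fit(nh, 60, perfect, chars_col)
  expect_false(out$result$positive)
  expect_null(out$colonoscopy)
})

test_that("a certain FIT-colonoscopy cascade diagnoses preclinical cancer", {
  params <- const_intensity_params(1e-300)
  les <- large_lesion_row(1)
  les$transition_age <- 58  # preclinical cancer from age 58
  les$sojourn <- 6
  nh <- synthetic_history(les, params, 1, 13)
  out <- perform_fit(nh, 60, perfect_chars("fit"),
                     perfect_chars("colonoscopy"))
  expect_true(out$result$positive)
  expect_true(out$colonoscopy$detected_preclinical_crc)
  expect_equal(out$history$screen_dx$age, 60)
  expect_equal(out$history$screen_dx$stage, 1L)  # helper's screen stage
})

test_that("surveillance intervals follow the findings decision table", {
  pol <- surveillance_policy(3, 5, 10, 80)
  res3 <- new_exam_result(60, "colonoscopy", 1:3, FALSE, c(3, 4, 5))
  expect_equal(next_surveillance_interval(res3, pol), 3)
  res_large <- new_exam_result(60, "colonoscopy", 1L, FALSE, 12)
  expect_equal(next_surveillance_interval(res_large, pol), 3)
  res1 <- new_exam_result(60, "colonoscopy", 1L, FALSE, 4)
  expect_equal(next_surveillance_interval(res1, pol), 5)
  res0 <- new_exam_result(60, "colonoscopy", integer(0), FALSE, numeric(0))
  expect_true(is.na(next_surveillance_interval(res0, pol)))
  fit_res <- new_exam_result(60, "fit", integer(0), FALSE, numeric(0))
  expect_error(next_surveillance_interval(fit_res, pol), "colonoscopy")
})

test_that("raising sensitivity never loses a detection (same draws)", {
  params <- default_cfg$natural_history$model_a
  hi <- default_cfg$test_characteristics$high_sensitivity$colonoscopy
  lo <- default_cfg$test_characteristics$low_sensitivity$colonoscopy
  n_checked <- 0
  for (i in 1:300) {
    nh <- sample_person(params, i, 555)
    aden <- nh$lesions$init_age <= 60 & nh$lesions$transition_age > 60
    if (!any(aden) || nh$other_cause_death_age <= 60) next
    dhi <- perform_colonoscopy(nh, 60, hi)$result$detected_adenoma_ids
    dlo <- perform_colonoscopy(nh, 60, lo)$result$detected_adenoma_ids
    expect_true(all(dlo %in% dhi))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("adenoma removal is permanent and cancels transformation", {
  params <- const_intensity_params(1e-300)
  les <- large_lesion_row(2)
  les$transition_age <- c(70, 1e6)  # lesion 1 would turn malignant at 70
  nh <- synthetic_history(les, params, 1, 5)
  out1 <- perform_colonoscopy(nh, 60, perfect_chars("colonoscopy"))
  expect_equal(out1$result$n_detected, 2)
  # a later exam must not re-detect the removed lesions
  out2 <- perform_colonoscopy(out1$history, 75, perfect_chars("colonoscopy"),
                              exam_ordinal = 2)
  expect_equal(out2$result$n_detected, 0)
  expect_false(out2$result$detected_preclinical_crc)
  # whole-replay view: polypectomy before transformation means no CRC ever
  rr <- replay_history(synthetic_history(les, params, 1, 5),
                       data.frame(age = c(60, 75),
                                  modality = "colonoscopy"),
                       perfect_chars("colonoscopy"), perfect_chars("fit"),
                       surveillance_policy(), ref_age = 50)
  expect_identical(rr$dx_mode, "none")
  expect_equal(rr$ly, 50)  # other-cause death at 100
})

test_that("exams after death or diagnosis are scheduling errors", {
  params <- const_intensity_params(1e-300)
  nh <- synthetic_history(large_lesion_row(1), params, 1, 5,
                          other_death = 59)
  expect_error(perform_colonoscopy(nh, 60, perfect_chars("colonoscopy")),
               "engine bug")
  expect_error(perform_fit(nh, 60, perfect_chars("fit"),
                           perfect_chars("colonoscopy")), "engine bug")
})

test_that("test characteristics validate their invariants", {
  expect_error(test_characteristics("colonoscopy", 0.9, 0.8, 0.95, 0.95, 1),
               "non-decreasing")
  expect_error(test_characteristics("fit", 0.1, 0.2, 0.3, 1.2, 1),
               "probabilities")
  expect_error(surveillance_policy(5, 3, 10), "high_risk <= low_risk")
})
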