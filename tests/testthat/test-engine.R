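test_that("a null disruption leaves life-years untouched, person by person", {
  s <- scenario_spec(cohort_spec("C60"), disruption_spec("none"))
  arms <- run_scenario(s, default_cfg, n = 2000, master_seed = 21)
  expect_identical(arms$disrupted$person_ly, arms$no_disruption$person_ly)
  expect_equal(compute_outcomes(arms)$LYL, 0)
})

test_that("screening cannot change a CRC-free lifetime", {
  s <- scenario_spec(cohort_spec("U50"), disruption_spec("none"))
  arms <- run_scenario(s, default_cfg, n = 3000, master_seed = 22)
  crc_free <- arms$no_screening$dx_mode == 0 &
    arms$no_disruption$dx_mode == 0
  expect_gt(sum(crc_free), 0)
  expect_identical(arms$no_disruption$person_ly[crc_free],
                   arms$no_screening$person_ly[crc_free])
})

test_that("the deterministic toy fixture reproduces the event timeline", {
  # every person: adenoma at 52, preclinical at 58, clinical dx 62,
  # untreated CRC death 65, other-cause death 85; a colonoscopy at 60
  # screen-detects with a stage shift generous enough that the person
  # reaches other-cause death.  LY(no disruption) = 25, LY(discontinue)
  # = 5, so discontinuation loses exactly 20 yr/person at any n.
  for (n in c(4, 37)) {
    arms <- run_scenario("C60 | U", toy_cfg, n = n, master_seed = 1)
    expect_equal(unique(arms$no_disruption$person_ly), 25)
    expect_equal(unique(arms$disrupted$person_ly), 5)
    expect_equal(unique(arms$no_screening$person_ly), 5)
    rec <- compute_outcomes(arms)
    expect_identical(rec$LYL, 20000)       # per 1,000 persons
    expect_identical(rec$LYG_nd, 20000)
    expect_identical(rec$pct_ly_lost, 100)
    expect_identical(rec$se_LYL, 0)
  }
})

test_that("the R reference replay and the compiled engine agree exactly", {
  params <- default_cfg$natural_history$model_a
  tc <- default_cfg$test_characteristics$high_sensitivity
  pol <- default_cfg$surveillance
  cases <- list(
    list(lab = "F60", sched = rbind(cohort_info("F60")$pre,
                                    data.frame(age = 60:75, modality = "fit"))),
    list(lab = "C60", sched = rbind(cohort_info("C60")$pre,
                                    data.frame(age = c(60, 70),
                                               modality = "colonoscopy"))),
    list(lab = "C70", sched = data.frame(age = c(50, 60, 71.5, 72.5, 73.5),
                                         modality = c("colonoscopy",
                                                      "colonoscopy", "fit",
                                                      "fit", "fit"))))
  for (cs in cases) {
    info <- cohort_info(cs$lab)
    n <- 250
    coh <- sample_cohort(params, n, 11, info$age, info$pre,
                         tc$colonoscopy, tc$fit, pol)
    r_cpp <- cpp_replay_cohort(unclass(coh), nh_params_cpp(params),
                               cs$sched$age, modality_code(cs$sched$modality),
                               unclass(tc$colonoscopy), unclass(tc$fit),
                               unclass(pol), info$age, info$age,
                               0, TRUE, 0, 11)
    for (i in seq_len(n)) {
      rr <- replay_history(cohort_person(coh, i), cs$sched,
                           tc$colonoscopy, tc$fit, pol,
                           ref_age = info$age, onset_age = info$age)
      expect_equal(rr$ly, r_cpp$ly[i], tolerance = 1e-12)
      expect_equal(rr$death_age, r_cpp$death_age[i], tolerance = 1e-12)
    }
  }
})

test_that("identical seeds give bit-identical scenario results", {
  s <- parse_label("C70 | F9m")
  a1 <- run_scenario(s, default_cfg, n = 1500, master_seed = 33)
  a2 <- run_scenario(s, default_cfg, n = 1500, master_seed = 33)
  expect_identical(a1$disrupted$person_ly, a2$disrupted$person_ly)
  expect_identical(a1$no_screening$person_ly, a2$no_screening$person_ly)
  a3 <- run_scenario(s, default_cfg, n = 1500, master_seed = 34)
  expect_false(identical(a1$disrupted$person_ly, a3$disrupted$person_ly))
})

test_that("scenarios of a cohort share person-aligned natural histories", {
  rec <- run_all(default_cfg, n = 800, master_seed = 9,
                 param_sets = "model_a", sensitivities = "high_sensitivity",
                 scenario_filter = "C60*")
  # one row per C60 scenario, all with the same no-screening life-years
  expect_equal(nrow(rec), 8)
  expect_equal(length(unique(rec$LYNS)), 1)
  expect_equal(length(unique(rec$LYND[rec$scenario_label != "C60 | U"])), 1)
})

test_that("n must be positive", {
  expect_error(run_scenario("C60 | U", default_cfg, n = 0, master_seed = 1))
  expect_error(run_disruption_analysis(default_cfg, n = 0, master_seed = 1,
                                       output_dir = tempfile()),
               "positive")
})

test_that("life-years are non-negative and bounded by the horizon", {
  arms <- run_scenario("F70 | U", default_cfg, n = 2000, master_seed = 5)
  for (arm in list(arms$disrupted, arms$no_disruption, arms$no_screening)) {
    expect_true(all(arm$person_ly >= 0))
    expect_true(all(arm$person_ly <= 110 - 70 + 1e-9))
  }
})
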