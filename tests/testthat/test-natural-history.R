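test_that("zero adenoma intensity yields an empty, CRC-free history", {
  params <- const_intensity_params(1e-300)
  nh <- sample_person(params, person_id = 3, master_seed = 17)
  expect_length(nh$adenomas, 0)
  expect_true(is.na(nh$clinical_dx_age))
  expect_true(is.na(nh$preclinical_onset_age))
  expect_true(is.finite(nh$other_cause_death_age))
  expect_lte(nh$other_cause_death_age, 110)
  expect_equal(untreated_death_age(nh), nh$other_cause_death_age)
})

test_that("adenoma counts follow the Poisson law of the intensity", {
  # constant intensity 0.02/yr over ages 20-80 with mortality disabled
  # before 85: counts by age 80 are Poisson(1.2)
  params <- const_intensity_params(0.02)
  n <- 1e5
  co <- sample_cohort(params, n, master_seed = 41, ref_age = 0,
                      chars_col = perfect_chars("colonoscopy"),
                      chars_fit = perfect_chars("fit"),
                      policy = surveillance_policy())
  by80 <- tapply(co$lesion_init <= 80, co$lesion_person, sum)
  cnt <- integer(n)
  cnt[as.integer(names(by80))] <- as.integer(by80)
  lambda <- 0.02 * 60
  expect_lt(abs(mean(cnt) - lambda), 3 * sd(cnt) / sqrt(n))
  # chi-square against Poisson(1.2), bins 0..6 and 7+
  obs <- tabulate(pmin(cnt, 7) + 1, nbins = 8)
  p <- c(dpois(0:6, lambda), 1 - ppois(6, lambda))
  x2 <- sum((obs - n * p)^2 / (n * p))
  expect_lt(x2, qchisq(0.99, df = 7))
})

test_that("adenoma initiation ages follow the intensity profile", {
  # with constant intensity the initiation ages are uniform on [20, 110]
  params <- const_intensity_params(0.02, lifetable = no_mort_lifetable(105))
  co <- sample_cohort(params, 2e4, master_seed = 43, ref_age = 0,
                      chars_col = perfect_chars("colonoscopy"),
                      chars_fit = perfect_chars("fit"),
                      policy = surveillance_policy())
  ks <- suppressWarnings(
    stats::ks.test(co$lesion_init, "punif", min = 20, max = 110))
  expect_gt(ks$p.value, 0.01)
})

test_that("growth curve hits its boundary, asymptote and 10mm time", {
  params <- default_cfg$natural_history$model_a
  lam <- log((params$d_inf - params$d0) / (params$d_inf - 10)) / 8
  ad <- structure(list(id = 1, init_age = 40, growth_rate = lam,
                       transition_age = NA_real_, removed_age = NA_real_),
                  class = "adenoma")
  expect_equal(adenoma_diameter(ad, params, 40), params$d0)
  expect_equal(adenoma_diameter(ad, params, 40 + 8), 10, tolerance = 1e-9)
  expect_equal(adenoma_diameter(ad, params, 4000), params$d_inf,
               tolerance = 1e-6)
  expect_error(adenoma_diameter(ad, params, 39), "precedes")
  # monotone non-decreasing in age for sampled lesions
  nh <- sample_person(params, 8, 4242)
  for (a in nh$adenomas) {
    ages <- a$init_age + seq(0, 40, by = 0.5)
    expect_true(all(diff(adenoma_diameter(a, params, ages)) >= 0))
  }
})

test_that("degenerate sojourn makes diagnosis lag onset by its mean", {
  params <- const_intensity_params(0.05)
  params$transition_hazard_per_mm <- 5e-3  # frequent transitions
  found <- 0
  for (i in 1:300) {
    nh <- sample_person(params, i, 2025)
    if (!is.na(nh$clinical_dx_age)) {
      found <- found + 1
      # sojourn_sdlog = 0 and meanlog = log(3): exactly 3 years
      expect_equal(nh$clinical_dx_age - nh$preclinical_onset_age, 3)
      expect_gt(nh$clinical_dx_age, nh$preclinical_onset_age)
    }
  }
  expect_gt(found, 5)
})

test_that("untreated death age is the minimum of the competing causes", {
  params <- const_intensity_params(1e-300)
  nh <- sample_person(params, 1, 9)
  nh$other_cause_death_age <- 82
  nh$crc_death_age_untreated <- NA_real_
  expect_equal(untreated_death_age(nh), 82)
  nh$crc_death_age_untreated <- 71.5
  expect_equal(untreated_death_age(nh), 71.5)
  nh$other_cause_death_age <- 70
  expect_equal(untreated_death_age(nh), 70)
})

test_that("histories are deterministic and order-independent", {
  params <- default_cfg$natural_history$model_a
  nh1 <- sample_person(params, 5, 123)
  nh2 <- sample_person(params, 5, 123)
  expect_identical(nh1, nh2)
  expect_false(identical(nh1$lesions, sample_person(params, 6, 123)$lesions))

  tc <- default_cfg$test_characteristics$high_sensitivity
  co_big <- sample_cohort(params, 500, 123, 60,
                          cohort_spec("C60")$pre_pandemic_exams,
                          tc$colonoscopy, tc$fit, default_cfg$surveillance)
  co_small <- sample_cohort(params, 200, 123, 60,
                            cohort_spec("C60")$pre_pandemic_exams,
                            tc$colonoscopy, tc$fit, default_cfg$surveillance)
  # a prefix sub-cohort is bit-identical: streams are keyed by person id,
  # not call order
  expect_identical(co_small$other_death, co_big$other_death[1:200])
  expect_identical(co_small$attempt, co_big$attempt[1:200])
  keep <- co_big$lesion_person <= 200
  expect_identical(co_small$lesion_init, co_big$lesion_init[keep])
  # a cohort member equals the standalone draw at its accepted attempt
  i <- which(co_big$attempt > 0)[1]
  if (is.na(i)) i <- 1L
  nh <- sample_person(params, i, 123, attempt = co_big$attempt[i])
  expect_equal(nh$other_cause_death_age, co_big$other_death[i])
  expect_equal(nh$lesions$init_age,
               co_big$lesion_init[co_big$lesion_person == i])
})

test_that("cohort conditioning enforces the reference-age constraints", {
  params <- default_cfg$natural_history$model_a
  tc <- default_cfg$test_characteristics$high_sensitivity
  co <- sample_cohort(params, 2000, 7, 70, cohort_spec("C70")$pre_pandemic_exams,
                      tc$colonoscopy, tc$fit, default_cfg$surveillance)
  expect_true(all(co$other_death > 70))
  expect_gte(sum(co$attempt), 1)  # some draws were rejected and replaced
})

test_that("pathological configurations fail conditioning loudly", {
  params <- const_intensity_params(1e-300,
                                   lifetable = no_mort_lifetable(30))
  tc <- default_cfg$test_characteristics$high_sensitivity
  # everyone dies at 30; a cohort aged 60 at onset cannot exist
  expect_error(
    sample_cohort(params, 10, 1, 60, empty_schedule(),
                  tc$colonoscopy, tc$fit, default_cfg$surveillance),
    "conditioning")
})
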