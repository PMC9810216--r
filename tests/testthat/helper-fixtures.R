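# Shared fixtures, all built in code.

default_cfg <- default_config()

toy_cfg <- local({
  path <- make_toy_fixture(tempfile(fileext = ".yaml"))
  load_config(path)
})

# a "no mortality until 85" life table: everyone alive through age 84,
# certain death at 85 (used to disable mortality in closed-form oracles)
no_mort_lifetable <- function(until = 85) fixed_age_lifetable(until)

# natural-history parameters with a constant adenoma intensity and no
# person-level heterogeneity; transitions pushed far into the future
const_intensity_params <- function(rate_per_yr, psi_sd = 0,
                                   lifetable = no_mort_lifetable()) {
  nh_params(
    baseline_log_risk_mean = 0, baseline_log_risk_sd = psi_sd,
    age_intensity_knots = data.frame(age = c(20, 110),
                                     log_intensity = rep(log(rate_per_yr), 2)),
    growth_time_to_10mm_scale = 12, growth_time_to_10mm_shape = 2,
    d0 = 1, d_inf = 50,
    transition_hazard_per_mm = 1e-9,
    sojourn_meanlog = log(3), sojourn_sdlog = 0,
    stage_probs_clinical = c(0.25, 0.25, 0.25, 0.25),
    stage_shift_screen = diag(4),
    crc_survival_rate_by_stage = c(0.01, 0.03, 0.09, 0.44),
    lifetable = lifetable)
}

perfect_chars <- function(modality)
  test_characteristics(modality, 1, 1, 1, 1, 1)

# a hand-built natural history with the given lesion table, for exercising
# the single-exam operations on controlled inputs
synthetic_history <- function(lesions, params, person_id, master_seed,
                              other_death = 100, attempt = 0) {
  n <- nrow(lesions)
  lesions$id <- seq_len(n)
  if (is.null(lesions$removed_age)) lesions$removed_age <- rep(NA_real_, n)
  if (is.null(lesions$sojourn)) lesions$sojourn <- rep(3, n)
  if (is.null(lesions$stage_clinical)) lesions$stage_clinical <- rep(2L, n)
  if (is.null(lesions$stage_screen)) lesions$stage_screen <- rep(1L, n)
  adenomas <- lapply(seq_len(n), function(j)
    structure(list(id = j, init_age = lesions$init_age[j],
                   growth_rate = lesions$growth_rate[j],
                   transition_age = lesions$transition_age[j],
                   removed_age = NA_real_), class = "adenoma"))
  structure(list(person_id = person_id, risk = 0, adenomas = adenomas,
                 preclinical_onset_age = NA_real_, clinical_dx_age = NA_real_,
                 stage_clinical = NA_integer_,
                 crc_death_age_untreated = NA_real_,
                 other_cause_death_age = other_death,
                 lesions = lesions, params = params,
                 stream = sim_stream(master_seed, person_id, attempt)),
            class = "natural_history")
}

# lesion table rows: adenomas that are large (~20 mm) at age 60
large_lesion_row <- function(k = 1) {
  data.frame(init_age = rep(40, k),
             growth_rate = rep(log((50 - 1) / (50 - 10)) / 8, k),
             transition_age = rep(1e6, k))
}

# pooled two-SE slack for comparing two outcome records (conservative:
# ignores the shared randomness between the arms being compared)
pooled_2se <- function(se1, se2) 2 * sqrt(se1^2 + se2^2)
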