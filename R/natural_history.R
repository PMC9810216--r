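#' Sample one untreated natural history
#'
#' Generates a complete untreated CRC life history: person-level risk
#' deviate, adenoma initiation ages from the non-homogeneous Poisson
#' process, per-adenoma growth rates (Frechet time-to-10mm inverted
#' through the growth curve), malignant transformation ages
#' (diameter-proportional hazard), lognormal sojourn times, clinical and
#' screen-detected stages, stage-specific survival, and an other-cause
#' death age from the life table.  Fully deterministic given
#' `(master_seed, person_id, attempt)`.
#'
#' @param params an [nh_params] object.
#' @param person_id 1-based person index.
#' @param master_seed integer master seed.
#' @param attempt rejection-sampling attempt (0-based); the conditioned
#'   cohort sampler records the accepted attempt per person.
#' @return an object of class `natural_history` with fields `person_id`,
#'   `risk` (the log-risk deviate), `adenomas` (list of `adenoma` objects),
#'   `preclinical_onset_age`, `clinical_dx_age`, `stage_clinical`,
#'   `crc_death_age_untreated`, `other_cause_death_age` (all ages in
#'   years; `NA` where the event does not occur before other-cause death),
#'   a `lesions` data frame used by the replay engine, and the `stream`
#'   identifying its random draws.
#' @examples
#' cfg <- default_config()
#' nh <- sample_person(cfg$natural_history$model_a, person_id = 1,
#'                     master_seed = 42)
#' untreated_death_age(nh)
#' @export
sample_person <- function(params, person_id, master_seed, attempt = 0) {
  stopifnot(inherits(params, "nh_params"))
  raw <- cpp_sample_person(nh_params_cpp(params), master_seed, person_id,
                           attempt)
  build_natural_history(params, raw, person_id, master_seed, attempt)
}

build_natural_history <- function(params, raw, person_id, master_seed,
                                  attempt) {
  n <- length(raw$init_age)
  lesions <- data.frame(
    id = seq_len(n),
    init_age = raw$init_age,
    growth_rate = raw$growth_rate,
    transition_age = raw$transition_age,
    sojourn = raw$sojourn,
    stage_clinical = raw$stage_clinical + 1L,
    stage_screen = raw$stage_screen + 1L,
    removed_age = rep(NA_real_, n))
  other <- raw$other_death
  adenomas <- lapply(seq_len(n), function(j) {
    structure(list(id = j, init_age = lesions$init_age[j],
                   growth_rate = lesions$growth_rate[j],
                   transition_age = if (lesions$transition_age[j] < other)
                     lesions$transition_age[j] else NA_real_,
                   removed_age = NA_real_), class = "adenoma")
  })
  eff <- lesions$transition_age < other
  onset <- if (any(eff)) min(lesions$transition_age[eff]) else NA_real_
  dx_cand <- lesions$transition_age + lesions$sojourn
  dx_cand[!eff] <- Inf
  jdx <- if (any(eff)) which.min(dx_cand) else NA_integer_
  dx <- if (!is.na(jdx) && dx_cand[jdx] < other) dx_cand[jdx] else NA_real_
  stage <- NA_integer_
  crc_death <- NA_real_
  if (!is.na(dx)) {
    stage <- lesions$stage_clinical[jdx]
    stream <- sim_stream(master_seed, person_id, attempt)
    u <- keyed_u01(stream, "survival", jdx - 1)
    surv <- if (identical(params$crc_survival_type, "fixed"))
      params$crc_survival_rate_by_stage[stage]
    else -log(u) / params$crc_survival_rate_by_stage[stage]
    crc_death <- dx + surv
  }
  structure(list(
    person_id = person_id,
    risk = raw$psi,
    adenomas = adenomas,
    preclinical_onset_age = onset,
    clinical_dx_age = dx,
    stage_clinical = stage,
    crc_death_age_untreated = crc_death,
    other_cause_death_age = other,
    lesions = lesions,
    params = params,
    stream = sim_stream(master_seed, person_id, attempt)),
    class = "natural_history")
}

#' Adenoma diameter along the growth curve
#'
#' von-Bertalanffy growth: d(t) = d_inf - (d_inf - d0) exp(-lambda (t -
#' t_init)); monotone non-decreasing in age from `d0` towards `d_inf`.
#'
#' @param ad an `adenoma` (element of `natural_history$adenomas`).
#' @param params the [nh_params] the person was sampled under.
#' @param age age (years) at which to evaluate; must be `>= ad$init_age`.
#' @return diameter in mm.
#' @export
adenoma_diameter <- function(ad, params, age) {
  stopifnot(inherits(params, "nh_params"))
  if (any(age < ad$init_age))
    stop("adenoma_diameter: age precedes the adenoma's initiation age")
  params$d_inf - (params$d_inf - params$d0) *
    exp(-ad$growth_rate * (age - ad$init_age))
}

#' Untreated death age
#'
#' The age a person would die with no screening: the minimum of the
#' other-cause death age and the untreated CRC death age (infinity when no
#' clinical cancer develops).
#'
#' @param nh a `natural_history`.
#' @return death age in years.
#' @export
untreated_death_age <- function(nh) {
  stopifnot(inherits(nh, "natural_history"))
  min(nh$other_cause_death_age,
      if (is.na(nh$crc_death_age_untreated)) Inf else nh$crc_death_age_untreated)
}

#' Sample a conditioned cohort
#'
#' Draws `n` natural histories conditioned on cohort membership at the
#' reference age (the age at pandemic onset): the person is alive, has no
#' CRC diagnosis, and their simulated pre-pandemic screening exams (with
#' lesions found removed and surveillance entered) are consistent with the
#' cohort definition.  Rejected draws are replaced deterministically by
#' incrementing the per-person attempt counter, so the cohort is
#' reproducible and order-independent.
#'
#' @param params an [nh_params].
#' @param n cohort size.
#' @param master_seed integer master seed.
#' @param ref_age cohort reference age (age in April 2020).
#' @param pre_exams data frame with columns `age`, `modality` of
#'   pre-pandemic exams (possibly empty).
#' @param chars_col,chars_fit [test_characteristics] in force.
#' @param policy a [surveillance_policy].
#' @return an `nh_cohort`: columnar person and lesion tables plus the
#'   sampling metadata needed to replay arms.
#' @export
sample_cohort <- function(params, n, master_seed, ref_age,
                          pre_exams = empty_schedule(),
                          chars_col, chars_fit, policy) {
  stopifnot(inherits(params, "nh_params"), n >= 1)
  raw <- cpp_sample_cohort(nh_params_cpp(params), as.integer(n), master_seed,
                           ref_age, pre_exams$age,
                           modality_code(pre_exams$modality),
                           unclass(chars_col), unclass(chars_fit),
                           unclass(policy), 1000L)
  structure(c(raw, list(master_seed = master_seed, ref_age = ref_age,
                        params = params, pre_exams = pre_exams,
                        chars_col = chars_col, chars_fit = chars_fit,
                        policy = policy)),
            class = "nh_cohort")
}

#' @rdname sample_cohort
#' @param cohort an `nh_cohort`.
#' @param i person index within the cohort.
#' @return `cohort_person()` returns the `natural_history` of cohort
#'   member `i` (identical to re-sampling that person at their accepted
#'   attempt).
#' @export
cohort_person <- function(cohort, i) {
  stopifnot(inherits(cohort, "nh_cohort"), i >= 1, i <= cohort$n)
  sample_person(cohort$params, i, cohort$master_seed, cohort$attempt[i])
}

empty_schedule <- function() {
  data.frame(age = numeric(0), modality = character(0),
             stringsAsFactors = FALSE)
}

modality_code <- function(m) {
  code <- match(m, c("colonoscopy", "fit")) - 1L
  if (any(is.na(code))) stop("unknown modality: ",
                             paste(unique(m[is.na(code)]), collapse = ", "))
  as.integer(code)
}
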