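#' Run a scenario as three paired arms
#'
#' Samples a conditioned cohort and replays every member under three
#' screening arms on common random numbers: `disrupted` (pre-pandemic
#' exams plus the disrupted post-onset schedule), `no_disruption`
#' (pre-pandemic exams plus the counterfactual schedule) and
#' `no_screening` (no exams at all).  Life-years are counted from the
#' cohort reference age; the three `person_ly` vectors are index-aligned
#' by person, which is what makes the life-years-lost difference a paired
#' estimate.
#'
#' @param scenario a [scenario_spec] (or a label accepted by
#'   [parse_label()]).
#' @param config a `sim_config` from [load_config()] /
#'   [default_config()].
#' @param n cohort size (persons).
#' @param master_seed integer master seed.
#' @param param_set name of the natural-history parameter set in
#'   `config$natural_history`.
#' @param sensitivity name of the test-characteristics scenario in
#'   `config$test_characteristics` (e.g. `"high_sensitivity"`).
#' @param cohort optionally, a pre-sampled `nh_cohort` for this cohort
#'   label (from [sample_cohort()] with the same seed, parameters and
#'   characteristics), re-used across scenarios to share natural
#'   histories.
#' @return list of class `scenario_arms` with elements `disrupted`,
#'   `no_disruption`, `no_screening` (each an `arm_result` with fields
#'   `scenario_label`, `arm`, `person_ly`, `n`, `dx_mode`, `dx_age`), and
#'   the run metadata.
#' @export
run_scenario <- function(scenario, config, n, master_seed,
                         param_set = NULL, sensitivity = NULL,
                         cohort = NULL) {
  if (is.character(scenario)) scenario <- parse_label(scenario)
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "sim_config"), n >= 1)
  param_set <- param_set %||% names(config$natural_history)[1]
  sensitivity <- sensitivity %||% names(config$test_characteristics)[1]
  params <- config$natural_history[[param_set]]
  if (is.null(params)) stop("unknown param_set: ", param_set)
  chars <- config$test_characteristics[[sensitivity]]
  if (is.null(chars)) stop("unknown sensitivity scenario: ", sensitivity)
  pol <- config$surveillance
  co <- scenario$cohort
  ref <- co$age_at_onset

  if (is.null(cohort)) {
    cohort <- sample_cohort(params, n, master_seed, ref,
                            co$pre_pandemic_exams,
                            chars$colonoscopy, chars$fit, pol)
  } else if (cohort$n != n) {
    stop("supplied cohort has n = ", cohort$n, ", expected ", n)
  }

  pre <- co$pre_pandemic_exams
  cf <- counterfactual_schedule(co)
  ds <- disrupted_schedule(co, scenario$disruption)
  kind <- scenario$disruption$kind
  arm_args <- list(
    surv_delay = if (kind %in% c("delay_months", "switch_to_fit"))
      scenario$disruption$d / 12 else 0,
    allow_post_surv = !identical(kind, "discontinue"),
    min_post_exam = if (identical(kind, "long_delay"))
      scenario$disruption$resume_ages[1] else 0)

  replay <- function(sched, arm, args = list(surv_delay = 0,
                                             allow_post_surv = TRUE,
                                             min_post_exam = 0)) {
    r <- cpp_replay_cohort(unclass(cohort), nh_params_cpp(params),
                           sched$age, modality_code(sched$modality),
                           unclass(chars$colonoscopy), unclass(chars$fit),
                           unclass(pol), ref, ref,
                           args$surv_delay, args$allow_post_surv,
                           args$min_post_exam, master_seed)
    structure(list(scenario_label = scenario$label, arm = arm,
                   person_ly = r$ly, n = cohort$n,
                   dx_mode = r$dx_mode, dx_age = r$dx_age,
                   dx_stage = r$dx_stage),
              class = "arm_result")
  }
  bind <- function(a, b) rbind(a, b)[order(c(a$age, b$age)), , drop = FALSE]

  structure(list(
    disrupted = replay(bind(pre, ds), "disrupted", arm_args),
    no_disruption = replay(bind(pre, cf), "no_disruption"),
    no_screening = replay(empty_schedule(), "no_screening"),
    scenario = scenario, n = n, master_seed = master_seed,
    param_set = param_set, sensitivity = sensitivity),
    class = "scenario_arms")
}

#' Run all scenarios of the study design
#'
#' Maps [run_scenario()] over the enumerated scenarios.  All scenarios of
#' a cohort label re-use the same conditioned natural-history draw, and
#' identical arm schedules are replayed once, so cross-scenario
#' comparisons share both persons and random numbers.
#'
#' @inheritParams run_scenario
#' @param param_sets,sensitivities character vectors of natural-history
#'   set names and sensitivity-scenario names to run (defaults: all in
#'   the config).
#' @param scenarios list of [scenario_spec] (default: the full
#'   enumeration).
#' @param scenario_filter optional glob (e.g. `"C60*"`) applied to
#'   scenario labels.
#' @param progress emit per-scenario progress messages to stderr.
#' @return a data frame of outcome records, one row per (scenario,
#'   sensitivity, parameter set); see [compute_outcomes()] for columns.
#' @export
run_all <- function(config, n, master_seed,
                    param_sets = names(config$natural_history),
                    sensitivities = names(config$test_characteristics),
                    scenarios = enumerate_scenarios(),
                    scenario_filter = NULL, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (!is.null(scenario_filter)) {
    keep <- grepl(utils::glob2rx(scenario_filter),
                  vapply(scenarios, function(s) s$label, character(1)))
    scenarios <- scenarios[keep]
    if (!length(scenarios)) stop("scenario_filter matches no scenario")
  }
  labels <- vapply(scenarios, function(s) s$cohort$label, character(1))
  out <- list()
  for (ps in param_sets) {
    for (sens in sensitivities) {
      chars <- config$test_characteristics[[sens]]
      if (is.null(chars)) stop("unknown sensitivity scenario: ", sens)
      params <- config$natural_history[[ps]]
      if (is.null(params)) stop("unknown param_set: ", ps)
      for (lab in unique(labels)) {
        co_info <- cohort_info(lab)
        cohort <- sample_cohort(params, n, master_seed, co_info$age,
                                co_info$pre, chars$colonoscopy, chars$fit,
                                config$surveillance)
        arm_cache <- new.env(parent = emptyenv())
        for (s in scenarios[labels == lab]) {
          if (progress)
            message(sprintf("[%s/%s] %s", ps, sens, s$label))
          t0 <- proc.time()[["elapsed"]]
          arms <- run_scenario_cached(s, config, n, master_seed, ps, sens,
                                      cohort, arm_cache)
          rec <- compute_outcomes(arms)
          if (progress)
            message(sprintf("  done in %.1fs (seed %d)",
                            proc.time()[["elapsed"]] - t0,
                            as.integer(master_seed)))
          out[[length(out) + 1]] <- rec
        }
      }
    }
  }
  do.call(rbind, out)
}

# run_scenario with memoised arm replays (schedule + disruption-arg digest)
run_scenario_cached <- function(scenario, config, n, master_seed,
                                param_set, sensitivity, cohort, cache) {
  params <- config$natural_history[[param_set]]
  chars <- config$test_characteristics[[sensitivity]]
  pol <- config$surveillance
  co <- scenario$cohort
  ref <- co$age_at_onset
  pre <- co$pre_pandemic_exams
  cf <- counterfactual_schedule(co)
  ds <- disrupted_schedule(co, scenario$disruption)
  kind <- scenario$disruption$kind
  args_dis <- list(
    surv_delay = if (kind %in% c("delay_months", "switch_to_fit"))
      scenario$disruption$d / 12 else 0,
    allow_post_surv = !identical(kind, "discontinue"),
    min_post_exam = if (identical(kind, "long_delay"))
      scenario$disruption$resume_ages[1] else 0)
  args_null <- list(surv_delay = 0, allow_post_surv = TRUE,
                    min_post_exam = 0)
  bind <- function(a, b) rbind(a, b)[order(c(a$age, b$age)), , drop = FALSE]

  replay_memo <- function(sched, arm, args) {
    key <- paste(c(sprintf("%.6f", sched$age), sched$modality,
                   sprintf("%.6f", args$surv_delay), args$allow_post_surv,
                   sprintf("%.6f", args$min_post_exam)), collapse = "|")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(hit)) {
      r <- cpp_replay_cohort(unclass(cohort), nh_params_cpp(params),
                             sched$age, modality_code(sched$modality),
                             unclass(chars$colonoscopy), unclass(chars$fit),
                             unclass(pol), ref, ref, args$surv_delay,
                             args$allow_post_surv, args$min_post_exam,
                             master_seed)
      assign(key, r, envir = cache)
      hit <- r
    }
    structure(list(scenario_label = scenario$label, arm = arm,
                   person_ly = hit$ly, n = cohort$n,
                   dx_mode = hit$dx_mode, dx_age = hit$dx_age,
                   dx_stage = hit$dx_stage),
              class = "arm_result")
  }
  structure(list(
    disrupted = replay_memo(bind(pre, ds), "disrupted", args_dis),
    no_disruption = replay_memo(bind(pre, cf), "no_disruption", args_null),
    no_screening = replay_memo(empty_schedule(), "no_screening", args_null),
    scenario = scenario, n = n, master_seed = master_seed,
    param_set = param_set, sensitivity = sensitivity),
    class = "scenario_arms")
}
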