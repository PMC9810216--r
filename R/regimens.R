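#' Study cohorts
#'
#' Eight pre-pandemic cohorts of average-risk individuals, defined by
#' their age at the pandemic onset (April 2020) and their pre-pandemic
#' screening behaviour: unscreened 50/60/70-year-olds (U50, U60, U70),
#' colonoscopy-adherent 60- and 70-year-olds (C60: colonoscopy at 50;
#' C70: colonoscopies at 50 and 60), FIT-adherent 60- and 70-year-olds
#' (F60: annual FIT ages 50-59; F70: annual FIT ages 50-69) and
#' FIT-semi-adherent 60-year-olds (f60: biennial FIT ages 50-56).
#'
#' @param label one of `"U50"`, `"U60"`, `"C60"`, `"F60"`, `"f60"`,
#'   `"U70"`, `"C70"`, `"F70"`.
#' @param modality counterfactual screening modality after the onset:
#'   `"colonoscopy"` or `"fit"`.  Fixed by the pre-pandemic regimen for
#'   screened cohorts; unscreened cohorts appear with both (their default
#'   is colonoscopy).
#' @return object of class `cohort_spec` with fields `label`,
#'   `age_at_onset`, `pre_pandemic_exams` (data frame `age`, `modality`)
#'   and `counterfactual_regimen` (a `screening_regimen`).
#' @export
cohort_spec <- function(label, modality = NULL) {
  info <- cohort_info(label)
  if (is.null(modality)) modality <- info$default_modality
  modality <- match.arg(modality, c("colonoscopy", "fit"))
  if (!is.na(info$fixed_modality) && modality != info$fixed_modality)
    stop(sprintf("cohort %s is %s-adherent; counterfactual modality must be %s",
                 label, info$fixed_modality, info$fixed_modality))
  reg <- if (modality == "colonoscopy")
    screening_regimen("colonoscopy", 50, 70, 10)
  else screening_regimen("fit", 50, 75, 1)
  structure(list(label = label, age_at_onset = info$age,
                 pre_pandemic_exams = info$pre,
                 counterfactual_modality = modality,
                 counterfactual_regimen = reg),
            class = "cohort_spec")
}

cohort_labels <- function() c("U50", "U60", "C60", "F60", "f60",
                              "U70", "C70", "F70")

cohort_info <- function(label) {
  sched <- function(ages, mod) data.frame(age = ages,
                                          modality = rep(mod, length(ages)),
                                          stringsAsFactors = FALSE)
  switch(label,
    U50 = list(age = 50, pre = empty_schedule(),
               default_modality = "colonoscopy", fixed_modality = NA),
    U60 = list(age = 60, pre = empty_schedule(),
               default_modality = "colonoscopy", fixed_modality = NA),
    C60 = list(age = 60, pre = sched(50, "colonoscopy"),
               default_modality = "colonoscopy",
               fixed_modality = "colonoscopy"),
    F60 = list(age = 60, pre = sched(50:59, "fit"),
               default_modality = "fit", fixed_modality = "fit"),
    f60 = list(age = 60, pre = sched(c(50, 52, 54, 56), "fit"),
               default_modality = "fit", fixed_modality = "fit"),
    U70 = list(age = 70, pre = empty_schedule(),
               default_modality = "colonoscopy", fixed_modality = NA),
    C70 = list(age = 70, pre = sched(c(50, 60), "colonoscopy"),
               default_modality = "colonoscopy",
               fixed_modality = "colonoscopy"),
    F70 = list(age = 70, pre = sched(50:69, "fit"),
               default_modality = "fit", fixed_modality = "fit"),
    stop("unknown cohort label: ", label))
}

#' Screening regimens
#'
#' The two guideline regimens in force at the pandemic onset: decennial
#' colonoscopy from age 50 to 70, and annual FIT from age 50 to 75 (with
#' diagnostic colonoscopy after a positive FIT).
#'
#' @param modality `"colonoscopy"` or `"fit"`.
#' @param start_age,stop_age first and last eligible ages.
#' @param interval years between exams.
#' @return object of class `screening_regimen`.
#' @export
screening_regimen <- function(modality = c("colonoscopy", "fit"),
                              start_age = NULL, stop_age = NULL,
                              interval = NULL) {
  modality <- match.arg(modality)
  d <- if (modality == "colonoscopy") c(50, 70, 10) else c(50, 75, 1)
  start_age <- start_age %||% d[1]
  stop_age <- stop_age %||% d[2]
  interval <- interval %||% d[3]
  stopifnot(start_age < stop_age, interval > 0)
  structure(list(modality = modality, start_age = start_age,
                 stop_age = stop_age, interval = interval),
            class = "screening_regimen")
}

#' Disruption specifications
#'
#' The post-pandemic disruption taxonomy: `none` (the no-disruption
#' counterfactual itself), `delay_months` (a 3-, 9- or 18-month delay
#' applied to the first post-onset exam and carried forward to all later
#' ones), `long_delay` (screening paused, colonoscopies only at the given
#' resume ages), `switch_to_fit` (a colonoscopy cohort permanently
#' switches to annual FIT to age 75, the first FIT delayed by `d`
#' months), and `discontinue` (no screening at all after the onset,
#' surveillance included).
#'
#' @param kind one of `"none"`, `"delay_months"`, `"long_delay"`,
#'   `"switch_to_fit"`, `"discontinue"`.
#' @param d delay in months (3, 9 or 18); required for `delay_months` and
#'   `switch_to_fit`.
#' @param resume_ages increasing ages of the resumed colonoscopies;
#'   required for `long_delay`.
#' @return object of class `disruption_spec`.
#' @export
disruption_spec <- function(kind = c("none", "delay_months", "long_delay",
                                     "switch_to_fit", "discontinue"),
                            d = NA_real_, resume_ages = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("delay_months", "switch_to_fit")) {
    if (!d %in% c(3, 9, 18))
      stop("delay d must be 3, 9 or 18 months")
  } else d <- NA_real_
  if (kind == "long_delay") {
    if (is.null(resume_ages) || is.unsorted(resume_ages, strictly = TRUE))
      stop("long_delay needs strictly increasing resume_ages")
  } else resume_ages <- NULL
  structure(list(kind = kind, d = d, resume_ages = resume_ages),
            class = "disruption_spec")
}

#' Scenario specifications and the label grammar
#'
#' A scenario is a (cohort, counterfactual regimen, disruption) triple
#' labelled `"<cohort> | <code>"`, where the code gives the post-pandemic
#' regimen: `C3m`/`C9m`/`C18m` and `F3m`/`F9m`/`F18m` are short-term
#' delays (of colonoscopy or FIT screening; for colonoscopy-adherent
#' cohorts an `F` code means a permanent switch to annual FIT), `C@65` /
#' `C@75` are long-term delays with colonoscopy at the stated resume
#' ages, and `U` is complete discontinuation.
#'
#' @param cohort a [cohort_spec] (or its label).
#' @param disruption a [disruption_spec].
#' @param modality counterfactual modality, for unscreened cohorts.
#' @return object of class `scenario_spec` with fields `cohort`,
#'   `disruption` and `label`.
#' @export
scenario_spec <- function(cohort, disruption, modality = NULL) {
  if (is.character(cohort)) cohort <- cohort_spec(cohort, modality)
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(disruption, "disruption_spec"))
  if (disruption$kind == "switch_to_fit" &&
      cohort$counterfactual_modality != "colonoscopy")
    stop("switch_to_fit applies only to colonoscopy cohorts")
  if (disruption$kind == "long_delay" &&
      any(disruption$resume_ages < cohort$age_at_onset))
    stop("resume_ages must not precede the cohort's age at onset")
  structure(list(cohort = cohort, disruption = disruption,
                 label = render_label(cohort, disruption)),
            class = "scenario_spec")
}

render_label <- function(cohort, disruption) {
  code <- switch(disruption$kind,
    none = paste0(substr(toupper(cohort$counterfactual_modality), 1, 1), "0m"),
    delay_months = sprintf("%s%dm",
                           if (cohort$counterfactual_modality == "fit") "F" else "C",
                           disruption$d),
    switch_to_fit = sprintf("F%dm", disruption$d),
    long_delay = sprintf("C@%d", disruption$resume_ages[1]),
    discontinue = "U")
  paste(cohort$label, code, sep = " | ")
}

#' @rdname scenario_spec
#' @param label a scenario label such as `"C60 | F18m"`.
#' @return `parse_label()` returns the `scenario_spec` the label denotes.
#' @export
parse_label <- function(label) {
  m <- regmatches(label,
                  regexec("^([UCFf]\\d{2}) \\| (?:([CF])(\\d+)m|C@(\\d+)|(U))$",
                          label))[[1]]
  if (!length(m)) stop("unparseable scenario label: ", label)
  clab <- m[2]
  if (!clab %in% cohort_labels()) stop("unknown cohort in label: ", clab)
  info <- cohort_info(clab)
  if (nzchar(m[5])) {                      # C@<age> long delay
    resume <- as.numeric(m[5])
    resumes <- if (resume < 70) c(resume, resume + 10) else resume
    scenario_spec(cohort_spec(clab, "colonoscopy"),
                  disruption_spec("long_delay", resume_ages = resumes))
  } else if (nzchar(m[6])) {               # U discontinue
    scenario_spec(cohort_spec(clab),
                  disruption_spec("discontinue"))
  } else {
    mod_letter <- m[3]
    d <- as.numeric(m[4])
    if (mod_letter == "F" && !is.na(info$fixed_modality) &&
        info$fixed_modality == "colonoscopy") {
      scenario_spec(cohort_spec(clab, "colonoscopy"),
                    disruption_spec("switch_to_fit", d = d))
    } else {
      mod <- if (mod_letter == "F") "fit" else "colonoscopy"
      scenario_spec(cohort_spec(clab, mod),
                    if (d == 0) disruption_spec("none")
                    else disruption_spec("delay_months", d = d))
    }
  }
}

#' No-disruption counterfactual schedule
#'
#' Post-onset exam ages under no disruption.  Adherent cohorts continue
#' on-interval (C60: colonoscopies at 60 and 70; F60: annual FIT 60-75);
#' late initiators start at the onset without extra screening beyond the
#' usual stopping age (U60: colonoscopies at 60 and 70; U70: a single
#' colonoscopy at 70); the semi-adherent f60 cohort resumes FIT at 60,
#' annually to 75.  Pre-pandemic exams are not included (see
#' `cohort$pre_pandemic_exams`).
#'
#' @param cohort a [cohort_spec].
#' @return data frame with columns `age`, `modality`, sorted by age.
#' @export
counterfactual_schedule <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  onset <- cohort$age_at_onset
  reg <- cohort$counterfactual_regimen
  ages <- seq(onset, reg$stop_age, by = reg$interval)
  data.frame(age = ages, modality = rep(reg$modality, length(ages)),
             stringsAsFactors = FALSE)
}

#' Disrupted post-onset schedule
#'
#' Applies a disruption to the counterfactual schedule: short-term delays
#' shift every post-onset exam by `d/12` years (carried forward, and
#' permitted past the regimen stop age when the undelayed exam was within
#' it); long-term delays replace the schedule with colonoscopies at the
#' resume ages; switching yields annual FIT to age 75 with the first FIT
#' delayed by `d` months; discontinuation empties the schedule.
#'
#' @param cohort a [cohort_spec].
#' @param disruption a [disruption_spec].
#' @return data frame with columns `age`, `modality`.
#' @export
disrupted_schedule <- function(cohort, disruption) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(disruption, "disruption_spec"))
  cf <- counterfactual_schedule(cohort)
  onset <- cohort$age_at_onset
  switch(disruption$kind,
    none = cf,
    delay_months = {
      cf$age <- cf$age + disruption$d / 12
      cf
    },
    long_delay = data.frame(age = as.numeric(disruption$resume_ages),
                            modality = "colonoscopy",
                            stringsAsFactors = FALSE),
    switch_to_fit = {
      if (cohort$counterfactual_modality != "colonoscopy")
        stop("switch_to_fit is not defined for FIT cohorts")
      first <- onset + disruption$d / 12
      ages <- seq(first, 75, by = 1)
      data.frame(age = ages, modality = rep("fit", length(ages)),
                 stringsAsFactors = FALSE)
    },
    discontinue = empty_schedule())
}

#' Enumerate the study scenarios
#'
#' Expands the full study design: for each cohort, every disruption in
#' the design (short-term delays of 3, 9 and 18 months for each
#' counterfactual regimen, long-term delays for the unscreened and
#' colonoscopy-adherent cohorts, permanent switch to FIT for the
#' colonoscopy-adherent cohorts, and discontinuation for the screened
#' cohorts).
#'
#' @return list of [scenario_spec] objects (49 scenarios).
#' @export
enumerate_scenarios <- function() {
  delays <- c(3, 9, 18)
  sc <- list()
  add <- function(s) sc[[length(sc) + 1]] <<- s
  del <- function(lab, mod) for (d in delays)
    add(scenario_spec(cohort_spec(lab, mod),
                      disruption_spec("delay_months", d = d)))
  sw <- function(lab) for (d in delays)
    add(scenario_spec(cohort_spec(lab, "colonoscopy"),
                      disruption_spec("switch_to_fit", d = d)))
  long <- function(lab, resumes)
    add(scenario_spec(cohort_spec(lab, "colonoscopy"),
                      disruption_spec("long_delay", resume_ages = resumes)))
  disc <- function(lab)
    add(scenario_spec(cohort_spec(lab), disruption_spec("discontinue")))

  del("U50", "colonoscopy"); long("U50", c(65, 75)); del("U50", "fit")
  del("U60", "colonoscopy"); long("U60", c(65, 75)); del("U60", "fit")
  del("C60", "colonoscopy"); sw("C60"); long("C60", c(65, 75)); disc("C60")
  del("F60", "fit"); disc("F60")
  del("f60", "fit"); disc("f60")
  del("U70", "colonoscopy"); long("U70", 75); del("U70", "fit")
  del("C70", "colonoscopy"); sw("C70"); long("C70", 75); disc("C70")
  del("F70", "fit"); disc("F70")
  sc
}

describe_counterfactual <- function(cohort) {
  if (cohort$label == "f60")
    return("Biannual FIT from age 50 to 56, annual FIT from age 60 to 75")
  reg <- cohort$counterfactual_regimen
  onset <- cohort$age_at_onset
  if (reg$modality == "colonoscopy") {
    start <- if (nrow(cohort$pre_pandemic_exams))
      min(cohort$pre_pandemic_exams$age) else onset
    if (start == 70) "COL at age 70"
    else sprintf("Decennial COL from age %d to 70", start)
  } else {
    start <- if (nrow(cohort$pre_pandemic_exams))
      min(cohort$pre_pandemic_exams$age) else onset
    sprintf("Annual FIT from age %d to 75", start)
  }
}

describe_disruption <- function(disruption) {
  switch(disruption$kind,
    none = "No disruption",
    delay_months = sprintf("Short-term delay (%d months)", disruption$d),
    switch_to_fit = sprintf("Switch to annual FIT, delayed %d months",
                            disruption$d),
    long_delay = sprintf("Long-term delay (COL at age %s)",
                         paste(disruption$resume_ages, collapse = " and ")),
    discontinue = "Discontinue screening")
}

#' Tabulate the scenario enumeration
#'
#' One row per scenario with its label, cohort, counterfactual
#' description, disruption kind and parameters, and the counterfactual
#' and disrupted post-onset exam ages; suitable for audit export as CSV.
#'
#' @param scenarios list of [scenario_spec]; defaults to the full
#'   enumeration.
#' @return a data frame.
#' @export
scenario_table <- function(scenarios = enumerate_scenarios()) {
  rows <- lapply(scenarios, function(s) {
    cf <- counterfactual_schedule(s$cohort)
    ds <- disrupted_schedule(s$cohort, s$disruption)
    data.frame(
      label = s$label,
      cohort = s$cohort$label,
      counterfactual = describe_counterfactual(s$cohort),
      disruption = describe_disruption(s$disruption),
      kind = s$disruption$kind,
      d_months = s$disruption$d,
      resume_ages = paste(s$disruption$resume_ages, collapse = ";"),
      exam_ages_counterfactual = paste(format(cf$age, trim = TRUE),
                                       collapse = ";"),
      exam_ages_disrupted = paste(format(ds$age, trim = TRUE),
                                  collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
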