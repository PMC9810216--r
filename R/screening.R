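#' Screening test characteristics
#'
#' Per-exam operating characteristics of a screening modality: per-lesion
#' sensitivity by adenoma size class (small < 6 mm, medium 6-9 mm, large
#' >= 10 mm), sensitivity for preclinical invasive cancer, and specificity
#' (relevant for FIT, where a failed specificity draw yields a
#' false-positive test and a diagnostic colonoscopy).
#'
#' @param modality `"colonoscopy"` or `"fit"`.
#' @param sens_small,sens_medium,sens_large,sens_preclinical_crc per-lesion
#'   sensitivities in \[0, 1\], non-decreasing in lesion severity.
#' @param specificity probability a lesion-free exam is negative.
#' @return object of class `test_characteristics`.
#' @export
test_characteristics <- function(modality = c("colonoscopy", "fit"),
                                 sens_small, sens_medium, sens_large,
                                 sens_preclinical_crc, specificity) {
  modality <- match.arg(modality)
  v <- c(sens_small, sens_medium, sens_large, sens_preclinical_crc,
         specificity)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("test characteristics must be probabilities in [0, 1]")
  if (sens_small > sens_medium || sens_medium > sens_large ||
      sens_large > sens_preclinical_crc)
    stop("sensitivities must be non-decreasing in lesion severity ",
         "(small <= medium <= large <= preclinical CRC)")
  structure(list(modality = modality, sens_small = sens_small,
                 sens_medium = sens_medium, sens_large = sens_large,
                 sens_preclinical_crc = sens_preclinical_crc,
                 specificity = specificity),
            class = "test_characteristics")
}

#' Post-polypectomy surveillance policy
#'
#' Findings at a colonoscopy determine the next exam: high-risk findings
#' (3 or more adenomas, or any adenoma >= 10 mm) trigger a surveillance
#' colonoscopy after `interval_high_risk` years; 1-2 smaller adenomas
#' after `interval_low_risk` years; with nothing found the person returns
#' to their routine regimen, with no screening exam within
#' `interval_clear` years of the clear colonoscopy.  Surveillance stops
#' after `max_surveillance_age`.
#'
#' @param interval_high_risk,interval_low_risk,interval_clear intervals in
#'   years, `interval_high_risk <= interval_low_risk <= interval_clear`.
#' @param max_surveillance_age no surveillance exam is scheduled beyond
#'   this age.
#' @return object of class `surveillance_policy`.
#' @export
surveillance_policy <- function(interval_high_risk = 3,
                                interval_low_risk = 5,
                                interval_clear = 10,
                                max_surveillance_age = 80) {
  if (!(interval_high_risk <= interval_low_risk &&
        interval_low_risk <= interval_clear))
    stop("surveillance intervals must satisfy high_risk <= low_risk <= clear")
  if (interval_high_risk <= 0) stop("surveillance intervals must be positive")
  structure(list(interval_high_risk = interval_high_risk,
                 interval_low_risk = interval_low_risk,
                 interval_clear = interval_clear,
                 max_surveillance_age = max_surveillance_age),
            class = "surveillance_policy")
}

size_class <- function(d) {
  ifelse(d < 6, "small", ifelse(d < 10, "medium", "large"))
}

sens_for_size <- function(chars, d) {
  ifelse(d < 6, chars$sens_small,
         ifelse(d < 10, chars$sens_medium, chars$sens_large))
}

new_exam_result <- function(age, modality, detected_ids, detected_crc,
                            sizes, false_positive = FALSE) {
  mx <- if (length(sizes)) {
    cls <- c("small", "medium", "large")
    cls[max(match(size_class(sizes), cls))]
  } else "none"
  structure(list(age = age, modality = modality,
                 detected_adenoma_ids = detected_ids,
                 detected_preclinical_crc = detected_crc,
                 max_detected_size_class = mx,
                 n_detected = length(detected_ids),
                 false_positive = false_positive),
            class = "exam_result")
}

#' Perform a colonoscopy on a natural history
#'
#' Each extant, unremoved adenoma is independently detected with the
#' size-class sensitivity at the exam age; detected adenomas are removed
#' (their future malignant transformation is cancelled).  An extant
#' preclinical cancer is detected with `sens_preclinical_crc`, giving a
#' screen-detected diagnosis whose stage is the stage-shifted one and
#' whose survival clock is anchored at the lesion's would-be clinical
#' diagnosis age (shared survival quantile across arms, so earlier
#' detection never shortens a given person's life).  Detection draws are
#' keyed by `(person, lesion, modality, exam ordinal)`, not by exam date,
#' so an exam that is merely delayed re-uses the same draws in every
#' counterfactual arm, while successive exams draw independently.
#'
#' @param nh a `natural_history` (see [sample_person()]).
#' @param age exam age; the person must be alive and undiagnosed.
#' @param chars colonoscopy [test_characteristics].
#' @param exam_ordinal 1-based ordinal of this colonoscopy within the
#'   person's colonoscopy sequence (keys the detection draws: a delayed
#'   exam keeps its ordinal and so re-uses the same draws across arms;
#'   successive exams draw independently).
#' @return list with elements `result` (an `exam_result`) and `history`
#'   (the updated `natural_history`: removals recorded in
#'   `$lesions$removed_age`, and `$screen_dx` set on diagnosis).
#' @export
perform_colonoscopy <- function(nh, age, chars, exam_ordinal = 1) {
  stopifnot(inherits(nh, "natural_history"),
            inherits(chars, "test_characteristics"))
  if (!identical(chars$modality, "colonoscopy"))
    stop("perform_colonoscopy requires colonoscopy characteristics")
  if (age >= nh$other_cause_death_age || !is.null(nh$screen_dx))
    stop("exam scheduled after death or diagnosis (engine bug)")
  L <- nh$lesions
  present <- L$init_age <= age & is.na(L$removed_age)
  pre <- present & L$transition_age <= age
  aden <- present & L$transition_age > age
  base <- exam_ordinal * 512

  detected_ids <- integer(0)
  sizes <- numeric(0)
  if (any(aden)) {
    j <- which(aden)
    d <- nh$params$d_inf - (nh$params$d_inf - nh$params$d0) *
      exp(-L$growth_rate[j] * (age - L$init_age[j]))
    u <- keyed_u01(nh$stream, "col_detect", base + j - 1)
    hit <- u < sens_for_size(chars, d)
    detected_ids <- L$id[j[hit]]
    sizes <- d[hit]
    L$removed_age[j[hit]] <- age
  }
  crc_hit <- FALSE
  if (any(pre)) {
    j <- which(pre)
    u <- keyed_u01(nh$stream, "col_crc", base + j - 1)
    hits <- j[u < chars$sens_preclinical_crc]
    if (length(hits)) {
      crc_hit <- TRUE
      jj <- hits[which.min(L$transition_age[hits])]
      anchor <- L$transition_age[jj] + L$sojourn[jj]
      stage <- L$stage_screen[jj]
      us <- keyed_u01(nh$stream, "survival", jj - 1)
      surv <- if (identical(nh$params$crc_survival_type, "fixed"))
        nh$params$crc_survival_rate_by_stage[stage]
      else -log(us) / nh$params$crc_survival_rate_by_stage[stage]
      nh$screen_dx <- list(age = age, stage = stage,
                           crc_death_age = anchor + surv, lesion = jj)
    }
  }
  nh$lesions <- L
  for (id in detected_ids) nh$adenomas[[id]]$removed_age <- age
  list(result = new_exam_result(age, "colonoscopy", detected_ids, crc_hit,
                                sizes),
       history = nh)
}

#' Perform a FIT exam
#'
#' The FIT is positive if any extant lesion triggers its per-lesion
#' sensitivity draw, or (with no true trigger) if the specificity draw
#' fails, a false positive.  Every positive FIT is followed by an
#' immediate diagnostic colonoscopy with the colonoscopy characteristics
#' in force.
#'
#' @inheritParams perform_colonoscopy
#' @param chars_fit FIT [test_characteristics].
#' @param chars_col colonoscopy characteristics used for the diagnostic
#'   colonoscopy cascade.
#' @param fit_ordinal 1-based ordinal of this FIT exam within the
#'   person's FIT sequence (keys the detection and false-positive draws).
#' @param col_ordinal colonoscopy ordinal to use for the diagnostic
#'   colonoscopy if the FIT is positive.
#' @return list with `result` (the FIT `exam_result`), `colonoscopy` (the
#'   diagnostic colonoscopy's `exam_result`, or `NULL` if the FIT was
#'   negative) and `history`.
#' @export
perform_fit <- function(nh, age, chars_fit, chars_col, fit_ordinal = 1,
                        col_ordinal = 1) {
  stopifnot(inherits(nh, "natural_history"),
            inherits(chars_fit, "test_characteristics"))
  if (!identical(chars_fit$modality, "fit"))
    stop("perform_fit requires FIT characteristics")
  if (age >= nh$other_cause_death_age || !is.null(nh$screen_dx))
    stop("exam scheduled after death or diagnosis (engine bug)")
  L <- nh$lesions
  present <- L$init_age <= age & is.na(L$removed_age)
  base <- fit_ordinal * 512
  pos <- FALSE
  if (any(present)) {
    j <- which(present)
    pre <- L$transition_age[j] <= age
    if (any(pre)) {
      u <- keyed_u01(nh$stream, "fit_crc", base + j[pre] - 1)
      if (any(u < chars_fit$sens_preclinical_crc)) pos <- TRUE
    }
    if (!pos && any(!pre)) {
      ja <- j[!pre]
      d <- nh$params$d_inf - (nh$params$d_inf - nh$params$d0) *
        exp(-L$growth_rate[ja] * (age - L$init_age[ja]))
      u <- keyed_u01(nh$stream, "fit_detect", base + ja - 1)
      if (any(u < sens_for_size(chars_fit, d))) pos <- TRUE
    }
  }
  fp <- FALSE
  if (!pos) {
    u <- keyed_u01(nh$stream, "fit_fp", fit_ordinal)
    if (u > chars_fit$specificity) { pos <- TRUE; fp <- TRUE }
  }
  res <- new_exam_result(age, "fit", integer(0), FALSE, numeric(0),
                         false_positive = fp)
  res$positive <- pos
  if (!pos) return(list(result = res, colonoscopy = NULL, history = nh))
  casc <- perform_colonoscopy(nh, age, chars_col, col_ordinal)
  list(result = res, colonoscopy = casc$result, history = casc$history)
}

#' Surveillance interval implied by a colonoscopy result
#'
#' Decision table: high-risk findings (>= 3 adenomas or any large one)
#' give `interval_high_risk`; 1-2 small/medium adenomas give
#' `interval_low_risk`; nothing found gives `NA` (return to the routine
#' regimen, no exam within `interval_clear`).
#'
#' @param res an `exam_result` from a (primary or diagnostic) colonoscopy.
#' @param policy a [surveillance_policy].
#' @return interval in years, or `NA` when no surveillance is indicated.
#' @export
next_surveillance_interval <- function(res, policy) {
  stopifnot(inherits(res, "exam_result"),
            inherits(policy, "surveillance_policy"))
  if (!identical(res$modality, "colonoscopy"))
    stop("surveillance intervals are assigned from colonoscopy results only")
  if (res$n_detected == 0) return(NA_real_)
  if (res$n_detected >= 3 || identical(res$max_detected_size_class, "large"))
    policy$interval_high_risk
  else policy$interval_low_risk
}

#' Replay a natural history under an exam schedule
#'
#' Reference (pure R) implementation of the screening replay: walks the
#' exam schedule, performing colonoscopies and FITs, applying polypectomy,
#' surveillance scheduling, the clear-colonoscopy routine skip, and the
#' disruption rules for surveillance exams straddling the pandemic onset.
#' The compiled engine used by [run_scenario()] implements the identical
#' contract; the two are cross-checked in the package tests.
#'
#' @param nh a `natural_history`.
#' @param schedule data frame with columns `age`, `modality`, sorted by age.
#' @param chars_col,chars_fit [test_characteristics].
#' @param policy a [surveillance_policy].
#' @param ref_age age from which life-years are counted.
#' @param onset_age pandemic onset age (disruption rules apply to
#'   surveillance exams falling at or after it).
#' @param surv_delay delay (years) added to surveillance exams owed from
#'   pre-onset findings that fall after the onset.
#' @param allow_post_surv if `FALSE` (discontinuation), no surveillance
#'   exam takes place at or after the onset.
#' @param min_post_exam earliest allowed post-onset exam age (long-term
#'   delay scenarios).
#' @return list with `ly`, `death_age`, `dx_age` (`NA` if none),
#'   `dx_mode` (`"none"`, `"clinical"`, `"screen"`) and `dx_stage`.
#' @export
replay_history <- function(nh, schedule, chars_col, chars_fit, policy,
                           ref_age, onset_age = Inf, surv_delay = 0,
                           allow_post_surv = TRUE, min_post_exam = 0) {
  stopifnot(inherits(nh, "natural_history"))
  eps <- 1e-9
  L0 <- nh$lesions
  nh$screen_dx <- NULL
  nh$lesions$removed_age <- rep(NA_real_, nrow(nh$lesions))
  surv_due <- Inf
  resume_at <- -Inf
  fit_ord <- 0
  col_ord <- 0
  si <- 1
  ages <- schedule$age
  mods <- schedule$modality
  ns <- length(ages)
  other <- nh$other_cause_death_age

  clinical_next <- function() {
    L <- nh$lesions
    ok <- is.na(L$removed_age)
    if (!any(ok)) return(list(age = Inf, j = NA))
    d <- L$transition_age[ok] + L$sojourn[ok]
    k <- which.min(d)
    list(age = d[k], j = which(ok)[k])
  }

  after_col <- function(res, age) {
    resume_at <<- age + policy$interval_clear - eps
    int <- next_surveillance_interval(res, policy)
    if (is.na(int)) { surv_due <<- Inf; return(invisible()) }
    due <- age + int
    if (age < onset_age && due >= onset_age) {
      due <- max(due + surv_delay, min_post_exam)
    }
    cancel <- due > policy$max_surveillance_age ||
      (due >= onset_age && !allow_post_surv)
    surv_due <<- if (cancel) Inf else due
    invisible()
  }

  dx <- NULL
  repeat {
    cn <- clinical_next()
    while (si <= ns && ages[si] < resume_at) si <- si + 1
    base_age <- if (si <= ns) ages[si] else Inf
    if (surv_due <= base_age) {
      ex_age <- surv_due; ex_kind <- "surv"
    } else {
      ex_age <- base_age; ex_kind <- mods[si]
    }
    if (!(ex_age < cn$age && ex_age < other)) break
    if (ex_kind %in% c("surv", "colonoscopy")) {
      if (ex_kind == "surv") surv_due <- Inf else si <- si + 1
      col_ord <- col_ord + 1
      out <- perform_colonoscopy(nh, ex_age, chars_col, col_ord)
      nh <- out$history
      if (!is.null(nh$screen_dx)) {
        dx <- list(age = ex_age, mode = "screen",
                   stage = nh$screen_dx$stage,
                   crc_death = nh$screen_dx$crc_death_age)
        break
      }
      after_col(out$result, ex_age)
    } else {
      si <- si + 1
      fit_ord <- fit_ord + 1
      out <- perform_fit(nh, ex_age, chars_fit, chars_col, fit_ord,
                         col_ordinal = col_ord + 1)
      nh <- out$history
      if (!is.null(out$colonoscopy)) col_ord <- col_ord + 1
      if (!is.null(nh$screen_dx)) {
        dx <- list(age = ex_age, mode = "screen",
                   stage = nh$screen_dx$stage,
                   crc_death = nh$screen_dx$crc_death_age)
        break
      }
      if (!is.null(out$colonoscopy)) after_col(out$colonoscopy, ex_age)
    }
  }

  crc_death <- Inf
  if (is.null(dx)) {
    cn <- clinical_next()
    if (cn$age < other) {
      stage <- nh$lesions$stage_clinical[cn$j]
      us <- keyed_u01(nh$stream, "survival", cn$j - 1)
      surv <- if (identical(nh$params$crc_survival_type, "fixed"))
        nh$params$crc_survival_rate_by_stage[stage]
      else -log(us) / nh$params$crc_survival_rate_by_stage[stage]
      dx <- list(age = cn$age, mode = "clinical", stage = stage,
                 crc_death = cn$age + surv)
    }
  }
  if (!is.null(dx)) crc_death <- dx$crc_death
  death <- min(other, crc_death)
  list(ly = max(0, death - ref_age), death_age = death,
       dx_age = if (is.null(dx)) NA_real_ else dx$age,
       dx_mode = if (is.null(dx)) "none" else dx$mode,
       dx_stage = if (is.null(dx)) NA_integer_ else dx$stage)
}
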