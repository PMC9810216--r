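#' Keyed random streams
#'
#' All randomness in the simulator is drawn from counter-based streams: a
#' uniform deviate is a pure function of the key
#' `(master_seed, person_id, attempt, purpose, counter)`.  The same key
#' always yields the same deviate, regardless of the order in which persons
#' or screening arms are simulated.  This is what makes the paired
#' counterfactual arms of a scenario share "common random numbers": a
#' lesion's detection draw at colonoscopy, say, is keyed by the lesion, not
#' by the exam date, so a delayed exam re-uses the same draw and the paired
#' difference between arms isolates the timing effect.
#'
#' @param master_seed integer master seed of the run.
#' @param person_id 1-based person index within a cohort.
#' @param attempt rejection-sampling attempt counter (0-based); conditioned
#'   cohort members record the attempt at which they were accepted.
#' @return `sim_stream()` returns an object of class `sim_stream`.
#' @examples
#' s <- sim_stream(42, person_id = 7)
#' keyed_u01(s, "col_detect", counter = 0:2)
#' @export
sim_stream <- function(master_seed, person_id, attempt = 0) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1,
            is.numeric(person_id), person_id >= 1,
            is.numeric(attempt), attempt >= 0)
  structure(list(master_seed = as.numeric(master_seed),
                 person_id = as.numeric(person_id),
                 attempt = as.numeric(attempt)),
            class = "sim_stream")
}

# purpose codes; must stay in sync with the Purpose enum in src/sim.cpp
purpose_codes <- function() {
  c(psi = 1, other_death = 2, adenoma_count = 3, adenoma_time = 4,
    growth = 5, transition = 6, sojourn = 7, stage = 8, stage_shift = 9,
    survival = 10, col_detect = 11, fit_detect = 12, col_crc = 13,
    fit_crc = 14, fit_fp = 15)
}

#' @rdname sim_stream
#' @param stream a `sim_stream`.
#' @param purpose one of the named draw purposes (`"psi"`, `"other_death"`,
#'   `"adenoma_count"`, `"adenoma_time"`, `"growth"`, `"transition"`,
#'   `"sojourn"`, `"stage"`, `"stage_shift"`, `"survival"`, `"col_detect"`,
#'   `"fit_detect"`, `"col_crc"`, `"fit_crc"`, `"fit_fp"`).
#' @param counter non-negative integer counter (vectorised), e.g. the
#'   0-based lesion ordinal or the FIT exam ordinal.
#' @return `keyed_u01()` returns a numeric vector of deviates in (0, 1).
#' @export
keyed_u01 <- function(stream, purpose, counter = 0) {
  if (is.character(purpose)) {
    p <- .purpose_lookup[[purpose]]
    if (is.null(p)) stop("unknown draw purpose: ", purpose)
    purpose <- p
  }
  cpp_keyed_u01(stream$master_seed, stream$person_id, stream$attempt,
                purpose, as.numeric(counter))
}

.purpose_lookup <- as.list(purpose_codes())
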