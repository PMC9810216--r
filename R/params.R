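#' Natural-history parameters
#'
#' Parameter set for the adenoma-carcinoma natural-history model.  A
#' person's adenomas arise from a non-homogeneous Poisson process whose
#' log-intensity is a person-level normal deviate (risk heterogeneity) plus
#' a piecewise-linear function of age; each adenoma grows along a
#' von-Bertalanffy curve towards `d_inf`, transforms to preclinical cancer
#' with hazard proportional to its diameter, dwells a lognormal sojourn
#' time before clinical presentation, and receives a clinical stage (I-IV)
#' that is shifted towards earlier stages when the cancer is instead found
#' by screening.
#'
#' @param baseline_log_risk_mean,baseline_log_risk_sd mean and SD of the
#'   person-level log-risk deviate added to the age log-intensity.
#' @param age_intensity_knots data frame (or 2-column matrix) with columns
#'   `age` (years) and `log_intensity` (log adenomas per person-year);
#'   piecewise linear between knots, flat outside them, zero below age 20.
#' @param growth_time_to_10mm_scale,growth_time_to_10mm_shape scale
#'   (years) and shape of the Frechet distribution of the time for an
#'   adenoma to reach 10 mm.
#' @param d0,d_inf initial and asymptotic adenoma diameters (mm); the
#'   10 mm threshold must satisfy `d0 < 10 < d_inf`.
#' @param transition_hazard_per_mm malignant-transformation hazard per
#'   year per mm of current diameter.
#' @param sojourn_meanlog,sojourn_sdlog lognormal parameters of the
#'   preclinical (screen-detectable) sojourn time in years.
#' @param stage_probs_clinical length-4 stage distribution (I-IV) at
#'   clinical presentation; must sum to 1.
#' @param stage_shift_screen 4x4 row-stochastic matrix; row k is the stage
#'   distribution of a screen-detected cancer whose clinical stage would
#'   have been k.
#' @param crc_survival_rate_by_stage length-4 exponential excess-death
#'   rates (per year) after diagnosis, by stage.
#' @param lifetable a [lifetable] for other-cause mortality.
#' @param crc_survival_type `"exponential"` (default) or `"fixed"`; with
#'   `"fixed"`, `crc_survival_rate_by_stage` is read as deterministic
#'   survival years by stage (used by the deterministic toy fixture).
#' @param fixed_history optional list `list(adenoma_init_age =,
#'   transition_age =)`; when given, every person has exactly one adenoma
#'   with those deterministic ages (toy fixture mode).
#' @return object of class `nh_params`.
#' @export
nh_params <- function(baseline_log_risk_mean, baseline_log_risk_sd,
                      age_intensity_knots,
                      growth_time_to_10mm_scale, growth_time_to_10mm_shape,
                      d0, d_inf, transition_hazard_per_mm,
                      sojourn_meanlog, sojourn_sdlog,
                      stage_probs_clinical, stage_shift_screen,
                      crc_survival_rate_by_stage, lifetable,
                      crc_survival_type = c("exponential", "fixed"),
                      fixed_history = NULL) {
  crc_survival_type <- match.arg(crc_survival_type)
  kn <- as.data.frame(age_intensity_knots)
  names(kn) <- c("age", "log_intensity")
  chk <- function(ok, key, what)
    if (!isTRUE(ok)) stop(sprintf("invalid natural-history parameter '%s': %s",
                                  key, what), call. = FALSE)
  chk(is.numeric(baseline_log_risk_sd) && baseline_log_risk_sd >= 0,
      "baseline_log_risk_sd", "must be non-negative")
  chk(nrow(kn) >= 1 && !is.unsorted(kn$age, strictly = TRUE),
      "age_intensity_knots", "ages must be strictly increasing")
  chk(growth_time_to_10mm_scale > 0, "growth_time_to_10mm_scale",
      "must be strictly positive")
  chk(growth_time_to_10mm_shape > 0, "growth_time_to_10mm_shape",
      "must be strictly positive")
  chk(d0 > 0 && d0 < 10 && d_inf > 10, "d0/d_inf",
      "must satisfy 0 < d0 < 10 < d_inf")
  chk(transition_hazard_per_mm > 0, "transition_hazard_per_mm",
      "must be strictly positive")
  chk(sojourn_sdlog >= 0, "sojourn_sdlog", "must be non-negative")
  chk(length(stage_probs_clinical) == 4 &&
        all(stage_probs_clinical >= 0) &&
        abs(sum(stage_probs_clinical) - 1) <= 1e-12,
      "stage_probs_clinical", "must be a 4-vector summing to 1")
  ss <- as.matrix(stage_shift_screen)
  chk(all(dim(ss) == c(4, 4)) && all(ss >= 0) &&
        all(abs(rowSums(ss) - 1) <= 1e-12),
      "stage_shift_screen", "must be 4x4 row-stochastic")
  chk(length(crc_survival_rate_by_stage) == 4 &&
        all(crc_survival_rate_by_stage > 0),
      "crc_survival_rate_by_stage", "must be 4 positive values")
  chk(inherits(lifetable, "lifetable"), "lifetable",
      "must be a lifetable object")
  if (!is.null(fixed_history)) {
    chk(is.list(fixed_history) &&
          all(c("adenoma_init_age", "transition_age",
                "sojourn_years") %in% names(fixed_history)) &&
          fixed_history$transition_age > fixed_history$adenoma_init_age &&
          fixed_history$sojourn_years > 0,
        "fixed_history",
        "needs adenoma_init_age < transition_age and sojourn_years > 0")
  }
  structure(list(
    baseline_log_risk_mean = baseline_log_risk_mean,
    baseline_log_risk_sd = baseline_log_risk_sd,
    age_intensity_knots = kn,
    growth_time_to_10mm_scale = growth_time_to_10mm_scale,
    growth_time_to_10mm_shape = growth_time_to_10mm_shape,
    d0 = d0, d_inf = d_inf,
    transition_hazard_per_mm = transition_hazard_per_mm,
    sojourn_meanlog = sojourn_meanlog, sojourn_sdlog = sojourn_sdlog,
    stage_probs_clinical = as.numeric(stage_probs_clinical),
    stage_shift_screen = ss,
    crc_survival_rate_by_stage = as.numeric(crc_survival_rate_by_stage),
    crc_survival_type = crc_survival_type,
    lifetable = lifetable,
    fixed_history = fixed_history), class = "nh_params")
}

# flatten an nh_params into the list the C++ core consumes
nh_params_cpp <- function(p) {
  stopifnot(inherits(p, "nh_params"))
  list(toy = !is.null(p$fixed_history),
       toy_init = p$fixed_history$adenoma_init_age %||% 0,
       toy_trans = p$fixed_history$transition_age %||% 0,
       toy_soj = p$fixed_history$sojourn_years %||% 0,
       psi_mean = p$baseline_log_risk_mean,
       psi_sd = p$baseline_log_risk_sd,
       knot_ages = as.numeric(p$age_intensity_knots$age),
       knot_logint = as.numeric(p$age_intensity_knots$log_intensity),
       growth_scale = p$growth_time_to_10mm_scale,
       growth_shape = p$growth_time_to_10mm_shape,
       d0 = p$d0, d_inf = p$d_inf,
       beta = p$transition_hazard_per_mm,
       soj_meanlog = p$sojourn_meanlog, soj_sdlog = p$sojourn_sdlog,
       stage_probs = p$stage_probs_clinical,
       stage_shift = p$stage_shift_screen,
       surv_fixed = identical(p$crc_survival_type, "fixed"),
       surv_by_stage = p$crc_survival_rate_by_stage,
       lt_cumhaz = p$lifetable$cumulative_hazard,
       age_min = 20, age_max = 110)
}

# ------------------------------------------------------------------
# configuration files

config_err <- function(path, what)
  stop(sprintf("config error at '%s': %s", path, what), call. = FALSE)

need <- function(x, key, path) {
  if (is.null(x[[key]])) config_err(paste(path, key, sep = "/"), "missing key")
  x[[key]]
}

parse_lifetable_cfg <- function(cfg, path) {
  type <- need(cfg, "type", path)
  if (type == "gompertz") {
    build_gompertz_lifetable(need(cfg, "a", path), need(cfg, "b", path),
                             cfg$makeham %||% 0)
  } else if (type == "fixed_age") {
    fixed_age_lifetable(need(cfg, "age", path))
  } else {
    config_err(paste0(path, "/type"), "must be 'gompertz' or 'fixed_age'")
  }
}

parse_nh_cfg <- function(cfg, path) {
  kn <- need(cfg, "age_intensity_knots", path)
  gr <- need(cfg, "growth_time_to_10mm", path)
  so <- need(cfg, "sojourn", path)
  sv <- need(cfg, "crc_survival", path)
  sv_type <- need(sv, "type", paste0(path, "/crc_survival"))
  sv_vals <- if (sv_type == "fixed") {
    need(sv, "years_by_stage", paste0(path, "/crc_survival"))
  } else if (sv_type == "exponential") {
    need(sv, "rate_by_stage", paste0(path, "/crc_survival"))
  } else config_err(paste0(path, "/crc_survival/type"),
                    "must be 'exponential' or 'fixed'")
  shift <- need(cfg, "stage_shift_screen", path)
  if (is.list(shift)) shift <- do.call(rbind, shift)
  out <- try(nh_params(
    baseline_log_risk_mean = need(cfg, "baseline_log_risk_mean", path),
    baseline_log_risk_sd = need(cfg, "baseline_log_risk_sd", path),
    age_intensity_knots = data.frame(
      age = need(kn, "ages", paste0(path, "/age_intensity_knots")),
      log_intensity = need(kn, "log_intensity",
                           paste0(path, "/age_intensity_knots"))),
    growth_time_to_10mm_scale = need(gr, "scale", paste0(path, "/growth_time_to_10mm")),
    growth_time_to_10mm_shape = need(gr, "shape", paste0(path, "/growth_time_to_10mm")),
    d0 = need(cfg, "d0", path), d_inf = need(cfg, "d_inf", path),
    transition_hazard_per_mm = need(cfg, "transition_hazard_per_mm", path),
    sojourn_meanlog = need(so, "meanlog", paste0(path, "/sojourn")),
    sojourn_sdlog = need(so, "sdlog", paste0(path, "/sojourn")),
    stage_probs_clinical = unlist(need(cfg, "stage_probs_clinical", path)),
    stage_shift_screen = shift,
    crc_survival_rate_by_stage = unlist(sv_vals),
    crc_survival_type = sv_type,
    lifetable = parse_lifetable_cfg(need(cfg, "lifetable", path),
                                    paste0(path, "/lifetable")),
    fixed_history = cfg$fixed_history), silent = TRUE)
  if (inherits(out, "try-error"))
    config_err(path, conditionMessage(attr(out, "condition")))
  out
}

parse_chars_cfg <- function(cfg, modality, path) {
  fields <- c("sens_small", "sens_medium", "sens_large",
              "sens_preclinical_crc", "specificity")
  vals <- lapply(fields, function(f) need(cfg, f, path))
  out <- try(do.call(test_characteristics,
                     c(list(modality = modality), setNames(vals, fields))),
             silent = TRUE)
  if (inherits(out, "try-error"))
    config_err(path, conditionMessage(attr(out, "condition")))
  out
}

#' Load and validate a simulation configuration
#'
#' Configurations are YAML files with three top-level blocks:
#' `natural_history` (named parameter sets, e.g. `model_a`, `model_b`),
#' `test_characteristics` (named sensitivity scenarios, each with a
#' `colonoscopy` and a `fit` block), and `surveillance` (post-polypectomy
#' surveillance policy).  Validation errors name the offending key path.
#'
#' @param path path to a YAML configuration file.
#' @return a `sim_config` object: list with elements `natural_history`
#'   (named list of [nh_params]), `test_characteristics` (named list with
#'   `$colonoscopy` and `$fit` [test_characteristics]), `surveillance`
#'   (a [surveillance_policy]) and `source` (the file path).
#' @seealso [default_config()], [make_toy_fixture()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  nh_raw <- need(raw, "natural_history", "")
  if (!length(names(nh_raw))) config_err("natural_history",
                                         "needs at least one named parameter set")
  nh <- lapply(names(nh_raw), function(nm)
    parse_nh_cfg(nh_raw[[nm]], paste0("natural_history/", nm)))
  names(nh) <- names(nh_raw)
  tc_raw <- need(raw, "test_characteristics", "")
  tc <- lapply(names(tc_raw), function(nm) {
    blk <- tc_raw[[nm]]
    p <- paste0("test_characteristics/", nm)
    list(colonoscopy = parse_chars_cfg(need(blk, "colonoscopy", p),
                                       "colonoscopy", paste0(p, "/colonoscopy")),
         fit = parse_chars_cfg(need(blk, "fit", p), "fit", paste0(p, "/fit")))
  })
  names(tc) <- names(tc_raw)
  if (!length(tc)) config_err("test_characteristics",
                              "needs at least one named sensitivity scenario")
  sv <- need(raw, "surveillance", "")
  pol <- try(surveillance_policy(
    interval_high_risk = need(sv, "interval_high_risk", "surveillance"),
    interval_low_risk = need(sv, "interval_low_risk", "surveillance"),
    interval_clear = need(sv, "interval_clear", "surveillance"),
    max_surveillance_age = need(sv, "max_surveillance_age", "surveillance")),
    silent = TRUE)
  if (inherits(pol, "try-error"))
    config_err("surveillance", conditionMessage(attr(pol, "condition")))
  structure(list(natural_history = nh, test_characteristics = tc,
                 surveillance = pol, source = path),
            class = "sim_config")
}

#' @rdname load_config
#' @details `default_config()` loads the configuration shipped with the
#'   package (`inst/extdata/default_params.yaml`): two natural-history
#'   parameter sets (`model_a`, `model_b`) whose min-max across runs
#'   emulates a cross-model range, and `high_sensitivity` /
#'   `low_sensitivity` test-characteristic scenarios.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_params.yaml",
                          package = "crcdisrupt", mustWork = TRUE))
}
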