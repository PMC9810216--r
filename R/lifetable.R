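#' Life tables for other-cause mortality
#'
#' A life table is the cumulative all-cause (non-CRC) hazard evaluated on a
#' one-year age grid from 0 to 110; the hazard is piecewise constant within
#' bins and treated as infinite beyond age 110, so every simulated person
#' has a finite other-cause death age at or below 110.
#'
#' `build_gompertz_lifetable()` builds the table from a Gompertz-Makeham
#' hazard h(t) = makeham + a e^(b t), whose cumulative hazard is
#' H(t) = makeham t + (a/b)(e^(b t) - 1).  `a = 0` is accepted as the
#' constant-hazard (pure Makeham) limit.
#'
#' @param a Gompertz baseline (per year); `a = 0` gives a constant hazard.
#' @param b Gompertz slope (per year); must be positive when `a > 0`.
#' @param makeham age-independent hazard component (per year).
#' @return an object of class `lifetable` with fields `ages` (0:110) and
#'   `cumulative_hazard`.
#' @examples
#' lt <- build_gompertz_lifetable(a = 1e-4, b = 0.09, makeham = 1e-3)
#' life_expectancy(lt)
#' @export
build_gompertz_lifetable <- function(a, b, makeham = 0) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a < 0)
    stop("lifetable parameter 'a' must be a non-negative number")
  if (!is.numeric(b) || length(b) != 1 || is.na(b) || (a > 0 && b <= 0))
    stop("lifetable parameter 'b' must be positive when a > 0")
  if (!is.numeric(makeham) || length(makeham) != 1 || makeham < 0)
    stop("lifetable parameter 'makeham' must be non-negative")
  ages <- 0:110
  H <- makeham * ages + if (a > 0) (a / b) * (exp(b * ages) - 1) else 0
  lifetable(ages, H)
}

#' @rdname build_gompertz_lifetable
#' @param ages integer age grid; must be `0:110`.
#' @param cumulative_hazard non-decreasing cumulative hazard at `ages`,
#'   starting at 0.
#' @export
lifetable <- function(ages, cumulative_hazard) {
  if (!identical(as.integer(ages), 0:110))
    stop("lifetable ages must be the grid 0:110")
  H <- as.numeric(cumulative_hazard)
  if (length(H) != 111 || any(is.na(H)) || H[1] != 0 || any(diff(H) < 0))
    stop("lifetable cumulative_hazard must start at 0 and be non-decreasing")
  structure(list(ages = 0:110, cumulative_hazard = H), class = "lifetable")
}

#' @rdname build_gompertz_lifetable
#' @param age age at which everyone dies (deterministic life table, used by
#'   the toy fixture).
#' @export
fixed_age_lifetable <- function(age) {
  stopifnot(age > 0, age < 110)
  ages <- 0:110
  # post-`age` hazard so large that the interpolated death age rounds to
  # `age` exactly in double precision, while H stays finite
  H <- ifelse(ages <= age, 0, (ages - age) * 1e300)
  lifetable(ages, H)
}

#' Life expectancy implied by a life table
#'
#' Exact integral of the survival curve implied by the piecewise-constant
#' hazard, including the mass of survivors dying at the age-110 boundary.
#'
#' @param lt a `lifetable`.
#' @param from age (integer, in 0..109) from which to measure; conditional
#'   on survival to `from`.
#' @return expected remaining years of life.
#' @export
life_expectancy <- function(lt, from = 0) {
  stopifnot(inherits(lt, "lifetable"), from >= 0, from < 110,
            from == as.integer(from))
  H <- lt$cumulative_hazard
  h <- diff(H)                       # bin hazards, ages k..k+1
  k <- (from + 1):110                # bin indices into h
  Hc <- H[k] - H[from + 1]           # cumulative hazard since `from`
  S <- exp(-Hc)                      # survival at bin starts
  hk <- h[k]
  w <- ifelse(hk > 0, (1 - exp(-hk)) / hk, 1)
  sum(S * w)
}

# inverse-cumulative-hazard sampling, R reference used in tests
invert_lifetable_r <- function(lt, u) {
  H <- lt$cumulative_hazard
  E <- -log(u)
  vapply(E, function(e) {
    if (e >= H[111]) return(110)
    k <- findInterval(e, H, left.open = FALSE)  # H[k] <= e < H[k+1]
    while (H[k + 1] == H[k]) k <- k + 1
    (k - 1) + (e - H[k]) / (H[k + 1] - H[k])
  }, numeric(1))
}
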