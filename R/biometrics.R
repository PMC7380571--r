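#' Von Bertalanffy growth parameters
#'
#' Parameters of the von Bertalanffy growth function
#' L(A) = L_inf (1 - e^(-k (A - t0))): `L_inf` the theoretical maximum fork
#' length (mm), `k` the growth coefficient (1/yr), `t0` the theoretical age
#' at length zero (yr). Stock assessments sometimes publish two growth
#' coefficients — a juvenile and an adult regime — so an optional second
#' regime `(k_old, split_age)` is supported: below `split_age` the first
#' coefficient applies, above it the second, with the curve kept continuous
#' at the split. Parameter values must come from the relevant stock
#' assessment; there are no biological defaults.
#'
#' @param L_inf theoretical maximum length, mm (> 0).
#' @param k growth coefficient, 1/yr (> 0).
#' @param t0 theoretical age at length 0, yr.
#' @param k_old optional second (older-age) growth coefficient, 1/yr.
#' @param split_age age (yr) at which the regime switches; required with
#'   `k_old`.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(L_inf, k, t0 = 0, k_old = NULL, split_age = NULL) {
  if (L_inf <= 0) stop("L_inf must be positive")
  if (k <= 0) stop("k must be positive")
  if (!is.null(k_old)) {
    if (is.null(split_age)) stop("split_age required with a second regime")
    if (k_old <= 0) stop("k_old must be positive")
    if (split_age <= t0) stop("split_age must exceed t0")
    # continuity: pick t0_old so both regimes give the same length at the split
    L_split <- L_inf * (1 - exp(-k * (split_age - t0)))
    t0_old <- split_age + log(1 - L_split / L_inf) / k_old
  } else {
    split_age <- Inf
    k_old <- k
    t0_old <- t0
  }
  structure(list(L_inf = L_inf, k = k, t0 = t0, k_old = k_old,
                 split_age = split_age, t0_old = t0_old),
            class = "growth_params")
}

#' Length at age under von Bertalanffy growth
#'
#' @param age age in years (>= t0); vectorized.
#' @param p a [growth_params()] object.
#' @return fork length in mm; strictly increasing in age, bounded by
#'   `L_inf`.
#' @export
length_at_age <- function(age, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(age < p$t0)) stop("age below t0: length undefined")
  young <- age <= p$split_age
  out <- numeric(length(age))
  out[young] <- p$L_inf * (1 - exp(-p$k * (age[young] - p$t0)))
  out[!young] <- p$L_inf * (1 - exp(-p$k_old * (age[!young] - p$t0_old)))
  out
}

#' Age from length (inverse von Bertalanffy)
#'
#' Exact algebraic inverse of [length_at_age()]:
#' A = t0 - ln(1 - L / L_inf) / k, dispatched to the regime whose age range
#' contains the result.
#'
#' @param length fork length in mm, 0 <= length < L_inf; vectorized.
#' @param p a [growth_params()] object.
#' @return age in years.
#' @export
age_from_length <- function(length, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(length < 0)) stop("negative length")
  if (any(length >= p$L_inf))
    stop("length exceeds theoretical maximum L_inf")
  age <- p$t0 - log(1 - length / p$L_inf) / p$k
  if (is.finite(p$split_age)) {
    old <- age > p$split_age
    age[old] <- p$t0_old - log(1 - length[old] / p$L_inf) / p$k_old
  }
  age
}

#' Fulton's condition factor
#'
#' K = 100 * mass / length^3 with mass in grams and length in centimeters —
#' the standard convention, giving values near 1 for fusiform fish. The
#' constant and units are explicit arguments so alternative conventions can
#' be reproduced exactly. Values above `warn_above` (default 5) are
#' biologically implausible for whole fish and trigger a warning, usually
#' indicating a unit mix-up.
#'
#' @param mass_g body mass in grams (> 0); vectorized.
#' @param length_cm fork length in centimeters (> 0); vectorized.
#' @param constant scaling constant (default 100).
#' @param warn_above plausibility bound for a sanity warning.
#' @return condition factor K.
#' @export
fulton_k <- function(mass_g, length_cm, constant = 100, warn_above = 5) {
  if (any(mass_g <= 0)) stop("mass must be positive")
  if (any(length_cm <= 0)) stop("length must be positive")
  k <- constant * mass_g / length_cm^3
  if (any(k > warn_above))
    warning(sprintf("condition factor above %g (max %.3g): check units",
                    warn_above, max(k)))
  k
}

#' Append derived biometrics to sample metadata
#'
#' Adds `age_yr` (inverse von Bertalanffy of `fork_length_mm`) and
#' `condition_k` (Fulton's K from `mass_kg` and `fork_length_mm`, converted
#' internally to g and cm) for fish body-site samples; environmental samples
#' keep NA.
#'
#' @param metadata sample metadata with `fork_length_mm` and `mass_kg`.
#' @param p a [growth_params()] object.
#' @return the metadata with `age_yr` and `condition_k` columns.
#' @export
add_biometrics <- function(metadata, p) {
  md <- metadata
  fish <- md$sample_type %in% fish_body_sites() & !is.na(md$fork_length_mm)
  md$age_yr <- NA_real_
  md$condition_k <- NA_real_
  md$age_yr[fish] <- age_from_length(md$fork_length_mm[fish], p)
  has_mass <- fish & !is.na(md$mass_kg)
  md$condition_k[has_mass] <- fulton_k(md$mass_kg[has_mass] * 1000,
                                       md$fork_length_mm[has_mass] / 10)
  md
}
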