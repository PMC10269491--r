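# Domain types: age bands, calibration constants, life expectancies.

#' Variables entering the biological-age formula
#'
#' The five inputs of the composite clock, in canonical order: relative
#' telomere length (`RTL`, dimensionless T/S ratio), serum iron (`Fe`,
#' ug/dL), total iron-binding capacity (`TIBC`, ug/dL), serum ferritin
#' (`F`, ug/L) and chronological age (`a`, years).
#'
#' @export
BIOAGE_VARS <- c("RTL", "Fe", "TIBC", "F", "a")

# ug/dL of elemental iron per umol/L (atomic mass of iron, 55.845 g/mol,
# over the dL-per-L factor of 10).
IRON_UGDL_PER_UMOL <- 5.5845

#' Calibration age bands
#'
#' The clock is calibrated separately in two age bands because several of
#' its inputs trend differently with age in young adults and in older
#' adults.  The bands are closed intervals: younger = \[19, 35\] years,
#' older = \[50, 77\] years.
#'
#' @param label `"younger"` or `"older"`.
#' @return An object of class `"age_band"`: a list with elements `label`,
#'   `lower` and `upper` (years).
#' @examples
#' age_band("younger")
#' @export
age_band <- function(label = c("younger", "older")) {
  label <- match.arg(label)
  b <- switch(label,
    younger = list(label = "younger", lower = 19, upper = 35),
    older   = list(label = "older",   lower = 50, upper = 77)
  )
  structure(b, class = "age_band")
}

#' @export
print.age_band <- function(x, ...) {
  cat(sprintf("<age_band> %s: [%g, %g] years\n", x$label, x$lower, x$upper))
  invisible(x)
}

#' Construct a set of calibration constants
#'
#' Bundles everything needed to evaluate the biological-age formula in one
#' band: per-variable normalization moments (`mu`, `sigma`), the per-year
#' slopes `k_X` (and intercepts `n_X`) of each normalized variable against
#' age in the referent population, the scaling factor `k = 1 / sum(|k_X|)`,
#' the additive constant `C`, and the two life-expectancy adjustments.
#'
#' @param band An [age_band()] object or its label.
#' @param mu,sigma Named numeric vectors over [BIOAGE_VARS]: referent
#'   means and standard deviations.  All `sigma` must be positive.
#' @param slope Named numeric vector of normalized-variable-vs-age slopes
#'   `k_X` (per year).
#' @param intercept Named numeric vector of fit intercepts `n_X`; may be
#'   `NA` when only the printed constants (which omit the intercepts but
#'   include `C`) are available.
#' @param k Scaling factor; must be positive and consistent with
#'   `1 / sum(|slope|)` to within `k_tol`.
#' @param C Additive constant (years).
#' @param delta_hiv_neg Population life-expectancy adjustment per year of
#'   age (dimensionless); multiplied by `a` in the formula.
#' @param delta_hiv_pos HIV life-expectancy adjustment per year since age
#'   20 (dimensionless); multiplied by `(a - 20)` for HIV-positive
#'   subjects only.
#' @param k_tol Absolute tolerance for the `k` consistency check.  The
#'   default 0.01 accommodates constants re-derived from slopes printed at
#'   4 decimal places.
#' @return An object of class `"calibration_constants"`.
#' @seealso [reference_constants()] for the built-in published values,
#'   [calibrate()] to derive constants from a referent population.
#' @export
calibration_constants <- function(band, mu, sigma, slope, intercept,
                                  k, C, delta_hiv_neg = 0, delta_hiv_pos = 0,
                                  k_tol = 0.01) {
  if (is.character(band)) band <- age_band(band)
  stopifnot(inherits(band, "age_band"))
  for (nm in c("mu", "sigma", "slope", "intercept")) {
    v <- get(nm)
    if (!is.numeric(v) || !setequal(names(v), BIOAGE_VARS)) {
      stop(sprintf("'%s' must be a numeric vector named over {%s}",
                   nm, paste(BIOAGE_VARS, collapse = ", ")), call. = FALSE)
    }
  }
  mu <- mu[BIOAGE_VARS]; sigma <- sigma[BIOAGE_VARS]
  slope <- slope[BIOAGE_VARS]; intercept <- intercept[BIOAGE_VARS]
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all sigma must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) stop("k must be finite and > 0", call. = FALSE)
  k_implied <- 1 / sum(abs(slope))
  if (abs(k - k_implied) > k_tol) {
    stop(sprintf(
      "k = %.6g inconsistent with 1/sum(|k_X|) = %.6g (tolerance %g)",
      k, k_implied, k_tol), call. = FALSE)
  }
  structure(
    list(band = band, mu = mu, sigma = sigma,
         slope = slope, intercept = intercept,
         k = k, C = C,
         delta_hiv_neg = delta_hiv_neg, delta_hiv_pos = delta_hiv_pos),
    class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, digits = 6, ...) {
  cat(sprintf("<calibration_constants> band %s [%g, %g]\n",
              x$band$label, x$band$lower, x$band$upper))
  tab <- rbind(mu = x$mu, sigma = x$sigma, k_X = x$slope, n_X = x$intercept)
  print(signif(tab, digits))
  cat(sprintf("k = %s, C = %s, delta_hiv_neg = %s, delta_hiv_pos = %s\n",
              format(x$k, digits = digits), format(x$C, digits = digits),
              format(x$delta_hiv_neg, digits = digits),
              format(x$delta_hiv_pos, digits = digits)))
  invisible(x)
}

# Published referent-population constants, exactly as printed.
# Iron and TIBC are in ug/dL, ferritin in ug/L, age in years.
.reference_table <- list(
  younger = list(
    mu    = c(RTL = 1.1674, Fe = 106.701,  TIBC = 350.4698, F = 141.099,  a = 27.4770),
    sigma = c(RTL = 0.2699, Fe = 40.65551, TIBC = 48.50848, F = 87.18172, a = 4.7178),
    slope = c(RTL = -0.0432, Fe = -0.0270, TIBC = -0.0183,  F = 0.0608,   a = 0.2120),
    k = 2.7681, C = 27.4907
  ),
  older = list(
    mu    = c(RTL = 0.9310, Fe = 92.84552, TIBC = 340.4459, F = 195.7973, a = 64.0432),
    sigma = c(RTL = 0.2211, Fe = 34.4174,  TIBC = 51.6161,  F = 171.4354, a = 7.9415),
    slope = c(RTL = -0.0327, Fe = -0.0086, TIBC = -0.0096,  F = 0.0058,   a = 0.1259),
    k = 5.4744, C = 68.1219
  )
)

#' Built-in published calibration constants
#'
#' Returns the referent-population constants for one age band exactly as
#' published: normalization means and SDs, normalized age-slopes `k_X`,
#' the scaling factor `k`, the constant `C`, and the life-expectancy
#' adjustments `delta_hiv_neg = -0.044` and `delta_hiv_pos = 0.194`.
#' The source table does not print the fit intercepts `n_X` (only their
#' combination `C`), so `intercept` is `NA` here.
#'
#' The referent moments derive from U.S. population surveys (RTL and the
#' iron panel from NHANES 2001-2006; ferritin from NHANES III); iron and
#' TIBC are in ug/dL, ferritin in ug/L.
#'
#' @inheritParams age_band
#' @return A [calibration_constants()] object.
#' @examples
#' reference_constants("younger")$k   # 2.7681
#' @export
reference_constants <- function(label = c("younger", "older")) {
  label <- match.arg(label)
  p <- .reference_table[[label]]
  calibration_constants(
    band = age_band(label),
    mu = p$mu, sigma = p$sigma, slope = p$slope,
    intercept = c(RTL = NA_real_, Fe = NA_real_, TIBC = NA_real_,
                  F = NA_real_, a = NA_real_),
    k = p$k, C = p$C,
    delta_hiv_neg = -0.044, delta_hiv_pos = 0.194)
}

#' Life expectancies used for the adjustment terms
#'
#' Defaults are the published values: 72.9 years for the study
#' population, 76.1 years for the referent population, and 67 years for
#' HIV-positive subjects whose treatment started at age 20.
#'
#' @param a_life_exp Study-population life expectancy (years).
#' @param a_ref_life_exp Referent-population life expectancy (years).
#' @param a_hiv_life_exp Life expectancy of treated HIV-positive subjects
#'   from age 20 (years); must exceed 20.
#' @return An object of class `"life_expectancy_set"`.
#' @export
life_expectancy_set <- function(a_life_exp = 72.9, a_ref_life_exp = 76.1,
                                a_hiv_life_exp = 67) {
  vals <- c(a_life_exp, a_ref_life_exp, a_hiv_life_exp)
  if (any(!is.finite(vals)) || any(vals <= 20)) {
    stop("all life expectancies must be finite and > 20 years", call. = FALSE)
  }
  structure(list(a_life_exp = a_life_exp,
                 a_ref_life_exp = a_ref_life_exp,
                 a_hiv_life_exp = a_hiv_life_exp),
            class = "life_expectancy_set")
}

#' Convert iron-panel concentrations between umol/L and ug/dL
#'
#' The calibration constants express serum iron and TIBC in ug/dL while
#' clinical laboratories often report umol/L; conversion uses the atomic
#' mass of iron (55.845), i.e. 5.5845 ug/dL per umol/L.
#'
#' @param x Numeric vector of concentrations.
#' @return Converted numeric vector.
#' @examples
#' umol_to_ugdl(16.87)  # 94.21...
#' @export
umol_to_ugdl <- function(x) x * IRON_UGDL_PER_UMOL

#' @rdname umol_to_ugdl
#' @export
ugdl_to_umol <- function(x) x / IRON_UGDL_PER_UMOL
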