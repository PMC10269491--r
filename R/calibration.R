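# Calibration of the clock against a referent population:
# z-score moments, normalized-variable-vs-age slopes, and the k and C
# constants that force the referent linear fit onto the identity line.

#' z-score normalization
#'
#' `(x - mu) / sigma`; the transform that puts heterogeneous biomarkers
#' on a common dimensionless scale before they are combined.
#'
#' @param x Numeric vector.
#' @param mu,sigma Normalization mean and standard deviation;
#'   `sigma` must be > 0.
#' @return Numeric vector of normalized values.
#' @export
zscore <- function(x, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be finite and > 0", call. = FALSE)
  }
  (x - mu) / sigma
}

# sign convention used throughout the formula: sgn(0) = +1, with a warning
# (the published sgn is only defined for nonzero arguments).
.sgn <- function(x) {
  if (any(x == 0)) warning("sgn(0) encountered; treating as +1")
  ifelse(x >= 0, 1, -1)
}

#' Per-variable sample moments of a referent population
#'
#' @param population A `data.frame` with columns `age`, `RTL`, `Fe`,
#'   `TIBC`, `F` (missing values allowed and ignored per variable).
#' @return A list with named numeric vectors `mu` and `sigma` over
#'   [BIOAGE_VARS] (sample SD, n - 1 denominator), plus `n` used per
#'   variable.  A constant column (sigma 0) is an error.
#' @export
estimate_moments <- function(population) {
  cols <- c(RTL = "RTL", Fe = "Fe", TIBC = "TIBC", F = "F", a = "age")
  missing_cols <- setdiff(unname(cols), names(population))
  if (length(missing_cols)) {
    stop("population lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mu <- sigma <- stats::setNames(numeric(length(cols)), names(cols))
  n <- stats::setNames(integer(length(cols)), names(cols))
  for (v in names(cols)) {
    x <- population[[cols[[v]]]]
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("variable ", v, ": fewer than 2 values",
                            call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("variable ", v, ": zero variance (constant column)",
           call. = FALSE)
    }
    mu[v] <- mean(x); sigma[v] <- s; n[v] <- length(x)
  }
  list(mu = mu, sigma = sigma, n = n)
}

#' Ordinary least-squares fit of a normalized variable against age
#'
#' Fits `X_norm = k_X * a + n_X` by unweighted OLS; `k_X` is the per-year
#' drift of the normalized variable in the referent population and is
#' the quantity whose sign and magnitude drive the clock.
#'
#' @param ages Numeric vector of chronological ages (years).
#' @param xnorm Numeric vector of z-scored values, same length.
#' @param variable Optional variable name carried into the result.
#' @return An object of class `"normalized_fit"`: list with `variable`,
#'   `k_X`, `n_X`, `n`.
#' @export
fit_normalized_slope <- function(ages, xnorm, variable = NA_character_) {
  keep <- !is.na(ages) & !is.na(xnorm)
  ages <- ages[keep]; xnorm <- xnorm[keep]
  if (length(ages) != length(xnorm)) stop("length mismatch", call. = FALSE)
  if (length(unique(ages)) < 2) {
    stop("need at least 2 distinct ages", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(intercept = 1, age = ages), xnorm)
  structure(list(variable = variable,
                 k_X = unname(fit$coefficients["age"]),
                 n_X = unname(fit$coefficients["intercept"]),
                 n = length(ages)),
            class = "normalized_fit")
}

#' Scaling factor k from the normalized age-slopes
#'
#' `k = 1 / sum(k_X * sgn(k_X)) = 1 / sum(|k_X|)`.  It rescales the sum
#' of signed normalized variables so that its fitted drift with age in
#' the referent population is exactly one year per year.
#'
#' @param slopes Named numeric vector of slopes `k_X`.
#' @return Positive scalar `k`.
#' @export
compute_k <- function(slopes) {
  if (!is.numeric(slopes) || !length(slopes)) {
    stop("slopes must be a non-empty numeric vector", call. = FALSE)
  }
  total <- sum(abs(slopes))
  if (total == 0) stop("all slopes are zero; k undefined", call. = FALSE)
  1 / total
}

#' Constant C from the fit intercepts
#'
#' `C = -k * sum(n_X * sgn(k_X))`.  Together with `k` it places the
#' referent-population linear fit of the score on the identity line
#' `a_bio = a`; on a complete-case calibration sample `C` equals the
#' sample mean age.
#'
#' @param k Scaling factor (> 0).
#' @param fits A list of [fit_normalized_slope()] results, or a list with
#'   named vectors `slope` and `intercept`.
#' @return Scalar `C` (years).
#' @export
compute_C <- function(k, fits) {
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (is.list(fits) && !is.null(fits$slope)) {
    slope <- fits$slope; intercept <- fits$intercept
  } else {
    slope <- vapply(fits, `[[`, 0, "k_X")
    intercept <- vapply(fits, `[[`, 0, "n_X")
  }
  -k * sum(intercept * .sgn(slope))
}

#' Calibrate clock constants from a referent population
#'
#' Full calibration for one age band: estimate per-variable moments,
#' z-score each variable (age included, with its own band mean and SD),
#' fit each normalized variable against age by OLS, then derive `k` and
#' `C`.  The life-expectancy adjustments are left at zero; fill them with
#' [set_adjustments()] when scoring a study population.
#'
#' Records with ages outside the band's closed interval are excluded
#' (count reported via `message()`).  Missing biomarker values are
#' allowed: moments and fits use each variable's available (pairwise
#' complete with age) records, mirroring calibration sources in which
#' different variables come from different survey subsamples.
#'
#' @param population `data.frame` with columns `age`, `RTL`, `Fe`,
#'   `TIBC`, `F`, e.g. from [generate_referent()].
#' @param band [age_band()] or label; defaults to the band attribute of
#'   `population` if present, else `"younger"`.
#' @param quiet Suppress the out-of-band exclusion message.
#' @return A [calibration_constants()] object with `delta_hiv_neg =
#'   delta_hiv_pos = 0` and an attribute `"fits"` holding the per-variable
#'   [fit_normalized_slope()] results.
#' @export
calibrate <- function(population, band = NULL, quiet = FALSE) {
  if (is.null(band)) {
    band <- attr(population, "band")
    if (is.null(band)) band <- "younger"
  }
  if (is.character(band)) band <- age_band(band)
  inside <- !is.na(population$age) &
    population$age >= band$lower & population$age <= band$upper
  n_out <- sum(!inside)
  if (n_out > 0 && !quiet) {
    message(sprintf("calibrate: excluded %d record(s) outside the %s band",
                    n_out, band$label))
  }
  population <- population[inside, , drop = FALSE]
  if (nrow(population) < 3) {
    stop("need at least 3 in-band records", call. = FALSE)
  }
  mom <- estimate_moments(population)
  cols <- c(RTL = "RTL", Fe = "Fe", TIBC = "TIBC", F = "F", a = "age")
  fits <- lapply(names(cols), function(v) {
    xn <- zscore(population[[cols[[v]]]], mom$mu[[v]], mom$sigma[[v]])
    fit_normalized_slope(population$age, xn, variable = v)
  })
  names(fits) <- names(cols)
  slope <- vapply(fits, `[[`, 0, "k_X")
  intercept <- vapply(fits, `[[`, 0, "n_X")
  k <- compute_k(slope)
  C <- compute_C(k, fits)
  out <- calibration_constants(
    band = band, mu = mom$mu, sigma = mom$sigma,
    slope = slope, intercept = intercept, k = k, C = C,
    delta_hiv_neg = 0, delta_hiv_pos = 0,
    k_tol = 1e-8)
  attr(out, "fits") <- fits
  attr(out, "n_excluded") <- n_out
  out
}
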