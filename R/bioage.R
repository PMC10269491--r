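# Biological age per subject: the composite formula
#   a_bio = k * sum_X sgn(k_X) X_norm + C + a*delta_hiv_neg
#           + (a - 20)*delta_hiv_pos,
# with X over {RTL, Fe, TIBC, F, a}.

#' Population life-expectancy adjustment
#'
#' `delta_hiv_neg = (a_life_exp - a_ref_life_exp) / a_life_exp`:
#' a per-year-of-age offset correcting for the life-expectancy gap
#' between the study population and the referent population used for
#' calibration.  With the default published values (72.9 vs 76.1 years)
#' this is -0.0439 (printed as -0.044).
#'
#' @param a_life_exp Study-population life expectancy (years, > 0).
#' @param a_ref_life_exp Referent-population life expectancy (years).
#' @return Dimensionless scalar.
#' @export
delta_hiv_neg <- function(a_life_exp = 72.9, a_ref_life_exp = 76.1) {
  if (!is.finite(a_life_exp) || a_life_exp <= 0) {
    stop("a_life_exp must be > 0", call. = FALSE)
  }
  (a_life_exp - a_ref_life_exp) / a_life_exp
}

#' HIV life-expectancy adjustment
#'
#' `delta_hiv_pos = (a_ref_life_exp - a_hiv_life_exp) /
#' (a_hiv_life_exp - 20)`: a per-year-since-age-20 offset for treated
#' HIV-positive subjects, whose life expectancy (67 years when treatment
#' starts at age 20) falls short of the referent population's.  With the
#' published defaults (76.1 vs 67) this is 0.1936 (printed as 0.194).
#' HIV-negative subjects receive zero.
#'
#' @param a_ref_life_exp Referent-population life expectancy (years).
#' @param a_hiv_life_exp Treated-HIV life expectancy from age 20
#'   (years, > 20).
#' @return Dimensionless scalar.
#' @export
delta_hiv_pos <- function(a_ref_life_exp = 76.1, a_hiv_life_exp = 67) {
  if (!is.finite(a_hiv_life_exp) || a_hiv_life_exp <= 20) {
    stop("a_hiv_life_exp must be > 20", call. = FALSE)
  }
  (a_ref_life_exp - a_hiv_life_exp) / (a_hiv_life_exp - 20)
}

#' Adjustment policy for scoring a cohort
#'
#' Controls whether the two life-expectancy terms enter the formula.
#' The population adjustment (`a * delta_hiv_neg`) applies to every
#' subject of the study population, HIV-positive and -negative alike,
#' and should be disabled when scoring the referent population itself.
#' The HIV adjustment (`(a - 20) * delta_hiv_pos`) applies to
#' HIV-positive subjects only; `adjust_naive = FALSE` additionally zeroes
#' it for untreated ("naive") subjects.
#'
#' @param apply_population_adjustment Use the `delta_hiv_neg` term.
#' @param apply_hiv_adjustment Use the `delta_hiv_pos` term for
#'   HIV-positive subjects.
#' @param adjust_naive Apply the HIV term to therapy-naive subjects too
#'   (default `TRUE`: one adjustment for all HIV-positive subjects).
#' @param life_expectancies A [life_expectancy_set()]; retained for
#'   provenance and for [set_adjustments()].
#' @return An object of class `"adjustment_policy"`.
#' @export
adjustment_policy <- function(apply_population_adjustment = TRUE,
                              apply_hiv_adjustment = TRUE,
                              adjust_naive = TRUE,
                              life_expectancies = life_expectancy_set()) {
  stopifnot(inherits(life_expectancies, "life_expectancy_set"))
  structure(list(apply_population_adjustment = apply_population_adjustment,
                 apply_hiv_adjustment = apply_hiv_adjustment,
                 adjust_naive = adjust_naive,
                 life_expectancies = life_expectancies),
            class = "adjustment_policy")
}

#' Fill the adjustment constants from life expectancies
#'
#' Computes [delta_hiv_neg()] and [delta_hiv_pos()] from a
#' [life_expectancy_set()] and stores them in a constants object (e.g.
#' freshly produced by [calibrate()], which leaves both at zero).
#'
#' @param constants A [calibration_constants()] object.
#' @param life_expectancies A [life_expectancy_set()].
#' @return The updated constants object.
#' @export
set_adjustments <- function(constants,
                            life_expectancies = life_expectancy_set()) {
  stopifnot(inherits(constants, "calibration_constants"),
            inherits(life_expectancies, "life_expectancy_set"))
  le <- life_expectancies
  constants$delta_hiv_neg <- delta_hiv_neg(le$a_life_exp, le$a_ref_life_exp)
  constants$delta_hiv_pos <- delta_hiv_pos(le$a_ref_life_exp,
                                           le$a_hiv_life_exp)
  constants
}

#' Assign an age to a calibration band
#'
#' Ages in \[18, 35\] use the younger-band constants (studies of this
#' design enrol from 18 while the calibration band starts at 19), ages
#' in \[50, 77\] the older ones.  Ages in the deliberately excluded gap
#' (35, 50), below 18 or above 77 are an error unless
#' `allow_out_of_band = TRUE`, which maps them to the nearest band with
#' a warning.
#'
#' @param age Numeric vector of ages (years).
#' @param allow_out_of_band Map out-of-band ages to the nearest band
#'   instead of erroring.
#' @return Character vector, `"younger"` or `"older"`.
#' @export
select_band <- function(age, allow_out_of_band = FALSE) {
  band <- rep(NA_character_, length(age))
  band[!is.na(age) & age >= 18 & age <= 35] <- "younger"
  band[!is.na(age) & age >= 50 & age <= 77] <- "older"
  out <- is.na(band) & !is.na(age)
  if (any(out)) {
    if (!allow_out_of_band) {
      stop(sprintf("age(s) outside the calibration bands: %s",
                   paste(utils::head(age[out], 5), collapse = ", ")),
           call. = FALSE)
    }
    warning(sprintf("%d age(s) outside the calibration bands mapped to the nearest band",
                    sum(out)))
    band[out] <- ifelse(age[out] < 42.5, "younger", "older")
  }
  band
}

# Vectorized core of the formula.  `df` must carry age, rtl, serum_iron,
# tibc, ferritin, hiv_status, regimen; all rows belong to the band of
# `constants`.  Returns the result columns; no validation here.
.bioage_core <- function(df, constants, policy) {
  cc <- constants
  sgn <- .sgn(cc$slope)
  z <- cbind(
    RTL  = zscore(df$rtl,        cc$mu[["RTL"]],  cc$sigma[["RTL"]]),
    Fe   = zscore(df$serum_iron, cc$mu[["Fe"]],   cc$sigma[["Fe"]]),
    TIBC = zscore(df$tibc,       cc$mu[["TIBC"]], cc$sigma[["TIBC"]]),
    F    = zscore(df$ferritin,   cc$mu[["F"]],    cc$sigma[["F"]]),
    a    = zscore(df$age,        cc$mu[["a"]],    cc$sigma[["a"]]))
  terms <- sweep(z, 2, sgn, `*`)
  colnames(terms) <- paste0("term_", colnames(z))
  adj_neg <- if (policy$apply_population_adjustment) {
    df$age * cc$delta_hiv_neg
  } else rep(0, nrow(df))
  hiv_pos <- !is.na(df$hiv_status) & df$hiv_status == "positive"
  if (!policy$adjust_naive) {
    hiv_pos <- hiv_pos & !(!is.na(df$regimen) & df$regimen == "naive")
  }
  adj_pos <- if (policy$apply_hiv_adjustment) {
    ifelse(hiv_pos, (df$age - 20) * cc$delta_hiv_pos, 0)
  } else rep(0, nrow(df))
  a_bio <- cc$k * rowSums(terms) + cc$C + adj_neg + adj_pos
  data.frame(a_bio = a_bio, terms, adjustment_neg = adj_neg,
             adjustment_pos = adj_pos)
}

#' Biological age of a single subject
#'
#' Evaluates the composite formula for one subject: each input is
#' z-scored against the band's referent moments, signed by the direction
#' of its population age-trend, summed, rescaled by `k` and shifted by
#' `C`; the life-expectancy adjustments are then added per `policy`.
#'
#' @param subject A list or one-row `data.frame` with `age`, `rtl`,
#'   `serum_iron` (ug/dL), `tibc` (ug/dL), `ferritin` (ug/L) and,
#'   for the HIV adjustment, `hiv_status` (and optionally `regimen`).
#' @param constants A [calibration_constants()] object for the subject's
#'   band; by default selected automatically from the built-in published
#'   constants via [select_band()].
#' @param policy An [adjustment_policy()].
#' @param allow_out_of_band Passed to [select_band()].
#' @return An object of class `"bioage_result"`: list with `subject_id`,
#'   `band`, `a_bio` (years), `term_contributions` (named vector of
#'   signed normalized contributions, so that `a_bio = k *
#'   sum(term_contributions) + C + adjustment_neg + adjustment_pos`),
#'   `adjustment_neg` and `adjustment_pos` (years).
#' @examples
#' cc <- reference_constants("younger")
#' s <- list(age = cc$mu[["a"]], rtl = cc$mu[["RTL"]],
#'           serum_iron = cc$mu[["Fe"]], tibc = cc$mu[["TIBC"]],
#'           ferritin = cc$mu[["F"]], hiv_status = "negative")
#' biological_age(s, cc, adjustment_policy(FALSE, FALSE))$a_bio  # = C
#' @export
biological_age <- function(subject, constants = NULL,
                           policy = adjustment_policy(),
                           allow_out_of_band = FALSE) {
  subject <- as.list(subject)
  needed <- c(age = "age", rtl = "rtl", serum_iron = "serum_iron",
              tibc = "tibc", ferritin = "ferritin")
  for (nm in needed) {
    if (is.null(subject[[nm]]) || is.na(subject[[nm]])) {
      stop("missing formula input: ", nm, call. = FALSE)
    }
  }
  if (is.null(subject$hiv_status)) subject$hiv_status <- "negative"
  if (is.null(subject$regimen)) subject$regimen <- NA_character_
  if (is.null(constants)) {
    band <- select_band(subject$age, allow_out_of_band)
    constants <- reference_constants(band)
  } else {
    band <- constants$band$label
  }
  df <- data.frame(age = subject$age, rtl = subject$rtl,
                   serum_iron = subject$serum_iron, tibc = subject$tibc,
                   ferritin = subject$ferritin,
                   hiv_status = subject$hiv_status,
                   regimen = subject$regimen)
  res <- .bioage_core(df, constants, policy)
  terms <- unlist(res[1, grep("^term_", names(res))])
  names(terms) <- sub("^term_", "", names(terms))
  structure(list(subject_id = subject$subject_id %||% NA_character_,
                 band = band,
                 a_bio = res$a_bio[1],
                 term_contributions = terms,
                 adjustment_neg = res$adjustment_neg[1],
                 adjustment_pos = res$adjustment_pos[1],
                 k = constants$k, C = constants$C),
            class = "bioage_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bioage_result <- function(x, ...) {
  cat(sprintf("<bioage_result> %s band, a_bio = %.4f years\n",
              x$band, x$a_bio))
  print(round(x$term_contributions, 4))
  cat(sprintf("adjustments: population %+.4f, HIV %+.4f years\n",
              x$adjustment_neg, x$adjustment_pos))
  invisible(x)
}

#' Biological age for a whole cohort
#'
#' Vectorized evaluation over a subject table.  Subjects missing any of
#' the five formula inputs, or with ages outside both calibration bands
#' (when `allow_out_of_band = FALSE`), are excluded and listed with
#' reasons in the `"excluded"` attribute; row order of eligible subjects
#' follows the input.
#'
#' @param subjects Subject `data.frame` as from [read_subjects()] or
#'   [generate_cohort()].
#' @param constants Named list with elements `younger` and `older`
#'   ([calibration_constants()]); defaults to the built-in published
#'   constants.
#' @param policy An [adjustment_policy()].
#' @param allow_out_of_band Map out-of-band ages to the nearest band
#'   instead of excluding them.
#' @return `data.frame` with columns `subject_id`, `age`, `hiv_status`,
#'   `band`, `a_bio`, `term_RTL`, `term_Fe`, `term_TIBC`, `term_F`,
#'   `term_a`, `adjustment_neg`, `adjustment_pos`; attribute
#'   `"excluded"` is a `data.frame` (`subject_id`, `row`, `reason`), and
#'   attribute `"outliers"` lists normalized values beyond |z| = 5
#'   (flagged, never altered).
#' @export
bioage_table <- function(subjects,
                         constants = list(younger = reference_constants("younger"),
                                          older = reference_constants("older")),
                         policy = adjustment_policy(),
                         allow_out_of_band = FALSE) {
  stopifnot(is.data.frame(subjects))
  n <- nrow(subjects)
  empty <- data.frame(subject_id = character(), age = numeric(),
                      hiv_status = character(), band = character(),
                      a_bio = numeric(), term_RTL = numeric(),
                      term_Fe = numeric(), term_TIBC = numeric(),
                      term_F = numeric(), term_a = numeric(),
                      adjustment_neg = numeric(), adjustment_pos = numeric())
  excluded <- data.frame(subject_id = character(), row = integer(),
                         reason = character())
  if (n == 0) {
    attr(empty, "excluded") <- excluded
    return(empty)
  }
  sid <- if (!is.null(subjects$subject_id)) {
    as.character(subjects$subject_id)
  } else sprintf("row%d", seq_len(n))
  need <- c("age", "rtl", "serum_iron", "tibc", "ferritin")
  reason <- rep(NA_character_, n)
  for (col in need) {
    v <- if (col %in% names(subjects)) subjects[[col]] else rep(NA_real_, n)
    hit <- is.na(reason) & is.na(v)
    reason[hit] <- paste("missing", col)
  }
  band <- rep(NA_character_, n)
  ok <- is.na(reason)
  band[ok] <- suppressWarnings(select_band(subjects$age[ok],
                                           allow_out_of_band = TRUE))
  if (!allow_out_of_band) {
    in_band <- !is.na(subjects$age) &
      ((subjects$age >= 18 & subjects$age <= 35) |
         (subjects$age >= 50 & subjects$age <= 77))
    hit <- ok & !in_band
    reason[hit] <- "age outside calibration bands"
    band[hit] <- NA_character_
  }
  keep <- is.na(reason)
  excluded <- data.frame(subject_id = sid[!keep], row = which(!keep),
                         reason = reason[!keep])
  if (!any(keep)) {
    attr(empty, "excluded") <- excluded
    return(empty)
  }
  df <- subjects[keep, , drop = FALSE]
  if (is.null(df$hiv_status)) df$hiv_status <- "negative"
  if (is.null(df$regimen)) df$regimen <- NA_character_
  bnd <- band[keep]
  res <- list()
  for (b in c("younger", "older")) {
    idx <- which(bnd == b)
    if (!length(idx)) next
    core <- .bioage_core(df[idx, , drop = FALSE], constants[[b]], policy)
    res[[b]] <- cbind(data.frame(subject_id = sid[keep][idx],
                                 age = df$age[idx],
                                 hiv_status = df$hiv_status[idx],
                                 band = b, .row = idx), core)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  # flag extreme z-scores (e.g. study ferritin scales far below the
  # referent's) without altering them
  zmat <- abs(as.matrix(out[paste0("term_", BIOAGE_VARS)]))
  hit <- which(zmat > 5, arr.ind = TRUE)
  attr(out, "outliers") <- data.frame(
    subject_id = out$subject_id[hit[, 1]],
    variable = BIOAGE_VARS[hit[, 2]],
    z = zmat[hit])
  out
}
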