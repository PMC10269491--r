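# Cohort-level statistics: viral-load floor, normality-gated two-group
# comparisons, quadratic ferritin-age fits, and linear fits of
# biological vs chronological age by group and regimen.

#' Floor undetectable viral loads
#'
#' Values below the assay detection limit (20 copies/mL) are replaced by
#' 10 copies/mL, the midpoint of the undetectable range, so they can
#' enter regressions; values at or above the limit pass unchanged.  The
#' transform is idempotent.
#'
#' @param pvl Numeric vector of viral loads (copies/mL); `NA` passes
#'   through, negative values are an error.
#' @param detection_limit Assay detection limit (copies/mL).
#' @param undetectable_value Replacement value for the undetectable
#'   range.
#' @return Numeric vector.
#' @examples
#' pvl_floor(c(0, 19, 20, 3940000))
#' @export
pvl_floor <- function(pvl, detection_limit = 20, undetectable_value = 10) {
  if (any(!is.na(pvl) & pvl < 0)) {
    stop("viral load cannot be negative", call. = FALSE)
  }
  ifelse(!is.na(pvl) & pvl < detection_limit, undetectable_value, pvl)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample, with the Lilliefors correction of the
#' p-value (Dallal-Wilkinson approximation, switching to the Stephens
#' polynomial for p > 0.1) since the classical KS null distribution does
#' not apply when the parameters are estimated.
#'
#' @param x Numeric vector, at least 4 non-missing values.
#' @return A list of class `"htest"` with `statistic` (D), `p.value`,
#'   `method` and `data.name`.
#' @references Dallal & Wilkinson (1986) Am Stat 40:294-296; Stephens
#'   (1974) J Am Stat Assoc 69:730-737.
#' @export
lilliefors_test <- function(x) {
  dname <- deparse(substitute(x))
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4) stop("sample size must be at least 4", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant sample", call. = FALSE)
  p <- stats::pnorm((x - mean(x)) / s)
  Dplus <- max(seq_len(n) / n - p)
  Dminus <- max(p - (seq_len(n) - 1) / n)
  K <- max(Dplus, Dminus)
  if (n <= 100) {
    Kd <- K; nd <- n
  } else {
    Kd <- K * (n / 100)^0.49; nd <- 100
  }
  pvalue <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
                  2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
                  0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pvalue > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * K
    pvalue <- if (KK <= 0.302) 1
    else if (KK <= 0.5) {
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
    } else if (KK <= 0.9) {
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
    } else if (KK <= 1.31) {
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
    } else 0
  }
  structure(list(statistic = c(D = K), p.value = min(max(pvalue, 0), 1),
                 method = "Lilliefors (Kolmogorov-Smirnov) normality test",
                 data.name = dname),
            class = "htest")
}

#' Normality gate for test selection
#'
#' Classifies a sample as `"normal"` or `"non_normal"` by the
#' Lilliefors-corrected KS test at `alpha` (default 0.05); this is the
#' gate deciding between the t test and the Mann-Whitney U test in
#' [compare_groups()].  A constant sample is `"non_normal"` with a
#' warning.
#'
#' @param x Numeric vector, at least 4 non-missing values.
#' @param alpha Significance level of the gate.
#' @return `"normal"` or `"non_normal"`, with attributes `p.value` and
#'   `statistic`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("sample size must be at least 4", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant sample; classified non_normal")
    return(structure("non_normal", p.value = 0, statistic = NA_real_))
  }
  t <- lilliefors_test(x)
  structure(if (t$p.value >= alpha) "normal" else "non_normal",
            p.value = t$p.value, statistic = unname(t$statistic))
}

#' Two-group comparison with a normality gate
#'
#' If both samples pass the normality gate, a pooled-variance two-sided
#' t test (df = n1 + n2 - 2) with groups summarized as mean +/- SD;
#' otherwise a Mann-Whitney U test (normal approximation with tie
#' correction) with groups summarized as median +/- IQR.
#'
#' @param a,b Numeric vectors (missing values dropped), both of length
#'   >= 2.  Samples too small for the gate (n < 4) or jointly constant
#'   fall back to Mann-Whitney with a warning / error respectively.
#' @param labels Length-2 character vector of group labels.
#' @param variable Optional variable name carried into the result.
#' @param alpha Gate significance level.
#' @return An object of class `"comparison_result"`: list with
#'   `variable`, `labels`, `n` (length 2), `test` (`"t_test"` or
#'   `"mann_whitney"`), `statistic`, `df` (t only), `p.value`,
#'   `location` and `scale` (means and SDs, or medians and IQRs),
#'   `summary_type`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b"),
                           variable = NA_character_, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
    # identical constants: no variability at all
    stop("degenerate samples: both groups constant and equal", call. = FALSE)
  }
  gate <- function(x) {
    if (length(x) < 4) {
      warning("group too small for the normality gate; using Mann-Whitney")
      return("non_normal")
    }
    if (stats::sd(x) == 0) return(suppressWarnings(normality_gate(x)))
    as.character(normality_gate(x, alpha))
  }
  ga <- gate(a); gb <- gate(b)
  if (ga == "normal" && gb == "normal") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test = "t_test",
                statistic = unname(ht$statistic),
                df = unname(ht$parameter), p.value = ht$p.value,
                location = c(mean(a), mean(b)),
                scale = c(stats::sd(a), stats::sd(b)),
                summary_type = "mean_sd")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    res <- list(test = "mann_whitney",
                statistic = unname(ht$statistic),
                df = NA_real_, p.value = ht$p.value,
                location = c(stats::median(a), stats::median(b)),
                scale = c(stats::IQR(a), stats::IQR(b)),
                summary_type = "median_iqr")
  }
  structure(c(list(variable = variable, labels = labels,
                   n = c(length(a), length(b)),
                   gate = c(ga, gb)),
              res),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  fmt <- function(i) sprintf("%s: %.3g +/- %.3g (n=%d)", x$labels[i],
                             x$location[i], x$scale[i], x$n[i])
  cat(sprintf("<comparison_result> %s [%s]\n",
              if (is.na(x$variable)) "" else x$variable,
              if (x$summary_type == "mean_sd") "mean +/- SD" else "median +/- IQR"))
  cat(" ", fmt(1), "vs", fmt(2), "\n")
  cat(sprintf("  %s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p.value))
  invisible(x)
}

#' Second-order polynomial fit
#'
#' Least-squares quadratic `X = c0 + c1*a + c2*a^2`, as used for the
#' ferritin-vs-age curves.
#'
#' @param ages Numeric vector with at least 3 distinct values.
#' @param values Numeric vector, same length.
#' @return An object of class `"polyfit2"`: list with `coefficients`
#'   (`c0`, `c1`, `c2`), `n`, `residual_sd`.
#' @export
polyfit2 <- function(ages, values) {
  keep <- !is.na(ages) & !is.na(values)
  ages <- ages[keep]; values <- values[keep]
  if (length(unique(ages)) < 3) {
    stop("need at least 3 distinct ages", call. = FALSE)
  }
  fit <- stats::lm(values ~ ages + I(ages^2))
  cf <- unname(stats::coef(fit))
  n <- length(ages)
  rsd <- if (n > 3) sqrt(sum(stats::resid(fit)^2) / (n - 3)) else NA_real_
  structure(list(coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
                 n = n, residual_sd = rsd),
            class = "polyfit2")
}

# single unweighted linear fit; shared by bioage_fits and relation_scan
.linfit <- function(x, y, group = NA_character_) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) return(NULL)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  data.frame(group = group, slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             n = length(x), r_squared = r2)
}

#' Linear fits of biological vs chronological age by group
#'
#' One unweighted least-squares line of `a_bio` on `age` per group
#' (HIV status by default, or therapy regimen), plus the referent
#' identity line `a_bio = a` for comparison.  Groups with fewer than 2
#' distinct ages are skipped with a warning.
#'
#' @param bioage `data.frame` from [bioage_table()].
#' @param cohort Optional subject table; required when grouping by a
#'   column (e.g. `regimen`) absent from `bioage`, joined on
#'   `subject_id`.
#' @param group_by Grouping column: `"hiv_status"` (default) or
#'   `"regimen"` (treated regimens only).
#' @return `data.frame` with columns `group`, `slope`, `intercept`, `n`,
#'   `r_squared`; first row is the referent identity line.
#' @export
bioage_fits <- function(bioage, cohort = NULL,
                        group_by = c("hiv_status", "regimen")) {
  group_by <- match.arg(group_by)
  df <- bioage
  if (!group_by %in% names(df)) {
    if (is.null(cohort)) {
      stop("grouping column '", group_by,
           "' not in bioage table; supply `cohort`", call. = FALSE)
    }
    df[[group_by]] <- cohort[[group_by]][match(df$subject_id,
                                               cohort$subject_id)]
  }
  if (group_by == "regimen") {
    df <- df[!is.na(df[[group_by]]) &
               df[[group_by]] %in% c("nrti_nnrti", "nrti_pi"), , drop = FALSE]
  }
  ref <- data.frame(group = "referent", slope = 1, intercept = 0,
                    n = NA_integer_, r_squared = NA_real_)
  fits <- list(ref)
  for (g in sort(unique(df[[group_by]]))) {
    sub <- df[df[[group_by]] == g, , drop = FALSE]
    f <- .linfit(sub$age, sub$a_bio, group = g)
    if (is.null(f)) {
      warning("group '", g, "' has fewer than 2 distinct ages; skipped")
      next
    }
    fits[[length(fits) + 1]] <- f
  }
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

#' Scan pairwise relations among viral load, telomere length and the
#' iron panel
#'
#' Unweighted linear fits, reported without significance claims, of:
#' RTL on floored viral load, RTL on therapy duration, and each iron
#' parameter on floored viral load and on RTL.  Viral load passes
#' through [pvl_floor()] first.  Pairs with no usable data are skipped.
#'
#' @param cohort Subject `data.frame`.
#' @return `data.frame` with columns `response`, `predictor`, `slope`,
#'   `intercept`, `n`, `r_squared` (zero rows for an empty cohort).
#' @export
relation_scan <- function(cohort) {
  iron_vars <- c("serum_iron", "tibc", "ferritin",
                 "transferrin_saturation", "transferrin")
  pvl <- if ("pvl" %in% names(cohort)) pvl_floor(cohort$pvl) else NULL
  pairs <- list(c("rtl", "pvl"), c("rtl", "therapy_duration"))
  for (v in iron_vars) pairs <- c(pairs, list(c(v, "pvl"), c(v, "rtl")))
  out <- list()
  for (p in pairs) {
    yv <- p[1]; xv <- p[2]
    x <- if (xv == "pvl") pvl else cohort[[xv]]
    y <- cohort[[yv]]
    if (is.null(x) || is.null(y)) next
    f <- .linfit(x, y)
    if (is.null(f)) next
    f$group <- NULL
    out[[length(out) + 1]] <- cbind(data.frame(response = yv,
                                               predictor = xv), f)
  }
  if (!length(out)) {
    return(data.frame(response = character(), predictor = character(),
                      slope = numeric(), intercept = numeric(),
                      n = integer(), r_squared = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
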