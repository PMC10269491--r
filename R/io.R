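# Subject-table and constants-file input/output.

.HIV_LEVELS <- c("negative", "positive")
.REGIMEN_LEVELS <- c("none", "naive", "nrti_nnrti", "nrti_pi")
.TREATED_REGIMENS <- c("naive", "nrti_nnrti", "nrti_pi")

.SUBJECT_NUMERIC <- c("age", "therapy_duration", "pvl", "cd4", "rtl",
                      "serum_iron", "tibc", "transferrin_saturation",
                      "transferrin", "ferritin")

#' Read a subject table from CSV
#'
#' Reads per-subject records (one row per person) and validates them.
#' Required columns: `subject_id`, `age`, `hiv_status`.  Optional
#' columns: `regimen`, `therapy_duration` (months), `pvl` (copies/mL),
#' `cd4` (cells/uL), `rtl` (T/S ratio), `serum_iron` (ug/dL), `tibc`
#' (ug/dL), `transferrin_saturation` (percent), `transferrin` (umol/L),
#' `ferritin` (ug/L).  Empty cells are missing values.
#'
#' Rows violating an invariant (non-positive age, negative biomarker,
#' unknown status/regimen label, a therapy regimen on an HIV-negative
#' subject, or an unparseable number) are dropped; row-indexed
#' diagnostics are attached as `attr(, "diagnostics")` and echoed to
#' standard error unless `quiet = TRUE`.
#'
#' Units for serum iron and TIBC default to ug/dL (the canonical internal
#' unit, matching the calibration constants).  A column named with the
#' suffix `_umol_l` (e.g. `serum_iron_umol_l`), or `iron_unit =
#' "umol_L"` / `tibc_unit = "umol_L"`, declares umol/L input, which is
#' converted on read via [umol_to_ugdl()].
#'
#' @param path Path to a CSV file with a header row.
#' @param iron_unit,tibc_unit `"ug_dL"` (default) or `"umol_L"`.
#' @param quiet Suppress diagnostics on standard error.
#' @return A `data.frame` of validated records with a `"diagnostics"`
#'   attribute (`data.frame` with columns `row`, `field`, `message`).
#' @export
read_subjects <- function(path, iron_unit = c("ug_dL", "umol_L"),
                          tibc_unit = c("ug_dL", "umol_L"), quiet = FALSE) {
  iron_unit <- match.arg(iron_unit)
  tibc_unit <- match.arg(tibc_unit)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"), strip.white = TRUE,
                         fileEncoding = "UTF-8")
  names(raw) <- trimws(names(raw))

  # header-suffix unit declaration, e.g. serum_iron_umol_l
  for (col in c("serum_iron", "tibc")) {
    suf <- grep(paste0("^", col, "[._]umol[._]l$"), names(raw),
                ignore.case = TRUE)
    if (length(suf)) {
      names(raw)[suf[1]] <- col
      if (col == "serum_iron") iron_unit <- "umol_L" else tibc_unit <- "umol_L"
    }
  }

  required <- c("subject_id", "age", "hiv_status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  n <- nrow(raw)
  diag <- list()
  note <- function(row, field, msg) {
    diag[[length(diag) + 1L]] <<- data.frame(row = row, field = field,
                                             message = msg)
  }

  out <- data.frame(subject_id = as.character(raw$subject_id))
  for (col in .SUBJECT_NUMERIC) {
    if (col %in% names(raw)) {
      txt <- raw[[col]]
      val <- suppressWarnings(as.numeric(txt))
      bad <- which(!is.na(txt) & is.na(val))
      for (r in bad) note(r, col, sprintf("unparseable numeric '%s'", txt[r]))
      out[[col]] <- val
    } else {
      out[[col]] <- NA_real_
    }
  }
  out$hiv_status <- tolower(as.character(raw$hiv_status))
  out$regimen <- if ("regimen" %in% names(raw)) {
    tolower(as.character(raw$regimen))
  } else NA_character_
  # absent regimen defaults to "none" for the HIV-negative
  out$regimen[is.na(out$regimen) & out$hiv_status == "negative"] <- "none"

  if (iron_unit == "umol_L") out$serum_iron <- umol_to_ugdl(out$serum_iron)
  if (tibc_unit == "umol_L") out$tibc <- umol_to_ugdl(out$tibc)

  bad_row <- rep(FALSE, n)
  flag <- function(rows, field, msg) {
    for (r in rows) note(r, field, msg)
    bad_row[rows] <<- TRUE
  }
  flag(which(is.na(out$subject_id) | out$subject_id == ""),
       "subject_id", "missing subject_id")
  flag(which(is.na(out$age) & !is.na(raw$age)), "age", "unparseable age")
  flag(which(is.na(raw$age)), "age", "missing age")
  flag(which(!is.na(out$age) & out$age <= 0), "age", "age must be > 0")
  flag(which(!out$hiv_status %in% .HIV_LEVELS), "hiv_status",
       "hiv_status must be 'negative' or 'positive'")
  flag(which(!is.na(out$regimen) & !out$regimen %in% .REGIMEN_LEVELS),
       "regimen", "unknown regimen label")
  flag(which(out$hiv_status == "negative" &
               out$regimen %in% .TREATED_REGIMENS),
       "regimen", "therapy regimen on an HIV-negative subject")
  for (col in setdiff(.SUBJECT_NUMERIC, "age")) {
    flag(which(!is.na(out[[col]]) & out[[col]] < 0), col,
         sprintf("%s must be >= 0", col))
  }
  # unparseable numerics in optional columns also invalidate the row
  if (length(diag)) {
    dd <- do.call(rbind, diag)
    bad_row[unique(dd$row)] <- TRUE
  }

  diagnostics <- if (length(diag)) {
    dd <- do.call(rbind, diag)
    dd[order(dd$row), , drop = FALSE]
  } else {
    data.frame(row = integer(), field = character(), message = character())
  }
  if (!quiet && nrow(diagnostics)) {
    apply(diagnostics, 1, function(d) {
      message(sprintf("row %s [%s]: %s", d[["row"]], d[["field"]],
                      d[["message"]]))
    })
    message(sprintf("rejected %d of %d row(s)", sum(bad_row), n))
  }
  res <- out[!bad_row, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "diagnostics") <- diagnostics
  res
}

#' Write a subject table to CSV
#'
#' Inverse of [read_subjects()]: canonical units (iron/TIBC in ug/dL),
#' empty cells for missing values.
#'
#' @param subjects Subject `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

.constants_keys <- function() {
  c("band.label", "band.lower", "band.upper",
    paste0("mu.", BIOAGE_VARS), paste0("sigma.", BIOAGE_VARS),
    paste0("slope.", BIOAGE_VARS), paste0("intercept.", BIOAGE_VARS),
    "k", "C", "delta_hiv_neg", "delta_hiv_pos")
}

#' Write calibration constants to a flat key-value text file
#'
#' One `key = value` pair per line, numbers at full double precision
#' (17 significant digits), so that `read_constants(write_constants(x))`
#' is the identity.
#'
#' @param constants A [calibration_constants()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_constants()]
#' @export
write_constants <- function(constants, path) {
  stopifnot(inherits(constants, "calibration_constants"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste("band.label =", constants$band$label),
    paste("band.lower =", num(constants$band$lower)),
    paste("band.upper =", num(constants$band$upper)),
    paste0("mu.", BIOAGE_VARS, " = ", num(constants$mu)),
    paste0("sigma.", BIOAGE_VARS, " = ", num(constants$sigma)),
    paste0("slope.", BIOAGE_VARS, " = ", num(constants$slope)),
    paste0("intercept.", BIOAGE_VARS, " = ",
           ifelse(is.na(constants$intercept), "NA",
                  num(constants$intercept))),
    paste("k =", num(constants$k)),
    paste("C =", num(constants$C)),
    paste("delta_hiv_neg =", num(constants$delta_hiv_neg)),
    paste("delta_hiv_pos =", num(constants$delta_hiv_pos)))
  writeLines(lines, path)
  invisible(path)
}

#' Read calibration constants from a flat key-value text file
#'
#' @param path Path to a file written by [write_constants()].
#' @param k_tol Passed to [calibration_constants()] validation.
#' @return A [calibration_constants()] object.  A missing key or a
#'   non-positive sigma is an error naming the offending key.
#' @export
read_constants <- function(path, k_tol = 0.01) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) {
    stop("malformed line(s): ", paste(lines[eq < 0], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substring(lines, eq + 1))
  missing <- setdiff(.constants_keys(), keys)
  if (length(missing)) {
    stop("constants file missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get1 <- function(key) vals[match(key, keys)]
  getnum <- function(key) {
    v <- suppressWarnings(as.numeric(get1(key)))
    if (is.na(v) && get1(key) != "NA") {
      stop("unparseable value for key '", key, "'", call. = FALSE)
    }
    v
  }
  vec <- function(prefix) {
    v <- vapply(paste0(prefix, ".", BIOAGE_VARS), getnum, 0)
    names(v) <- BIOAGE_VARS
    v
  }
  label <- get1("band.label")
  sigma <- vec("sigma")
  bad_sigma <- names(sigma)[!is.na(sigma) & sigma <= 0]
  if (length(bad_sigma)) {
    stop("non-positive sigma for: ",
         paste(paste0("sigma.", bad_sigma), collapse = ", "), call. = FALSE)
  }
  calibration_constants(
    band = label, mu = vec("mu"), sigma = sigma,
    slope = vec("slope"), intercept = vec("intercept"),
    k = getnum("k"), C = getnum("C"),
    delta_hiv_neg = getnum("delta_hiv_neg"),
    delta_hiv_pos = getnum("delta_hiv_pos"),
    k_tol = k_tol)
}
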