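# Shared fixtures, built in code.

# Literal transcription of the published constants table, kept separate from
# the package's own copy so the built-in values are asserted against an
# independent rendering.
table3_fixture <- function() {
  list(
    younger = list(
      mu    = c(RTL = 1.1674, Fe = 106.701, TIBC = 350.4698,
                F = 141.099, a = 27.4770),
      sigma = c(RTL = 0.2699, Fe = 40.65551, TIBC = 48.50848,
                F = 87.18172, a = 4.7178),
      slope = c(RTL = -0.0432, Fe = -0.0270, TIBC = -0.0183,
                F = 0.0608, a = 0.2120),
      k = 2.7681, C = 27.4907,
      delta_hiv_neg = -0.044, delta_hiv_pos = 0.194),
    older = list(
      mu    = c(RTL = 0.9310, Fe = 92.84552, TIBC = 340.4459,
                F = 195.7973, a = 64.0432),
      sigma = c(RTL = 0.2211, Fe = 34.4174, TIBC = 51.6161,
                F = 171.4354, a = 7.9415),
      slope = c(RTL = -0.0327, Fe = -0.0086, TIBC = -0.0096,
                F = 0.0058, a = 0.1259),
      k = 5.4744, C = 68.1219,
      delta_hiv_neg = -0.044, delta_hiv_pos = 0.194))
}

# A subject whose five formula inputs all sit at the band means.
all_means_subject <- function(band = "younger", hiv_status = "negative",
                              age = NULL) {
  cc <- reference_constants(band)
  list(subject_id = paste0("mean_", band),
       age = age %||% unname(cc$mu["a"]),
       rtl = unname(cc$mu["RTL"]), serum_iron = unname(cc$mu["Fe"]),
       tibc = unname(cc$mu["TIBC"]), ferritin = unname(cc$mu["F"]),
       hiv_status = hiv_status, regimen = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rescale normal draws so the sample mean and SD are exactly as requested.
exact_moment_sample <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# Convert a referent-population table to the subject layout.
referent_as_subjects <- function(pop, hiv_status = "negative") {
  data.frame(subject_id = sprintf("R%05d", seq_len(nrow(pop))),
             age = pop$age, hiv_status = hiv_status,
             rtl = pop$RTL, serum_iron = pop$Fe, tibc = pop$TIBC,
             ferritin = pop$F)
}

write_subject_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
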