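# shared fixtures: paths, quick constructors

table1_path <- function() {
  system.file("extdata", "table1_settings.csv", package = "dbsteer")
}

# monopolar setting from cathodic percents, e.g. pct_setting(c(E1 = 70, E2 = 30), 3)
pct_setting <- function(pct, amplitude, mode = "ring") {
  full <- stats::setNames(numeric(8), paste0("E", 1:8))
  full[names(pct)] <- pct
  fr <- c(-full / 100, case = 1)
  names(fr) <- c(paste0("E", 1:8), "case")
  stim_setting(amplitude, fr, mode = mode)
}

# two-symptom spec with equal weights, ids s1/s2
toy_spec <- function() {
  select_symptoms(list(
    symptom_assessment("s1", "left", "clinician", 4, 0),
    symptom_assessment("s2", "left", "clinician", 4, 0)
  ), max_n = 2)
}
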