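# Shared fixture builders.  Tests express laboratory values in fold of ULN
# against the default table so thresholds read directly off the code.

ULN <- uln_table()

# series from fold-of-ULN values
fser <- function(analyte, t, folds) {
  lab_series(analyte, t, folds * unname(ULN[[toupper(analyte)]]))
}

# random positive trajectory on a random grid (for property tests)
rand_series <- function(analyte, n_pts = sample(3:10, 1)) {
  t <- sort(sample(0:60, n_pts))
  folds <- stats::rlnorm(n_pts, meanlog = log(2), sdlog = 1)
  fser(analyte, t, folds)
}

# a small hand-built cohort with known onset values and outcomes
tiny_cohort <- function() {
  list(
    patient_record("P1",
      series = list(
        ALT = fser("ALT", c(0, 3, 6), c(5, 10, 4)),
        TB = fser("TB", c(0, 3, 6), c(1, 1.2, 0.9)),
        INR = lab_series("INR", c(0, 3), c(1.1, 1.3))),
      onset_alp = 140, onset_ast = 150,
      outcome_alf = FALSE, outcome_death_or_lt = FALSE),
    patient_record("P2",
      series = list(
        ALT = fser("ALT", c(0, 2, 9), c(4, 8, 3)),
        TB = fser("TB", c(0, 2, 9), c(1.5, 2, 4))),
      onset_inr = 1.8, onset_alp = 220, onset_ast = 400,
      outcome_alf = TRUE, outcome_death_or_lt = FALSE),
    patient_record("P3",
      series = list(
        ALT = fser("ALT", c(1, 4), c(2, 2.5)),
        TB = fser("TB", c(1, 4), c(3, 4))),
      onset_inr = 1.2, onset_alp = 300, onset_ast = 80,
      outcome_alf = FALSE, outcome_death_or_lt = FALSE)
  )
}

expect_series_equal <- function(a, b) {
  expect_equal(a$analyte, b$analyte)
  expect_equal(a$points$t, b$points$t)
  expect_equal(a$points$value, b$points$value)
}
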