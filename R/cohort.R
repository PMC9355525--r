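#' @title Patient records and cohort I/O
#' @description Lightweight S3 containers for longitudinal laboratory series
#'   and per-patient outcome labels, plus long-format CSV ingest/export.
#'   Time is measured in real-valued days since DILI onset (day 0).
#' @name cohort
NULL

#' Construct a laboratory time series for one analyte
#'
#' Points are sorted ascending by time; exact duplicate rows (same day, same
#' value) are collapsed.  Two measurements at the same day with different
#' values are ambiguous and rejected.
#'
#' @param analyte Analyte name ("ALT", "AST", "ALP", "GGT", "TB", "INR", ...).
#' @param t Days since DILI onset (finite, >= 0).
#' @param value Measurements in native units (finite, > 0).
#' @return A list of class \code{"lab_series"} with fields \code{analyte} and
#'   \code{points} (a data.frame with columns \code{t}, \code{value}).
#' @export
lab_series <- function(analyte, t, value) {
  if (length(t) != length(value)) stop("t and value must have equal length")
  if (length(t) > 0) {
    if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
    if (any(!is.finite(value)) || any(value <= 0)) {
      stop("values must be finite and strictly positive")
    }
  }
  pts <- data.frame(t = as.numeric(t), value = as.numeric(value))
  pts <- unique(pts[order(pts$t, pts$value), , drop = FALSE])
  if (anyDuplicated(pts$t)) {
    stop("ambiguous series for ", analyte,
         ": multiple differing values at the same day")
  }
  rownames(pts) <- NULL
  structure(list(analyte = toupper(analyte), points = pts),
            class = "lab_series")
}

#' Number of points in a lab series
#' @param x A \code{lab_series}.
#' @param ... Unused.
#' @export
length.lab_series <- function(x, ...) nrow(x$points)

series_value_at_onset <- function(s) {
  if (length(s) == 0) return(NA_real_)
  s$points$value[1L]
}

#' Construct a patient record
#'
#' Onset covariates default to the value at the earliest time point of the
#' matching series when not given explicitly; INR must be supplied (it has no
#' trajectory requirement but drives the optimized risk model).
#'
#' @param id Patient identifier (string).
#' @param series Named list of \code{\link{lab_series}} keyed by analyte.
#' @param onset_inr International normalized ratio at DILI onset.
#' @param onset_alp,onset_alt,onset_ast,onset_tb Onset values in native units;
#'   default to the earliest measurement of the corresponding series.
#' @param outcome_alf Logical: did the patient develop acute liver failure?
#' @param outcome_death_or_lt Logical: liver-related death or transplantation.
#' @return A list of class \code{"patient_record"}.
#' @export
patient_record <- function(id, series = list(),
                           onset_inr = NA_real_,
                           onset_alp = NA_real_, onset_alt = NA_real_,
                           onset_ast = NA_real_, onset_tb = NA_real_,
                           outcome_alf = NA, outcome_death_or_lt = NA) {
  names(series) <- toupper(names(series))
  pick <- function(given, analyte) {
    if (!is.na(given)) return(as.numeric(given))
    if (analyte %in% names(series)) return(series_value_at_onset(series[[analyte]]))
    NA_real_
  }
  if (is.na(onset_inr) && "INR" %in% names(series)) {
    onset_inr <- series_value_at_onset(series[["INR"]])
  }
  structure(list(
    id = as.character(id),
    series = series,
    onset_inr = as.numeric(onset_inr),
    onset_alp = pick(onset_alp, "ALP"),
    onset_alt = pick(onset_alt, "ALT"),
    onset_ast = pick(onset_ast, "AST"),
    onset_tb  = pick(onset_tb,  "TB"),
    outcome_alf = as.logical(outcome_alf),
    outcome_death_or_lt = as.logical(outcome_death_or_lt)
  ), class = "patient_record")
}

#' Read a cohort from long-format CSV files
#'
#' @param labs_path CSV with header \code{patient_id, day, analyte, value}.
#' @param outcomes_path Optional CSV with header
#'   \code{patient_id, alf, death_or_lt} (0/1 or TRUE/FALSE); patients missing
#'   from it get NA outcomes.
#' @param uln A \code{\link{uln_table}} (kept for interface symmetry; raw
#'   values are stored, folds are computed on demand).
#' @return List of \code{\link{patient_record}} objects, ordered by first
#'   appearance in the labs file.
#' @export
read_cohort <- function(labs_path, outcomes_path = NULL, uln = uln_table()) {
  labs <- utils::read.csv(labs_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "analyte", "value")
  if (!all(need %in% names(labs))) {
    stop("labs file must have columns: ", paste(need, collapse = ", "))
  }
  labs$day <- suppressWarnings(as.numeric(labs$day))
  labs$value <- suppressWarnings(as.numeric(labs$value))
  bad <- which(!is.finite(labs$day) | !is.finite(labs$value))
  if (length(bad) > 0) {
    stop("unparseable numeric value(s) in labs rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- NULL
  if (!is.null(outcomes_path)) {
    out <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
    oneed <- c("patient_id", "alf", "death_or_lt")
    if (!all(oneed %in% names(out))) {
      stop("outcomes file must have columns: ", paste(oneed, collapse = ", "))
    }
  }
  ids <- unique(as.character(labs$patient_id))
  cohort <- lapply(ids, function(pid) {
    sub <- labs[labs$patient_id == pid, , drop = FALSE]
    series <- lapply(split(sub, toupper(sub$analyte)), function(d) {
      lab_series(d$analyte[1], d$day, d$value)
    })
    alf <- NA; dlt <- NA
    if (!is.null(out)) {
      row <- out[as.character(out$patient_id) == pid, , drop = FALSE]
      if (nrow(row) > 1) stop("duplicate outcome rows for patient ", pid)
      if (nrow(row) == 1) {
        alf <- as.logical(as.integer(row$alf))
        dlt <- as.logical(as.integer(row$death_or_lt))
      }
    }
    patient_record(pid, series, outcome_alf = alf, outcome_death_or_lt = dlt)
  })
  cohort
}

#' Write a cohort to long-format CSV files
#'
#' Inverse of \code{\link{read_cohort}}: reading the written files recreates
#' the cohort field-for-field (onset covariates are re-derived from the
#' earliest measurements).
#'
#' @param cohort List of \code{\link{patient_record}}s.
#' @param labs_path,outcomes_path Output paths.
#' @export
write_cohort <- function(cohort, labs_path, outcomes_path = NULL) {
  rows <- lapply(cohort, function(p) {
    from_series <- do.call(rbind, lapply(p$series, function(s) {
      if (length(s) == 0) return(NULL)
      data.frame(patient_id = p$id, day = s$points$t,
                 analyte = s$analyte, value = s$points$value,
                 stringsAsFactors = FALSE)
    }))
    # onset-only covariates (no trajectory) survive the round-trip as a
    # single measurement at the patient's earliest observation day
    day0 <- if (is.null(from_series)) 0 else min(from_series$day)
    onset <- c(INR = p$onset_inr, ALP = p$onset_alp, AST = p$onset_ast,
               ALT = p$onset_alt, TB = p$onset_tb)
    onset <- onset[!names(onset) %in% names(p$series) & is.finite(onset)]
    from_onset <- if (length(onset) == 0) NULL else {
      data.frame(patient_id = p$id, day = day0, analyte = names(onset),
                 value = unname(onset), stringsAsFactors = FALSE)
    }
    rbind(from_series, from_onset)
  })
  labs <- do.call(rbind, rows)
  if (is.null(labs)) {
    labs <- data.frame(patient_id = character(), day = numeric(),
                       analyte = character(), value = numeric())
  }
  if (nrow(labs) > 0 && (any(!is.finite(labs$day)) || any(!is.finite(labs$value)))) {
    stop("refusing to write non-finite laboratory values")
  }
  utils::write.csv(labs, labs_path, row.names = FALSE, quote = FALSE)
  if (!is.null(outcomes_path)) {
    oc <- data.frame(
      patient_id = vapply(cohort, `[[`, "", "id"),
      alf = vapply(cohort, function(p) as.integer(p$outcome_alf), 0L),
      death_or_lt = vapply(cohort, function(p) as.integer(p$outcome_death_or_lt), 0L)
    )
    utils::write.csv(oc, outcomes_path, row.names = FALSE, quote = FALSE)
  }
  invisible(labs_path)
}
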