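#' @title Dynamic ALT/TB evolution-pattern classifier
#' @description The four dynamic evolution patterns of ALT and TB after DILI
#'   onset are defined on the peak fold-of-ULN of each trajectory and the time
#'   interval between the two peaks:
#'   \itemize{
#'     \item ALT-mono-peak: ALT peak >= 3x ULN and TB peak < 2.5x ULN;
#'     \item TB-mono-peak: ALT peak < 3x ULN and TB peak >= 2.5x ULN;
#'     \item double-overlap-peak (DOP): both thresholds met, peak interval
#'       < 3 days;
#'     \item double-separate-peak (DSP): both thresholds met, peak interval
#'       >= 3 days.
#'   }
#'   Patients below both thresholds receive \code{"NONE"} and are excluded
#'   from the four-pattern comparison.
#' @name pattern_classifier
NULL

#' Pattern labels
#' @export
PATTERNS <- c("ALT_MONO", "TB_MONO", "DOP", "DSP", "NONE")

#' Locate the peak of a laboratory series
#'
#' The peak is the maximum observed value; ties are broken to the earliest
#' time so the result is deterministic and independent of input order.
#'
#' @param series A nonempty \code{\link{lab_series}}.
#' @param uln A \code{\link{uln_table}} used to express the peak in fold of ULN.
#' @return List with \code{t_peak} (days), \code{value_peak} (native units)
#'   and \code{fold_peak} (x ULN; NA for analytes without a ULN such as INR).
#' @export
find_peak <- function(series, uln = uln_table()) {
  if (length(series) == 0) stop("cannot locate the peak of an empty series")
  pts <- series$points
  vmax <- max(pts$value)
  tpk <- min(pts$t[pts$value == vmax])
  fold <- if (series$analyte %in% names(uln)) {
    fold_uln(vmax, series$analyte, uln)
  } else NA_real_
  list(t_peak = tpk, value_peak = vmax, fold_peak = fold)
}

#' Classify a patient's ALT/TB trajectories into a dynamic evolution pattern
#'
#' Thresholds are applied to the peak fold of each series; the interval is
#' the absolute difference of the two peak times.  All boundary conventions
#' are inclusive as in the definition: ALT \eqn{\ge} 3x ULN, TB \eqn{\ge}
#' 2.5x ULN, and an interval of exactly 3 days is DSP.
#'
#' @param alt,tb Nonempty \code{\link{lab_series}} for ALT and TB.
#' @param uln A \code{\link{uln_table}}.
#' @param alt_fold_min ALT peak threshold in fold of ULN (default 3).
#' @param tb_fold_min TB peak threshold in fold of ULN (default 2.5).
#' @param interval_days_min Peak-interval cut separating DOP from DSP
#'   (default 3 days; the boundary belongs to DSP).
#' @param require_tb_after_alt If TRUE, DSP additionally requires the TB peak
#'   to occur after the ALT peak (the schematic draws TB peaking later, but
#'   the definition itself does not order the peaks); double-peak patients
#'   with TB peaking >= 3 days *before* ALT are then DOP.
#' @return A list of class \code{"pattern_call"}: \code{pattern} (one of
#'   \code{\link{PATTERNS}}), \code{alt_peak}, \code{tb_peak} (see
#'   \code{\link{find_peak}}), \code{interval_days}.
#' @export
classify_pattern <- function(alt, tb, uln = uln_table(),
                             alt_fold_min = 3, tb_fold_min = 2.5,
                             interval_days_min = 3,
                             require_tb_after_alt = FALSE) {
  if (length(alt) == 0 || length(tb) == 0) {
    stop("pattern classification needs nonempty ALT and TB series")
  }
  pa <- find_peak(alt, uln)
  pb <- find_peak(tb, uln)
  alt_hit <- pa$fold_peak >= alt_fold_min
  tb_hit <- pb$fold_peak >= tb_fold_min
  interval <- abs(pb$t_peak - pa$t_peak)
  pattern <- if (alt_hit && !tb_hit) {
    "ALT_MONO"
  } else if (!alt_hit && tb_hit) {
    "TB_MONO"
  } else if (alt_hit && tb_hit) {
    separated <- interval >= interval_days_min &&
      (!require_tb_after_alt || pb$t_peak > pa$t_peak)
    if (separated) "DSP" else "DOP"
  } else {
    "NONE"
  }
  structure(list(pattern = pattern, alt_peak = pa, tb_peak = pb,
                 interval_days = interval),
            class = "pattern_call")
}

restrict_series <- function(series, day) {
  keep <- series$points$t <= day
  structure(list(analyte = series$analyte,
                 points = series$points[keep, , drop = FALSE]),
            class = "lab_series")
}

#' Day at which the dynamic pattern became determinable
#'
#' Scans prefixes of the observed trajectories: the confirmation day is the
#' smallest observation day from which classifying the data seen so far
#' yields the full-trajectory pattern at that day and at every later day.
#' Because thresholds apply to running peaks, prefix labels can only move
#' along monotone routes (e.g. NONE to ALT_MONO to DOP/DSP), so stability of
#' the prefix label through the end of follow-up is exactly the point where
#' the call could have been made in real time.
#'
#' @inheritParams classify_pattern
#' @param admission_day Day of hospital admission (days since onset); kept
#'   with the result so "confirmed within k days of admission" statistics can
#'   be derived.
#' @return List with \code{confirmed_at_day} (absolute day since onset),
#'   \code{days_from_admission} (clamped at 0 for pre-admission confirmation)
#'   and \code{pattern} (the full-trajectory label).
#' @export
confirmation_day <- function(alt, tb, uln = uln_table(), admission_day = 0,
                             alt_fold_min = 3, tb_fold_min = 2.5,
                             interval_days_min = 3,
                             require_tb_after_alt = FALSE) {
  if (length(alt) == 0 || length(tb) == 0) {
    stop("confirmation needs nonempty ALT and TB series")
  }
  if (admission_day < 0) stop("admission_day must be >= 0")
  full <- classify_pattern(alt, tb, uln, alt_fold_min, tb_fold_min,
                           interval_days_min, require_tb_after_alt)
  days <- sort(unique(c(alt$points$t, tb$points$t)))
  prefix_label <- vapply(days, function(d) {
    a <- restrict_series(alt, d)
    b <- restrict_series(tb, d)
    if (length(a) == 0 || length(b) == 0) return(NA_character_)
    classify_pattern(a, b, uln, alt_fold_min, tb_fold_min,
                     interval_days_min, require_tb_after_alt)$pattern
  }, character(1))
  stable_from <- NA_real_
  for (i in seq_along(days)) {
    tail_ok <- all(!is.na(prefix_label[i:length(days)]) &
                     prefix_label[i:length(days)] == full$pattern)
    if (tail_ok) { stable_from <- days[i]; break }
  }
  list(confirmed_at_day = stable_from,
       days_from_admission = if (is.na(stable_from)) NA_real_ else
         max(stable_from - admission_day, 0),
       pattern = full$pattern)
}
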