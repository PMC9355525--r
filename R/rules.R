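#' @title Single-time-point prognostic rules and injury-type classification
#' @description Comparator rules long used to flag severe DILI from one panel
#'   of biochemistry: Hy's law, new Hy's law (nR-based) and the Robles-Diaz
#'   model, plus the CIOMS R-value injury-type classification.  Inequality
#'   strictness follows the published wordings verbatim (a mixture of strict
#'   and inclusive bounds); boundary behaviour is the whole content of these
#'   rules, so no harmonization is attempted.
#' @name rule_models
NULL

#' Assemble the onset (or peak) biochemistry panel a rule consumes
#'
#' @param alt_fold,ast_fold,alp_fold,tb_fold Values in fold of ULN (>= 0).
#' @param ast_raw,alt_raw Raw AST and ALT in U/L, used only for the AST/ALT
#'   ratio of the Robles-Diaz model (ULNs need not cancel if ALT and AST have
#'   different laboratory ULNs).
#' @return List of class \code{"onset_panel"}.
#' @export
onset_panel <- function(alt_fold, ast_fold, alp_fold, tb_fold,
                        ast_raw = NA_real_, alt_raw = NA_real_) {
  folds <- c(alt_fold, ast_fold, alp_fold, tb_fold)
  if (any(!is.finite(folds)) || any(folds < 0)) {
    stop("fold-of-ULN values must be finite and >= 0")
  }
  structure(list(alt_fold = alt_fold, ast_fold = ast_fold,
                 alp_fold = alp_fold, tb_fold = tb_fold,
                 ast_raw = ast_raw, alt_raw = alt_raw),
            class = "onset_panel")
}

#' CIOMS R value
#'
#' R = (ALT / ALT ULN) / (ALP / ALP ULN).
#'
#' @param alt_fold ALT in fold of ULN (>= 0).
#' @param alp_fold ALP in fold of ULN (> 0).
#' @export
r_value <- function(alt_fold, alp_fold) {
  if (any(alp_fold == 0)) stop("ALP fold must be > 0 to form the R value")
  alt_fold / alp_fold
}

#' nR value: the higher of the ALT and AST folds over the ALP fold
#' @param alt_fold,ast_fold ALT/AST in fold of ULN.
#' @param alp_fold ALP in fold of ULN (> 0).
#' @export
nr_value <- function(alt_fold, ast_fold, alp_fold) {
  if (any(alp_fold == 0)) stop("ALP fold must be > 0 to form the nR value")
  pmax(alt_fold, ast_fold) / alp_fold
}

#' Classify the injury type from the R value
#'
#' Hepatocellular: R >= 5; cholestatic: R <= 2; mixed: 2 < R < 5 (both
#' boundaries belong to the outer classes).
#'
#' @param r Nonnegative R (or nR) value.
#' @return "hepatocellular", "cholestatic" or "mixed"; vectorised.
#' @export
classify_injury <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop("R value must be finite and >= 0")
  ifelse(r >= 5, "hepatocellular", ifelse(r <= 2, "cholestatic", "mixed"))
}

#' Hy's law
#'
#' Positive iff (ALT > 3x ULN or AST > 3x ULN) and TB > 2x ULN and
#' ALP < 2x ULN.  All three comparisons are strict.
#'
#' @param p An \code{\link{onset_panel}}.
#' @return List of class \code{"rule_verdict"} with \code{rule} and
#'   \code{positive}.
#' @export
hys_law <- function(p) {
  pos <- (p$alt_fold > 3 || p$ast_fold > 3) && p$tb_fold > 2 && p$alp_fold < 2
  structure(list(rule = "hys_law", positive = pos), class = "rule_verdict")
}

#' New Hy's law
#'
#' Positive iff TB > 2x ULN and nR >= 5 (TB strict, nR inclusive).
#'
#' @inheritParams hys_law
#' @export
new_hys_law <- function(p) {
  pos <- p$tb_fold > 2 && nr_value(p$alt_fold, p$ast_fold, p$alp_fold) >= 5
  structure(list(rule = "new_hys_law", positive = pos), class = "rule_verdict")
}

#' Robles-Diaz model
#'
#' Positive iff AST > 17.3x ULN and TB > 6.6x ULN, or AST <= 17.3x ULN but
#' AST/ALT > 1.5 (the ratio uses raw U/L values).
#'
#' @inheritParams hys_law
#' @export
robles_diaz <- function(p) {
  branch1 <- p$ast_fold > 17.3 && p$tb_fold > 6.6
  branch2 <- FALSE
  if (p$ast_fold <= 17.3) {
    if (!is.finite(p$ast_raw) || !is.finite(p$alt_raw)) {
      stop("raw AST and ALT are required for the AST/ALT ratio branch")
    }
    if (p$alt_raw == 0) stop("ALT = 0: AST/ALT ratio undefined")
    branch2 <- p$ast_raw / p$alt_raw > 1.5
  }
  structure(list(rule = "robles_diaz", positive = branch1 || branch2),
            class = "rule_verdict")
}

#' Evaluate every comparator rule on a panel
#'
#' @inheritParams hys_law
#' @return Named logical vector (hys_law, new_hys_law, robles_diaz).
#' @export
all_rules <- function(p) {
  c(hys_law = hys_law(p)$positive,
    new_hys_law = new_hys_law(p)$positive,
    robles_diaz = robles_diaz(p)$positive)
}

#' Build the onset panel of a patient record
#'
#' @param patient A \code{\link{patient_record}}.
#' @param uln A \code{\link{uln_table}}.
#' @param at "onset" (default) evaluates the rules on onset values, matching
#'   the covariates of the optimized model; "peak" uses each series' maximum.
#' @export
panel_from_patient <- function(patient, uln = uln_table(), at = c("onset", "peak")) {
  at <- match.arg(at)
  grab <- function(analyte, onset_field) {
    if (at == "peak" && analyte %in% names(patient$series)) {
      return(find_peak(patient$series[[analyte]], uln)$value_peak)
    }
    patient[[onset_field]]   # analytes without a trajectory keep onset values
  }
  alt <- grab("ALT", "onset_alt"); ast <- grab("AST", "onset_ast")
  alp <- grab("ALP", "onset_alp"); tb <- grab("TB", "onset_tb")
  onset_panel(alt_fold = fold_uln(alt, "ALT", uln),
              ast_fold = fold_uln(ast, "AST", uln),
              alp_fold = fold_uln(alp, "ALP", uln),
              tb_fold = fold_uln(tb, "TB", uln),
              ast_raw = ast, alt_raw = alt)
}
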