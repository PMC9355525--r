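#' Upper-limit-of-normal (ULN) table
#'
#' Builds a named ULN table for the five analytes every rule in the package is
#' expressed against.  All thresholds in the pattern classifier and the
#' prognostic rules are stated in multiples of ULN ("fold of ULN"), so the
#' actual laboratory ULNs only matter when raw measurements are ingested; the
#' defaults follow common Chinese hospital laboratory conventions and can be
#' overridden per analyte.
#'
#' @param alt ULN of alanine aminotransferase, U/L.
#' @param ast ULN of aspartate aminotransferase, U/L.
#' @param alp ULN of alkaline phosphatase, U/L.
#' @param ggt ULN of gamma-glutamyltransferase, U/L.
#' @param tb  ULN of total bilirubin, umol/L.
#' @return A named numeric vector of class \code{"uln_table"}.  INR is
#'   dimensionless and deliberately carries no entry.
#' @examples
#' uln <- uln_table()
#' fold_uln(120, "ALT", uln)   # 3x ULN
#' @export
uln_table <- function(alt = 40, ast = 40, alp = 125, ggt = 50, tb = 17.1) {
  u <- c(ALT = alt, AST = ast, ALP = alp, GGT = ggt, TB = tb)
  if (any(!is.finite(u)) || any(u <= 0)) {
    stop("all ULN values must be finite and strictly positive")
  }
  structure(u, class = "uln_table")
}

#' Convert a raw laboratory value to fold of ULN
#'
#' @param value Numeric value(s) in the analyte's native units.
#' @param analyte One of "ALT", "AST", "ALP", "GGT", "TB".  INR has no ULN and
#'   is rejected.
#' @param uln A \code{\link{uln_table}}.
#' @return \code{value / ULN(analyte)}; vectorised over \code{value}.
#' @export
fold_uln <- function(value, analyte, uln = uln_table()) {
  if (length(analyte) != 1L) stop("one analyte at a time")
  if (identical(toupper(analyte), "INR")) {
    stop("INR is dimensionless and has no ULN")
  }
  key <- toupper(analyte)
  if (!key %in% names(uln)) {
    stop("unknown analyte '", analyte, "': no ULN available")
  }
  if (any(!is.finite(value))) stop("non-finite value for analyte ", analyte)
  as.numeric(value) / unname(uln[[key]])
}
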