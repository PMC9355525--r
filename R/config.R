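#' Read an analysis configuration from YAML
#'
#' Supported keys (all optional, defaults in parentheses):
#' \preformatted{
#' uln:                       # laboratory upper limits of normal
#'   alt: 40                  # U/L
#'   ast: 40                  # U/L
#'   alp: 125                 # U/L
#'   ggt: 50                  # U/L
#'   tb: 17.1                 # umol/L
#' thresholds:
#'   alt_fold_min: 3          # ALT peak threshold, x ULN
#'   tb_fold_min: 2.5         # TB peak threshold, x ULN
#'   interval_days_min: 3     # DOP/DSP peak-interval cut, days
#'   require_tb_after_alt: no # restrict DSP to TB peaking after ALT
#' seed: 1
#' }
#'
#' @param path Path to a YAML file.
#' @return List with \code{uln} (a \code{\link{uln_table}}),
#'   \code{thresholds} and \code{seed}, ready to splice into
#'   \code{\link{classify_pattern}} and \code{\link{sim_config}}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  u <- raw$uln
  uln <- uln_table(alt = u$alt %||% 40, ast = u$ast %||% 40,
                   alp = u$alp %||% 125, ggt = u$ggt %||% 50,
                   tb = u$tb %||% 17.1)
  th <- raw$thresholds
  thresholds <- list(
    alt_fold_min = th$alt_fold_min %||% 3,
    tb_fold_min = th$tb_fold_min %||% 2.5,
    interval_days_min = th$interval_days_min %||% 3,
    require_tb_after_alt = isTRUE(th$require_tb_after_alt))
  list(uln = uln, thresholds = thresholds,
       seed = as.integer(raw$seed %||% 1L))
}
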