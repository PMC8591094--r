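#' Reference 15-subnetwork risk coefficients
#'
#' The one-decimal coefficient set used in the package's worked examples:
#' fifteen multivariate Cox coefficients for a colorectal-cancer
#' subnetwork-marker risk score. With every activity score set to 1 the
#' risk score is the plain coefficient sum, -5.4.
#'
#' @return Data frame with columns `subnetwork` and `beta` (15 rows).
#' @export
reference_risk_coefficients <- function() {
  path <- system.file("extdata", "risk_coefficients_15.tsv",
                      package = "subnetmark", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
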