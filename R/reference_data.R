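#' Published reference estimates from a Scots pine diallel study
#'
#' Ships the reported genetic-parameter tables of a published genomic
#' evaluation of a Scots pine partial-diallel progeny trial (695 full-sib
#' progeny from 184 families of 40 parents, 6,344 SNPs) so that every
#' derived statistic - heritabilities, variance fractions, predictive
#' accuracies - can be recomputed from the printed variance components and
#' predictive abilities and checked against the printed values.
#'
#' `"variance_components"`: per trait and model, the AIC, the estimated
#' variance components (`add`, `dom`, `aa`, `ad`, `dd`, `residual`;
#' components reported as fixed at the zero boundary are stored as 0,
#' unfitted components as `NA`) and the reported `h2`/`H2`.
#' `"predictive_ability"`: per trait, method and effect set, the reported
#' cross-validated predictive ability `r1` and accuracy `r2`, separately
#' for additive and total-genetic predictions.
#'
#' @param table which table to load.
#' @return A `data.frame`.
#' @examples
#' vc <- reference_estimates("variance_components")
#' head(vc)
#' @export
reference_estimates <- function(table = c("variance_components",
                                          "predictive_ability")) {
  table <- match.arg(table)
  path <- system.file("extdata",
                      paste0("scots_pine_", table, ".csv"),
                      package = "pineGS", mustWork = TRUE)
  out <- as.data.frame(data.table::fread(path))
  out
}
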