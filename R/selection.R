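#' Truncation-selection intensity
#'
#' The mean deviation, in phenotypic standard deviation units, of the
#' selected fraction under truncation selection on a normal trait:
#' `i = dnorm(z) / p` with `z` the upper-`p` standard normal quantile.
#' Selecting the top 1% gives `i = 2.67` (to two decimals).
#'
#' @param p proportion selected, in (0, 1]; `p = 1` returns 0.
#' @return Selection intensity `i`.
#' @examples
#' selection_intensity(0.01)
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]")
  ifelse(p == 1, 0, stats::dnorm(stats::qnorm(1 - p)) / p)
}

#' Response to selection as a percentage of the population mean
#'
#' `100 * (mean(selected) - mean(all)) / mean(all)`, with the selected set
#' the top fraction ranked by the same values. Values must be on the
#' phenotype scale (add the fitted overall mean to BLUPs first): because
#' the denominator is the population mean, the percentage is not invariant
#' to shifting the values, and centered BLUPs would make it ill-defined.
#'
#' @param values per-individual EGV or EBV, phenotype scale.
#' @param proportion fraction selected in (0, 1]; the number selected is
#'   `max(1, round(proportion * n))`.
#' @return Response percentage (RGS for genomic, RPS for pedigree models).
#' @examples
#' response_percent(c(90, 100, 110, 120), 0.25)  # 14.29
#' @export
response_percent <- function(values, proportion) {
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0, 1]")
  mu <- mean(values)
  if (mu == 0) stop("population mean is zero; percentage undefined")
  n_sel <- max(1L, round(proportion * length(values)))
  sel <- sort(values, decreasing = TRUE)[seq_len(n_sel)]
  100 * (mean(sel) - mu) / mu
}

#' Per-year scaling of a selection response
#'
#' Divides a per-cycle response by the breeding-cycle length: genomic
#' selection is credited with a shortened cycle (11 years by default,
#' i.e. a 50% reduction) against conventional phenotypic selection
#' (23 years).
#'
#' @param R response percentage per cycle.
#' @param cycle_years breeding-cycle length in years.
#' @return Response in % per year.
#' @export
response_per_year <- function(R, cycle_years) {
  if (any(cycle_years <= 0)) stop("cycle_years must be positive")
  R / cycle_years
}

#' Expected genetic gain under truncation selection
#'
#' Classical mass-selection gain expressed as a percentage of the
#' population mean: `100 * i * heritability * sigma_p / mean`, with the
#' narrow-sense heritability for additive-only deployment (seed orchard)
#' or the broad-sense heritability for total-genetic deployment (clonal
#' propagation).
#'
#' @param heritability `h2` or `H2`, in \[0, 1\].
#' @param i selection intensity (see [selection_intensity()]).
#' @param sigma_p phenotypic standard deviation, trait units.
#' @param mean population mean, trait units (nonzero).
#' @return Expected gain, % of the mean.
#' @examples
#' expected_gain(0.25, 2.67, 20, 100)  # 13.35
#' @export
expected_gain <- function(heritability, i, sigma_p, mean) {
  if (any(mean == 0)) stop("population mean is zero; percentage undefined")
  if (any(heritability < 0 | heritability > 1))
    stop("heritability must lie in [0, 1]")
  100 * i * heritability * sigma_p / mean
}
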