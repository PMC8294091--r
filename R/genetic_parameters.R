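#' Narrow- and broad-sense heritability from variance components
#'
#' `h2 = s2_add / s2_p` and `H2 = s2_g / s2_p`, where `s2_g` is the sum of
#' every fitted genetic component (additive, dominance and the epistatic
#' terms the model includes, boundary-fixed components entering as 0) and
#' `s2_p = s2_g + s2_residual`. Full precision is retained; rounding (2
#' decimals, the reporting convention) happens only in `print()`.
#'
#' @param vc a [fit_reml()] result, or a named numeric vector of variance
#'   components with an element `residual` and genetic components among
#'   `add`, `dom`, `aa`, `ad`, `dd` (useful for recomputing published
#'   tables).
#' @return An object of class `HeritabilityReport`: list with `h2`, `H2`,
#'   `sigma2_g`, `sigma2_p`, `fractions` (percent of phenotypic variance
#'   per component, residual included).
#' @examples
#' heritability(c(add = 2166.02, dom = 0.56, aa = 3573.72, ad = 0.01,
#'                dd = 0.01, residual = 3936.31))
#' @export
heritability <- function(vc) {
  est <- .vc_estimates(vc)
  gen <- setdiff(names(est), "residual")
  sigma2_g <- sum(est[gen])
  sigma2_p <- sigma2_g + est[["residual"]]
  if (sigma2_p <= 0) stop("phenotypic variance is zero")
  h2 <- if ("add" %in% gen) est[["add"]] / sigma2_p else NA_real_
  out <- list(h2 = h2, H2 = sigma2_g / sigma2_p,
              sigma2_g = sigma2_g, sigma2_p = sigma2_p,
              fractions = variance_fractions(est))
  class(out) <- "HeritabilityReport"
  out
}

.vc_estimates <- function(vc) {
  if (inherits(vc, "VarianceComponents")) return(vc$estimates)
  if (is.numeric(vc) && !is.null(names(vc)) && "residual" %in% names(vc))
    return(vc)
  stop("vc must be a VarianceComponents object or a named numeric vector ",
       "with a 'residual' element")
}

#' Per-component percentages of the phenotypic variance
#'
#' Each fitted component (residual included) divided by the phenotypic
#' variance, times 100. Fractions sum to 100.
#'
#' @inheritParams heritability
#' @return Named numeric vector of percentages.
#' @examples
#' variance_fractions(c(add = 269.57, dom = 501.60, residual = 1009.78))
#' @export
variance_fractions <- function(vc) {
  est <- .vc_estimates(vc)
  sigma2_p <- sum(est)
  if (sigma2_p <= 0) stop("phenotypic variance is zero")
  100 * est / sigma2_p
}

#' @export
print.HeritabilityReport <- function(x, ...) {
  cat(sprintf("h2 = %.2f, H2 = %.2f (sigma2_g = %.4g, sigma2_p = %.4g)\n",
              x$h2, x$H2, x$sigma2_g, x$sigma2_p))
  cat("variance fractions (%):\n")
  print(round(x$fractions, 2))
  invisible(x)
}
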