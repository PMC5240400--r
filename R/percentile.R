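#' Type-7 percentile
#'
#' Quantile of a numeric vector using the Hyndman-Fan type 7 definition
#' (linear interpolation between order statistics at \eqn{h = (n-1)p + 1}),
#' the default of \code{\link[stats]{quantile}} and the "R7" estimator of
#' Apache Commons Math. All gene-level percentiles in this package (the
#' pathogenic allele-frequency ceiling and the 95th percentile
#' sensitivity/specificity CADD thresholds) use this definition.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param p A single probability in \eqn{[0, 1]}.
#' @return The type-7 percentile as a single numeric value.
#' @examples
#' percentileR7(c(1, 2, 3, 4), 0.5)  # 2.5
#' @export
percentileR7 <- function(values, p) {
    if (length(values) == 0L) {
        stop("percentileR7: 'values' must be non-empty")
    }
    if (!is.numeric(values) || any(!is.finite(values))) {
        stop("percentileR7: 'values' must be finite numerics")
    }
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
        stop("percentileR7: 'p' must be a single probability in [0, 1]")
    }
    unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}
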