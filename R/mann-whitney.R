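#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples, as used to test per-gene CADD score
#' separation between pathogenic and matched benign variants. When both
#' samples have at most 8 observations and no ties are present, the exact
#' two-sided p value is used; otherwise the normal approximation with tie
#' correction is applied (via \code{\link[stats]{wilcox.test}}).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with \code{U} (the Mann-Whitney U statistic for \code{a}
#'   over \code{b}) and \code{p} (two-sided p value).
#' @examples
#' mannWhitneyU(c(10, 11, 12, 13, 14), c(1, 2, 3, 4, 5))  # U = 25
#' @export
mannWhitneyU <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) {
        stop("mannWhitneyU: both samples must be non-empty")
    }
    if (!is.numeric(a) || !is.numeric(b) ||
        any(!is.finite(a)) || any(!is.finite(b))) {
        stop("mannWhitneyU: samples must be finite numerics")
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- length(a) <= 8L && length(b) <= 8L && !ties
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = !exact)
    )
    list(U = unname(wt$statistic), p = min(1, unname(wt$p.value)))
}
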