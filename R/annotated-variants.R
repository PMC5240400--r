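# Accessors and methods for AnnotatedVariants.

#' @rdname AnnotatedVariants-class
#' @param object,x An \linkS4class{AnnotatedVariants} object.
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("impactCategory", function(x) standardGeneric("impactCategory"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("caddScore", function(x) standardGeneric("caddScore"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("truthLabel", function(x) standardGeneric("truthLabel"))
#' @rdname AnnotatedVariants-class
#' @export
setGeneric("variantKey", function(x) standardGeneric("variantKey"))

#' @rdname AnnotatedVariants-class
setMethod("refAllele", "AnnotatedVariants", function(x) mcols(x)$ref)
#' @rdname AnnotatedVariants-class
setMethod("altAllele", "AnnotatedVariants", function(x) mcols(x)$alt)
#' @rdname AnnotatedVariants-class
setMethod("geneSymbol", "AnnotatedVariants", function(x) mcols(x)$gene)
#' @rdname AnnotatedVariants-class
setMethod("impactCategory", "AnnotatedVariants", function(x) mcols(x)$impact)
#' @rdname AnnotatedVariants-class
setMethod("caddScore", "AnnotatedVariants", function(x) mcols(x)$cadd)
#' @rdname AnnotatedVariants-class
setMethod("alleleFreq", "AnnotatedVariants", function(x) mcols(x)$af)
#' @rdname AnnotatedVariants-class
setMethod("truthLabel", "AnnotatedVariants", function(x) mcols(x)$label)

#' @rdname AnnotatedVariants-class
setMethod("variantKey", "AnnotatedVariants", function(x) {
    paste(as.character(seqnames(x)), start(x),
          mcols(x)$ref, mcols(x)$alt, sep = ":")
})

#' @rdname AnnotatedVariants-class
#' @param row.names,optional,... Passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "AnnotatedVariants",
    function(x, row.names = NULL, optional = FALSE, ...) {
        m <- mcols(x)
        data.frame(
            chrom = as.character(seqnames(x)), pos = start(x),
            ref = m$ref, alt = m$alt, gene = m$gene, impact = m$impact,
            cadd = m$cadd, af = m$af, label = m$label,
            significance = m$significance,
            row.names = row.names, stringsAsFactors = FALSE
        )
    })

setMethod("show", "AnnotatedVariants", function(object) {
    n <- length(object)
    cat("AnnotatedVariants with", n, "variant instance(s) in",
        length(unique(mcols(object)$gene)), "gene(s)\n")
    if (n > 0L) {
        lab <- table(factor(mcols(object)$label, levels = TRUTH_LABELS),
                     useNA = "ifany")
        cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "),
            "\n")
        callNextMethod()
    }
})
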