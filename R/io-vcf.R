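# VCF import/export. Reading goes through VariantAnnotation; writing
# serializes the simple sites-only records this package produces.

#' Default INFO key configuration
#'
#' Upstream annotators differ in the INFO keys they emit, so every reader
#' and writer takes a key configuration. Defaults: SnpEff-style \code{ANN}
#' annotations, \code{CADD} scaled scores, \code{EXAC_AF} population allele
#' frequencies and \code{CLNSIG} clinical significance.
#'
#' @param ann,cadd,af,significance INFO key names.
#' @return A named list of INFO keys.
#' @export
vcfFieldDefaults <- function(ann = "ANN", cadd = "CADD", af = "EXAC_AF",
                             significance = "CLNSIG") {
    list(ann = ann, cadd = cadd, af = af, significance = significance)
}

# structural pre-scan so malformed files fail with a line number,
# which readVcf does not report
.preScanVcf <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=VCF")) {
        stop("VCF parse error at line 1: missing ##fileformat header in ",
             path)
    }
    hdr <- which(startsWith(lines, "#CHROM"))
    if (length(hdr) != 1L) {
        stop("VCF parse error: expected exactly one #CHROM header line in ",
             path)
    }
    body <- which(!startsWith(lines, "#"))
    body <- body[body > hdr]
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 8L]
    if (length(bad) > 0L) {
        stop("VCF parse error at line ", bad[1L],
             ": fewer than 8 tab-separated fields")
    }
    length(body)
}

.infoColumn <- function(vcf, key, as = "numeric") {
    inf <- VariantAnnotation::info(vcf)
    if (!key %in% colnames(inf)) {
        return(rep(if (as == "numeric") NA_real_ else NA_character_,
                   nrow(inf)))
    }
    v <- inf[[key]]
    if (is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) {
            if (length(x) == 0L || all(is.na(x)))
                if (as == "numeric") NA_real_ else NA_character_
            else if (as == "numeric") as.numeric(x[[1L]])
            else paste(as.character(x), collapse = ",")
        }, if (as == "numeric") numeric(1) else character(1))
    } else {
        v <- if (as == "numeric") as.numeric(v) else as.character(v)
    }
    v
}

# parse SnpEff-style ANN entries for one expanded record; returns a
# data.frame with one row per distinct gene (first = most severe impact)
.parseAnn <- function(entries, altAllele, key) {
    if (length(entries) == 0L || all(is.na(entries))) {
        return(data.frame(gene = NA_character_, impact = NA_character_,
                          stringsAsFactors = FALSE))
    }
    parts <- strsplit(entries, "|", fixed = TRUE)
    keep <- vapply(parts, function(p) length(p) >= 4L && p[1L] == altAllele,
                   logical(1))
    parts <- parts[keep]
    if (length(parts) == 0L) {
        return(data.frame(gene = NA_character_, impact = NA_character_,
                          stringsAsFactors = FALSE))
    }
    gene <- vapply(parts, `[`, character(1), 4L)
    impact <- vapply(parts, `[`, character(1), 3L)
    bad <- !(impact %in% IMPACT_LEVELS)
    if (any(bad)) {
        stop("VCF parse error at ", key, ": unknown impact token '",
             impact[bad][1L], "'")
    }
    first <- !duplicated(gene)
    data.frame(gene = gene[first], impact = impact[first],
               stringsAsFactors = FALSE)
}

.normalizeLabel <- function(sig) {
    ifelse(is.na(sig), NA_character_,
    ifelse(grepl("pathogenic", sig, ignore.case = TRUE), "PATHOGENIC",
    ifelse(grepl("benign", sig, ignore.case = TRUE), "BENIGN", "VUS")))
}

#' Read an annotated VCF
#'
#' Imports a VCF v4.x file whose INFO fields carry SnpEff-style gene/impact
#' annotations, a scaled CADD score and a population allele frequency.
#' Multi-allelic records are expanded to one alternate allele each, and a
#' record whose annotation names several genes yields one variant instance
#' per distinct gene with the most severe impact listed for that gene.
#' Missing INFO fields yield absent (\code{NA}) values, never errors;
#' records with symbolic or non-ACGTN alleles are rejected and reported in
#' \code{metadata(result)$rejected} so that no record is silently dropped.
#'
#' @param path Path to a plain or bgzip-compressed VCF file.
#' @param fields INFO key configuration from [vcfFieldDefaults()].
#' @return An \linkS4class{AnnotatedVariants} object.
#' @export
readAnnotatedVcf <- function(path, fields = vcfFieldDefaults()) {
    .preScanVcf(path)
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)
    n <- length(vcf)
    gr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(seqnames(gr))
    pos <- start(gr)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    cadd <- .infoColumn(vcf, fields$cadd, "numeric")
    af <- .infoColumn(vcf, fields$af, "numeric")
    sig <- .infoColumn(vcf, fields$significance, "character")

    inf <- VariantAnnotation::info(vcf)
    ann <- if (fields$ann %in% colnames(inf)) inf[[fields$ann]]
           else replicate(n, character(0), simplify = FALSE)

    ok <- grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt)
    rejected <- data.frame(
        key = paste(chrom[!ok], pos[!ok], ref[!ok], alt[!ok], sep = ":"),
        reason = rep("symbolic or non-ACGTN allele", sum(!ok)),
        stringsAsFactors = FALSE
    )

    rows <- vector("list", n)
    for (i in which(ok)) {
        key <- paste(chrom[i], pos[i], ref[i], alt[i], sep = ":")
        g <- .parseAnn(as.character(ann[[i]]), alt[i], key)
        rows[[i]] <- data.frame(
            chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
            gene = g$gene, impact = g$impact, cadd = cadd[i], af = af[i],
            significance = sig[i], stringsAsFactors = FALSE
        )
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(df)) {
        df <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         gene = character(0), impact = character(0),
                         cadd = numeric(0), af = numeric(0),
                         significance = character(0))
    }
    out <- AnnotatedVariants(
        df$chrom, df$pos, df$ref, df$alt, gene = df$gene,
        impact = df$impact, cadd = df$cadd, af = df$af,
        label = .normalizeLabel(df$significance),
        significance = df$significance
    )
    metadata(out)$rejected <- rejected
    if (nrow(rejected) > 0L) {
        warning(nrow(rejected), " record instance(s) rejected (see ",
                "metadata(x)$rejected)")
    }
    out
}

.IMPACT_TERM <- c(HIGH = "stop_gained", MODERATE = "missense_variant",
                  LOW = "synonymous_variant", MODIFIER = "intergenic_region")

.sanitizeInfoText <- function(x) {
    gsub("[;=, ]+", "_", x)
}

# serialize variants (grouped by variant key) to VCF lines; extraKey /
# extraValues optionally add one more INFO key with per-instance values
.vcfLines <- function(variants, fields, extraKey = NULL,
                      extraValues = NULL) {
    df <- as.data.frame(variants)
    key <- variantKey(variants)
    contigs <- unique(df$chrom)
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s>", contigs),
        sprintf(paste0("##INFO=<ID=%s,Number=.,Type=String,Description=",
                       "\"Functional annotations: 'Allele | Annotation | ",
                       "Annotation_Impact | Gene_Name | Gene_ID'\">"),
                fields$ann),
        sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,",
                       "Description=\"Scaled CADD score\">"), fields$cadd),
        sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,Description=",
                       "\"Population allele frequency\">"), fields$af),
        sprintf(paste0("##INFO=<ID=%s,Number=.,Type=String,Description=",
                       "\"Clinical significance\">"), fields$significance)
    )
    if (!is.null(extraKey)) {
        header <- c(header, sprintf(
            paste0("##INFO=<ID=%s,Number=.,Type=String,Description=",
                   "\"Classification: Verdict|Rule|Source|Reason, one entry ",
                   "per annotated gene\">"), extraKey))
    }
    header <- c(header,
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))

    records <- character(0)
    for (k in unique(key)) {
        idx <- which(key == k)
        first <- idx[1L]
        annEntries <- character(0)
        for (i in idx) {
            if (!is.na(df$gene[i]) && !is.na(df$impact[i])) {
                annEntries <- c(annEntries, sprintf(
                    "%s|%s|%s|%s|%s", df$alt[i],
                    unname(.IMPACT_TERM[df$impact[i]]), df$impact[i],
                    df$gene[i], df$gene[i]))
            }
        }
        info <- character(0)
        if (length(annEntries) > 0L) {
            info <- c(info, paste0(fields$ann, "=",
                                   paste(annEntries, collapse = ",")))
        }
        if (!is.na(df$cadd[first])) {
            info <- c(info, sprintf("%s=%s", fields$cadd,
                                    formatC(df$cadd[first], format = "g",
                                            digits = 8)))
        }
        if (!is.na(df$af[first])) {
            info <- c(info, sprintf("%s=%s", fields$af,
                                    formatC(df$af[first], format = "g",
                                            digits = 8)))
        }
        sig <- .orElse(df$significance[first], df$label[first])
        if (!is.na(sig)) {
            info <- c(info, sprintf("%s=%s", fields$significance,
                                    .sanitizeInfoText(sig)))
        }
        if (!is.null(extraKey)) {
            info <- c(info, paste0(extraKey, "=",
                                   paste(extraValues[idx], collapse = ",")))
        }
        records <- c(records, paste(
            df$chrom[first], df$pos[first], ".", df$ref[first],
            df$alt[first], ".", ".",
            if (length(info) > 0L) paste(info, collapse = ";") else ".",
            sep = "\t"))
    }
    c(header, records)
}

#' Write annotated variants to a VCF file
#'
#' Serializes variants to a sites-only VCF v4.2 file, merging instances that
#' share (chrom, pos, ref, alt) into one record with one annotation entry
#' per gene. Reading the result with [readAnnotatedVcf()] recovers all
#' modeled fields.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object.
#' @param path Output file path.
#' @param fields INFO key configuration from [vcfFieldDefaults()].
#' @return \code{path}, invisibly.
#' @export
writeAnnotatedVcf <- function(variants, path, fields = vcfFieldDefaults()) {
    stopifnot(is(variants, "AnnotatedVariants"))
    writeLines(.vcfLines(variants, fields), path)
    invisible(path)
}

#' Write classified variants to a VCF file
#'
#' Like [writeAnnotatedVcf()] but adds one INFO key (default \code{VCLASS})
#' carrying, per gene instance, the verdict, the fired rule code, the rule
#' source and a human-readable reason.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object.
#' @param judgments The [classifyVariants()] result parallel to
#'   \code{variants}.
#' @param path Output file path.
#' @param fields INFO key configuration.
#' @param infoKey Name of the added INFO key.
#' @return \code{path}, invisibly.
#' @export
writeClassifiedVcf <- function(variants, judgments, path,
                               fields = vcfFieldDefaults(),
                               infoKey = "VCLASS") {
    stopifnot(is(variants, "AnnotatedVariants"),
              length(variants) == nrow(judgments))
    values <- sprintf("%s|%s|%s|%s", judgments$verdict, judgments$rule,
                      judgments$source, .sanitizeInfoText(judgments$reason))
    writeLines(.vcfLines(variants, fields, extraKey = infoKey,
                         extraValues = values), path)
    invisible(path)
}

#' Read back a classified VCF
#'
#' Re-imports a VCF written by [writeClassifiedVcf()], pairing every
#' (variant, gene) instance with its serialized judgment.
#'
#' @param path Path to the classified VCF.
#' @param fields INFO key configuration.
#' @param infoKey INFO key holding the classification entries.
#' @return A list with \code{variants} (\linkS4class{AnnotatedVariants})
#'   and \code{judgments} (a \linkS4class{DataFrame} with \code{verdict},
#'   \code{rule}, \code{source}, \code{reason}).
#' @export
readClassifiedVcf <- function(path, fields = vcfFieldDefaults(),
                              infoKey = "VCLASS") {
    variants <- readAnnotatedVcf(path, fields = fields)
    vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
    gr <- SummarizedExperiment::rowRanges(vcf)
    recKey <- paste(as.character(seqnames(gr)), start(gr),
                    as.character(VariantAnnotation::ref(vcf)),
                    as.character(VariantAnnotation::alt(vcf)), sep = ":")
    inf <- VariantAnnotation::info(vcf)
    if (!infoKey %in% colnames(inf)) {
        stop("INFO key '", infoKey, "' not present in ", path)
    }
    entries <- lapply(inf[[infoKey]], as.character)
    names(entries) <- recKey
    vkey <- variantKey(variants)
    within <- stats::ave(seq_along(vkey), vkey, FUN = seq_along)
    parts <- lapply(seq_along(vkey), function(i) {
        e <- entries[[vkey[i]]]
        if (is.null(e) || length(e) < within[i]) {
            return(c("VUS", "UNPARSED", "GENOME_WIDE", ""))
        }
        p <- strsplit(e[within[i]], "|", fixed = TRUE)[[1L]]
        length(p) <- 4L
        p
    })
    judgments <- DataFrame(
        verdict = vapply(parts, `[`, character(1), 1L),
        rule = vapply(parts, `[`, character(1), 2L),
        source = vapply(parts, `[`, character(1), 3L),
        reason = vapply(parts, `[`, character(1), 4L)
    )
    list(variants = variants, judgments = judgments)
}

#' Attach truth labels from a sidecar table
#'
#' @param variants An \linkS4class{AnnotatedVariants} object.
#' @param truth A data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{label}, e.g. from [readTruthTsv()].
#' @return \code{variants} with the \code{label} column filled in where the
#'   table matches; "likely" qualifiers in the table are merged into the
#'   plain labels.
#' @export
applyTruthLabels <- function(variants, truth) {
    stopifnot(is(variants, "AnnotatedVariants"))
    tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
    m <- match(variantKey(variants), tkey)
    lab <- .normalizeLabel(as.character(truth$label))
    hit <- !is.na(m)
    mcols(variants)$label[hit] <- lab[m[hit]]
    variants
}

#' Read a truth-label sidecar TSV
#'
#' @param path TSV with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{label} (free-text labels are normalized, merging
#'   "likely benign"/"likely pathogenic" into the plain classes).
#' @return A data.frame.
#' @export
readTruthTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    required <- c("chrom", "pos", "ref", "alt", "label")
    missing <- setdiff(required, colnames(df))
    if (length(missing) > 0L) {
        stop("truth table is missing column(s): ",
             paste(missing, collapse = ", "))
    }
    df$label <- .normalizeLabel(as.character(df$label))
    df
}
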