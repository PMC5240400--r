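# Independent oracles: brute-force reimplementations kept deliberately
# separate from the package's code paths.

# Hyndman-Fan type 7 quantile, directly from the interpolation formula
oracleType7 <- function(values, p) {
    x <- sort(values)
    n <- length(x)
    h <- (n - 1) * p + 1
    if (h <= 1) return(x[1])
    if (h >= n) return(x[n])
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# exact two-sided Mann-Whitney p by exhaustive enumeration over all
# assignments of the pooled ranks (no ties assumed)
oracleMwuExact <- function(a, b) {
    n <- length(a)
    m <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    sets <- utils::combn(n + m, n)
    us <- apply(sets, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    pLe <- mean(us <= uObs)
    pGe <- mean(us >= uObs)
    min(1, 2 * min(pLe, pGe))
}

# straight-line table-driven reimplementation of the classification
# cascade, operating on plain data.frames
oracleCascade <- function(df, calDf, defaults, setting = 5) {
    sev <- function(imp) match(imp, c("MODIFIER", "LOW", "MODERATE", "HIGH"))
    dist <- function(s) {
        if (is.na(s)) return(rep(NA_real_, 4))
        as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    }
    out <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        gene <- df$gene[i]
        impact <- df$impact[i]
        cadd <- df$cadd[i]
        af <- ifelse(is.na(df$af[i]), 0, df$af[i])
        row <- if (!is.na(gene)) calDf[calDf$Gene == gene, , drop = FALSE]
               else calDf[0, , drop = FALSE]
        verdict <- NA_character_
        if (nrow(row) == 1) {
            mafThr <- row$PathoMafThreshold * (1 + setting)
            if (!is.na(mafThr) && af > mafThr) verdict <- "Benign"
            if (is.na(verdict) && row$Category == "IMPACT_PREDICTIVE" &&
                !is.na(impact)) {
                pd <- dist(row$PathogenicImpactDistribution)
                bd <- dist(row$BenignImpactDistribution)
                lev <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
                uniq <- lev[!is.na(pd) & pd > 0 & !is.na(bd) & bd == 0]
                obs <- lev[!is.na(pd) & pd > 0]
                if (length(uniq) > 0 && sev(impact) >= min(sev(uniq))) {
                    verdict <- "Pathogenic"
                } else if (length(obs) > 0 && sev(impact) < min(sev(obs))) {
                    verdict <- "Benign"
                }
            }
            if (is.na(verdict) &&
                row$Category %in% c("CADD_PREDICTIVE",
                                    "CADD_LESS_PREDICTIVE", "LITTLE_DATA") &&
                !is.na(row$Sens95CaddThreshold) &&
                !is.na(row$Spec95CaddThreshold) && !is.na(cadd)) {
                pb <- max(row$Spec95CaddThreshold,
                          row$Sens95CaddThreshold - setting)
                verdict <- if (cadd >= pb) "Pathogenic"
                           else if (cadd <= row$Spec95CaddThreshold) "Benign"
                           else "VUS"
            }
        }
        if (is.na(verdict)) {
            verdict <- if (af > defaults$maf) "Benign"
                       else if (is.na(cadd)) "VUS"
                       else if (cadd > defaults$cadd) "Pathogenic"
                       else "Benign"
        }
        out[i] <- verdict
    }
    out
}

# brute-force confusion tally
oracleTally <- function(truth, verdict) {
    tp <- tn <- fp <- fn <- mp <- mn <- 0
    for (i in seq_along(truth)) {
        if (truth[i] == "PATHOGENIC") {
            if (verdict[i] == "Pathogenic") tp <- tp + 1
            else if (verdict[i] == "Benign") fn <- fn + 1
            else mp <- mp + 1
        } else {
            if (verdict[i] == "Benign") tn <- tn + 1
            else if (verdict[i] == "Pathogenic") fp <- fp + 1
            else mn <- mn + 1
        }
    }
    list(tp = tp, tn = tn, fp = fp, fn = fn, missedPos = mp, missedNeg = mn,
         sensitivity = tp / (tp + fn + mp),
         specificity = tn / (tn + fp + mn),
         accuracy = (tp + tn) / length(truth))
}
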