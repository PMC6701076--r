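# Independent oracles used to cross-check the package implementations.
# These are written from first principles and deliberately share no code
# with the functions they verify.

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by direct
# hypergeometric enumeration: with margins fixed, sum the probabilities of
# all tables no more probable than the observed one.
oracleFisher2x2 <- function(a, b, c, d) {
    m <- a + b          # row 1 total
    n <- c + d          # row 2 total
    k <- a + c          # column 1 total
    lo <- max(0L, k - n)
    hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Mantel-Haenszel log-rank chi-square from explicit risk-set sums.
oracleLogrank <- function(time, event, group) {
    group <- as.factor(group)
    stopifnot(nlevels(group) == 2)
    g1 <- levels(group)[1]
    o <- 0; e <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & group == g1)
        dTot <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == g1)
        o <- o + d1
        e <- e + dTot * n1 / n
        if (n > 1)
            v <- v + dTot * (n1 / n) * (1 - n1 / n) * (n - dTot) / (n - 1)
    }
    (o - e)^2 / v
}

# Benjamini-Hochberg step-up by hand.
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

# Neoepitope call truth table written independently of the package rule.
oracleNeoCall <- function(mut, wt, mhc, vtype,
                          cdnCut = 50, daiI = 10, daiII = 4) {
    dai <- wt / mut
    cdn <- mut < cdnCut
    adn <- if (mhc == "I") dai > daiI else dai > daiII
    pri <- (cdn && adn) || (cdn && vtype == "frameshift")
    c(cdn = cdn, adn = adn, priority = pri)
}

# Small deterministic MAF fixture used across mutation tests.
toyMaf <- function() {
    data.frame(
        Hugo_Symbol = c("MSH2", "TP53", "KRAS", "APC", "MLH1", "TP53",
                        "BRAF"),
        Chromosome = 1, Start_Position = 1:7,
        Reference_Allele = c("C", "C", "G", "T", "A", "C", "T"),
        Tumor_Seq_Allele2 = c("T", "T", "A", "G", "G", "A", "C"),
        Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                                   "Silent", "Nonsense_Mutation",
                                   "Nonsense_Mutation", "Silent",
                                   "Missense_Mutation"),
        Tumor_Sample_Barcode = c("S1", "S1", "S1", "S1", "S2", "S2", "S2"),
        t_ref_count = c(5, 7, 10, 30, 5, 8, 0),
        t_alt_count = c(5, 3, 10, 0, 15, 2, 12),
        stringsAsFactors = FALSE)
}

# Tiny expression SummarizedExperiment built directly (no generator).
toySe <- function(counts, lengths, tissue = NULL) {
    counts <- as.matrix(counts)
    if (is.null(tissue)) tissue <- rep("tumor", ncol(counts))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(max_transcript_length = lengths,
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(tissue = tissue,
                                       dataset = rep("COAD", ncol(counts)),
                                       row.names = colnames(counts)))
}
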