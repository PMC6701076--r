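#' Filter lowly expressed genes
#'
#' Computes counts-per-million against each sample's library size and
#' keeps a gene when its CPM reaches \code{cpmThreshold} in at least
#' \code{sampleFraction} of the samples (both boundaries inclusive, so a
#' gene at exactly 1 CPM in exactly half the samples is kept). The
#' removed genes are reported via a message.
#'
#' @param se SummarizedExperiment with a \code{counts} assay.
#' @param cpmThreshold CPM threshold (default 1).
#' @param sampleFraction required fraction of samples (default 0.5).
#' @return the filtered SummarizedExperiment.
#' @export
filterLowExpression <- function(se, cpmThreshold = 1,
                                sampleFraction = 0.5) {
    counts <- SummarizedExperiment::assay(se, "counts")
    lib <- colSums(counts)
    if (any(lib <= 0))
        stop("library size must be positive for every sample",
             call. = FALSE)
    cpm <- sweep(counts, 2, lib, "/") * 1e6
    keep <- rowMeans(cpm >= cpmThreshold) >= sampleFraction
    message(sprintf("filterLowExpression: removed %d of %d genes",
                    sum(!keep), length(keep)))
    se[keep, ]
}

.log2cpm <- function(counts) {
    lib <- colSums(counts)
    log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
}

#' Two-group differential expression between cytolytic strata
#'
#' A deliberately simple two-group test: counts are transformed to log2
#' CPM with a 0.5-count stabilizer, and each gene is tested with Welch's
#' unequal-variance t-test between CYT-high and CYT-low samples.
#' Log2 fold-change is the mean difference (high minus low); q-values are
#' BH-adjusted across the tested genes, and a gene is called at
#' \code{q < deFdr}.
#'
#' @param se filtered SummarizedExperiment (see
#'   \code{\link{filterLowExpression}}).
#' @param strata data.frame from \code{\link{stratifyCyt}}, or any table
#'   with \code{sample_id} and a two-level \code{stratum}; only samples
#'   labelled with the two extreme strata enter the test. Each group
#'   needs at least 3 samples.
#' @param deFdr FDR call threshold (default 0.1).
#' @param groups optional length-2 character giving the stratum labels to
#'   contrast (default \code{c("CYT-high", "CYT-low")}).
#' @return data.frame with \code{gene}, \code{log2fc}, \code{t},
#'   \code{df}, \code{p}, \code{q}, \code{called}, sorted by \code{q}.
#' @export
differentialExpression <- function(se, strata, deFdr = 0.1,
                                   groups = c("CYT-high", "CYT-low")) {
    stopifnot(all(c("sample_id", "stratum") %in% colnames(strata)))
    hi <- strata$sample_id[strata$stratum == groups[1]]
    lo <- strata$sample_id[strata$stratum == groups[2]]
    hi <- intersect(hi, colnames(se)); lo <- intersect(lo, colnames(se))
    if (length(hi) < 3 || length(lo) < 3)
        stop("each stratum needs at least 3 samples with expression data",
             call. = FALSE)
    lcpm <- .log2cpm(SummarizedExperiment::assay(se, "counts"))
    x <- lcpm[, hi, drop = FALSE]; y <- lcpm[, lo, drop = FALSE]
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1)
    vy <- rowSums((y - my)^2) / (ny - 1)
    sterr2 <- vx / nx + vy / ny
    tstat <- (mx - my) / sqrt(sterr2)
    df <- sterr2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[sterr2 == 0] <- 1            # constant genes carry no evidence
    q <- p.adjust(p, method = "BH")
    out <- data.frame(gene = rownames(se), log2fc = mx - my, t = tstat,
                      df = df, p = p, q = q, called = q < deFdr,
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$q, out$p), ]
}

#' Correlate checkpoint gene expression with the cytolytic index
#'
#' Pearson correlation (two-sided p) of each checkpoint gene's
#' log2 TPM against the per-sample cytolytic index.
#'
#' @param se SummarizedExperiment with a \code{tpm} assay.
#' @param cyt data.frame with \code{sample_id} and \code{cyt_index}.
#' @param checkpointGenes gene panel; genes absent from the matrix are
#'   dropped with a message.
#' @return data.frame with \code{gene}, \code{pearson_r}, \code{p},
#'   \code{n}.
#' @export
checkpointCorrelation <- function(se, cyt,
                                  checkpointGenes = cytConfig()@checkpointGenes) {
    if (!"tpm" %in% SummarizedExperiment::assayNames(se))
        stop("run computeTpm() first: no 'tpm' assay", call. = FALSE)
    present <- intersect(checkpointGenes, rownames(se))
    if (length(present) < length(checkpointGenes))
        message("checkpointCorrelation: dropping absent gene(s): ",
                paste(setdiff(checkpointGenes, present), collapse = ", "))
    idx <- match(cyt$sample_id, colnames(se))
    stopifnot(!anyNA(idx))
    ltpm <- log2(SummarizedExperiment::assay(se, "tpm")[present, idx,
                                                        drop = FALSE])
    rows <- lapply(present, function(g) {
        x <- ltpm[g, ]
        if (stats::sd(x) == 0 || stats::sd(cyt$cyt_index) == 0)
            return(data.frame(gene = g, pearson_r = NA_real_, p = NA_real_,
                              n = length(x)))
        ct <- cor.test(x, cyt$cyt_index, method = "pearson")
        data.frame(gene = g, pearson_r = unname(ct$estimate),
                   p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Compare checkpoint expression between MSI and MSS tumors
#'
#' Per checkpoint gene, a two-sided Mann-Whitney test on log2 TPM between
#' MSI and MSS samples, BH-adjusted across the panel; the direction is
#' the group with the higher median.
#'
#' @param se SummarizedExperiment with a \code{tpm} assay.
#' @param msiStatus named vector of \code{MSI}/\code{MSS} labels keyed by
#'   sample ID (see \code{\link{classifyMsiFromMaf}}).
#' @param checkpointGenes gene panel.
#' @return data.frame with \code{gene}, \code{U}, \code{p}, \code{q},
#'   \code{direction} (\code{MSI}/\code{MSS}/\code{tie}).
#' @export
checkpointByMsi <- function(se, msiStatus,
                            checkpointGenes = cytConfig()@checkpointGenes) {
    if (!"tpm" %in% SummarizedExperiment::assayNames(se))
        stop("run computeTpm() first: no 'tpm' assay", call. = FALSE)
    ids <- intersect(names(msiStatus), colnames(se))
    msi <- ids[msiStatus[ids] == "MSI"]
    mss <- ids[msiStatus[ids] == "MSS"]
    if (!length(msi) || !length(mss))
        stop("both MSI and MSS groups must be non-empty", call. = FALSE)
    present <- intersect(checkpointGenes, rownames(se))
    ltpm <- log2(SummarizedExperiment::assay(se, "tpm"))
    rows <- lapply(present, function(g) {
        a <- ltpm[g, msi]; b <- ltpm[g, mss]
        ht <- suppressWarnings(wilcox.test(a, b,
                                           alternative = "two.sided"))
        data.frame(gene = g, U = unname(ht$statistic), p = ht$p.value,
                   direction = if (median(a) > median(b)) "MSI"
                               else if (median(b) > median(a)) "MSS"
                               else "tie",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out
}
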