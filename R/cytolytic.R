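#' Length-normalize raw counts to TPM
#'
#' Divides each gene's raw counts by its maximum transcript length to form
#' a coverage estimate, scales every sample column to sum to 1e6
#' (transcripts per million), then adds a small offset to every entry so
#' that zero counts do not break logarithms and geometric means
#' downstream. Columns therefore sum to 1e6 before the offset and to
#' 1e6 + offset * nGenes after it.
#'
#' @param se SummarizedExperiment with a \code{counts} assay and rowData
#'   \code{max_transcript_length}.
#' @param offset numeric added to every TPM entry (default 0.01).
#' @return the same SummarizedExperiment with an added \code{tpm} assay;
#'   the offset is recorded in \code{metadata(se)$tpm_offset}.
#' @examples
#' cohort <- simulateCohort(simConfig(nTumor = 12, nGenes = 100, seed = 1))
#' se <- computeTpm(exprData(cohort))
#' summary(colSums(SummarizedExperiment::assay(se, "tpm")))
#' @export
computeTpm <- function(se, offset = 0.01) {
    stopifnot(offset >= 0)
    counts <- SummarizedExperiment::assay(se, "counts")
    lens <- SummarizedExperiment::rowData(se)$max_transcript_length
    if (is.null(lens) || any(lens < 1))
        stop("every gene needs a max_transcript_length >= 1", call. = FALSE)
    cov <- counts / lens
    tot <- colSums(cov)
    if (any(tot == 0))
        stop("all-zero counts for sample(s): ",
             paste(colnames(counts)[tot == 0], collapse = ", "),
             call. = FALSE)
    tpm <- sweep(cov, 2, tot, "/") * 1e6 + offset
    SummarizedExperiment::assay(se, "tpm") <- tpm
    S4Vectors::metadata(se)$tpm_offset <- offset
    se
}

#' Per-sample cytolytic index
#'
#' The cytolytic activity of a sample is the geometric mean of the TPM of
#' the configured cytolytic genes (GZMA and PRF1 by default), a
#' transcriptional proxy for cytotoxic T / NK cell activity. The index
#' reported alongside is \code{log2(cyt_raw + 1)}.
#'
#' @param se SummarizedExperiment with a \code{tpm} assay (offset already
#'   applied so entries are strictly positive; see
#'   \code{\link{computeTpm}}).
#' @param cytGenes genes entering the geometric mean.
#' @return data.frame with columns \code{sample_id}, \code{cyt_raw},
#'   \code{cyt_index}, plus \code{tissue}/\code{dataset} when present in
#'   the colData.
#' @export
computeCyt <- function(se, cytGenes = c("GZMA", "PRF1")) {
    if (!"tpm" %in% SummarizedExperiment::assayNames(se))
        stop("run computeTpm() first: no 'tpm' assay", call. = FALSE)
    miss <- setdiff(cytGenes, rownames(se))
    if (length(miss))
        stop("cytolytic gene(s) absent from the matrix: ",
             paste(miss, collapse = ", "), call. = FALSE)
    tpm <- SummarizedExperiment::assay(se, "tpm")[cytGenes, , drop = FALSE]
    if (any(tpm <= 0))
        stop("TPM entries must be strictly positive (apply the offset)",
             call. = FALSE)
    raw <- exp(colMeans(log(tpm)))
    out <- data.frame(sample_id = colnames(se), cyt_raw = as.numeric(raw),
                      cyt_index = log2(as.numeric(raw) + 1),
                      stringsAsFactors = FALSE)
    cd <- SummarizedExperiment::colData(se)
    if ("tissue" %in% colnames(cd)) out$tissue <- cd$tissue
    if ("dataset" %in% colnames(cd)) out$dataset <- cd$dataset
    out
}

#' Stratify samples into cytolytic quartile groups
#'
#' Ranks tumor samples by raw cytolytic activity (ties broken
#' lexicographically by sample ID, so the stratification is deterministic
#' and invariant to input order) and labels the top
#' \code{floor(fraction * n)} samples \code{CYT-high}, the bottom
#' \code{floor(fraction * n)} \code{CYT-low}, and the remainder
#' \code{middle}. With \code{by} given (e.g. the dataset label), the
#' stratification is performed within each level separately.
#'
#' @param cyt data.frame from \code{\link{computeCyt}} (or any table with
#'   \code{sample_id} and \code{cyt_raw}); tumor samples only.
#' @param fraction fraction assigned to each extreme stratum
#'   (default 0.25).
#' @param by optional factor (one value per row of \code{cyt}) within
#'   whose levels stratification is carried out.
#' @return \code{cyt} with an added \code{stratum} column
#'   (\code{CYT-high}/\code{middle}/\code{CYT-low}), in the input row
#'   order.
#' @examples
#' cyt <- data.frame(sample_id = sprintf("S%02d", 1:8), cyt_raw = 1:8)
#' cyt$cyt_index <- log2(cyt$cyt_raw + 1)
#' stratifyCyt(cyt, 0.25)
#' @export
stratifyCyt <- function(cyt, fraction = 0.25, by = NULL) {
    stopifnot(is.data.frame(cyt),
              all(c("sample_id", "cyt_raw") %in% colnames(cyt)))
    if (fraction <= 0 || fraction > 0.5)
        stop("'fraction' must lie in (0, 0.5]", call. = FALSE)
    if (anyDuplicated(cyt$sample_id))
        stop("duplicate sample_id in cytolytic table", call. = FALSE)
    one <- function(d) {
        n <- nrow(d)
        if (n < ceiling(2 / fraction))
            stop(sprintf(
                "need at least %d samples to form %g-fraction strata, got %d",
                ceiling(2 / fraction), fraction, n), call. = FALSE)
        k <- floor(fraction * n)
        ord <- order(-d$cyt_raw, d$sample_id)  # desc value, stable ID ties
        stratum <- rep("middle", n)
        stratum[ord[seq_len(k)]] <- "CYT-high"
        stratum[ord[seq.int(n - k + 1L, n)]] <- "CYT-low"
        d$stratum <- stratum
        d
    }
    if (is.null(by)) {
        out <- one(cyt)
    } else {
        stopifnot(length(by) == nrow(cyt))
        parts <- split(seq_len(nrow(cyt)), by)
        stratum <- rep(NA_character_, nrow(cyt))
        for (idx in parts) stratum[idx] <- one(cyt[idx, , drop = FALSE])$stratum
        out <- cyt
        out$stratum <- stratum
    }
    out$stratum <- factor(out$stratum,
                          levels = c("CYT-high", "middle", "CYT-low"))
    out
}

#' Nonparametric group comparison with FDR adjustment
#'
#' Compares a per-sample statistic between groups: two groups are tested
#' with a two-sided Mann-Whitney U, more with Kruskal-Wallis. A named
#' list of statistics submitted together forms one batch over which
#' Benjamini-Hochberg q-values are computed.
#'
#' @param values numeric vector, or named list of numeric vectors, one
#'   value per sample.
#' @param groups group labels, one per sample; every group needs at least
#'   two members.
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{test} (\code{mann-whitney} or \code{kruskal-wallis}),
#'   \code{statistic}, \code{p}, \code{q}.
#' @examples
#' compareCytGroups(list(burden = c(1, 2, 3, 10, 11, 12)),
#'                  rep(c("low", "high"), each = 3))
#' @export
compareCytGroups <- function(values, groups) {
    if (!is.list(values)) values <- list(statistic = values)
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) < 2)
        stop("need at least two groups", call. = FALSE)
    if (any(table(groups) < 2))
        stop("every group needs at least two samples", call. = FALSE)
    rows <- lapply(names(values), function(nm) {
        v <- values[[nm]]
        stopifnot(length(v) == length(groups))
        if (nlevels(groups) == 2L) {
            ht <- suppressWarnings(
                wilcox.test(v[groups == levels(groups)[1]],
                            v[groups == levels(groups)[2]],
                            alternative = "two.sided"))
            data.frame(comparison = nm, test = "mann-whitney",
                       statistic = unname(ht$statistic), p = ht$p.value,
                       stringsAsFactors = FALSE)
        } else {
            ht <- kruskal.test(v, groups)
            data.frame(comparison = nm, test = "kruskal-wallis",
                       statistic = unname(ht$statistic), p = ht$p.value,
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out
}
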