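#' Call microsatellite instability from MAF mutations
#'
#' A tumor is labelled MSI when it carries at least one missense mutation
#' in any of the configured mismatch-repair genes (MLH1, MLH3, MSH2,
#' MSH3, MSH4, MSH5, MSH6, PMS1, PMS2 by default), and MSS otherwise.
#' The rule is deliberately missense-only; other classifications in MMR
#' genes do not trigger an MSI call. Samples absent from the MAF are
#' labelled MSS with a warning.
#'
#' @param maf data.frame of mutation records (see \code{\link{readMaf}}).
#' @param mmrGenes mismatch-repair gene panel.
#' @param samples optional full sample roster; defaults to the samples
#'   seen in the MAF.
#' @return named character vector (\code{MSI}/\code{MSS}), one entry per
#'   sample.
#' @export
classifyMsiFromMaf <- function(maf,
                               mmrGenes = c("MLH1", "MLH3", "MSH2", "MSH3",
                                            "MSH4", "MSH5", "MSH6", "PMS1",
                                            "PMS2"),
                               samples = NULL) {
    stopifnot(length(mmrGenes) >= 1)
    seen <- unique(maf$Tumor_Sample_Barcode)
    if (is.null(samples)) samples <- sort(seen)
    absent <- setdiff(samples, seen)
    if (length(absent))
        warning(length(absent),
                " sample(s) absent from the MAF labelled MSS",
                call. = FALSE)
    hit <- maf$Variant_Classification == "Missense_Mutation" &
        maf$Hugo_Symbol %in% mmrGenes
    msi <- unique(maf$Tumor_Sample_Barcode[hit])
    setNames(ifelse(samples %in% msi, "MSI", "MSS"), samples)
}

#' Per-sample nonsynonymous mutation burden
#'
#' Counts records whose classification is non-silent coding (missense,
#' nonsense, nonstop, splice site, translation start site, frameshift
#' insertion/deletion, in-frame insertion/deletion). Silent, UTR, intron
#' and RNA records — and any classification outside the controlled
#' vocabulary — are excluded.
#'
#' @param maf data.frame of mutation records.
#' @param samples optional full sample roster (absent samples get 0).
#' @param nonsynClasses classifications counted as nonsynonymous.
#' @return named integer vector of burdens.
#' @export
nonsynBurden <- function(maf, samples = NULL,
                         nonsynClasses = c("Missense_Mutation",
                                           "Nonsense_Mutation",
                                           "Nonstop_Mutation", "Splice_Site",
                                           "Translation_Start_Site",
                                           "Frame_Shift_Ins",
                                           "Frame_Shift_Del",
                                           "In_Frame_Ins", "In_Frame_Del")) {
    if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
    keep <- maf$Variant_Classification %in% nonsynClasses
    tab <- table(factor(maf$Tumor_Sample_Barcode[keep], levels = samples))
    setNames(as.integer(tab), samples)
}

.complementBase <- c(A = "T", C = "G", G = "C", T = "A")
.spectrumClasses <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Per-sample single-nucleotide substitution spectrum
#'
#' Collapses SNVs into the six pyrimidine-reference substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference substitutions are
#' complemented first (so G>A counts as C>T). Non-SNV records (multi-base
#' or non-ACGT alleles, or ref equal to alt) are skipped. Fractions are
#' over a sample's SNVs and sum to 1 whenever at least one SNV exists.
#'
#' @param maf data.frame with \code{Reference_Allele} and
#'   \code{Tumor_Seq_Allele2}.
#' @param samples optional full sample roster.
#' @return matrix of fractions, samples in rows, the six classes in
#'   columns; rows without SNVs are all-NA.
#' @export
mutationSpectrum <- function(maf, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
    ref <- toupper(as.character(maf$Reference_Allele))
    alt <- toupper(as.character(maf$Tumor_Seq_Allele2))
    snv <- !is.na(ref) & !is.na(alt) &
        ref %in% names(.complementBase) & alt %in% names(.complementBase) &
        ref != alt
    ref <- ref[snv]; alt <- alt[snv]
    flip <- ref %in% c("A", "G")
    ref[flip] <- .complementBase[ref[flip]]
    alt[flip] <- .complementBase[alt[flip]]
    cls <- factor(paste0(ref, ">", alt), levels = .spectrumClasses)
    sid <- factor(maf$Tumor_Sample_Barcode[snv], levels = samples)
    counts <- table(sid, cls)
    frac <- counts / rowSums(counts)          # NaN rows for 0-SNV samples
    out <- matrix(as.numeric(frac), nrow = length(samples),
                  dimnames = list(samples, .spectrumClasses))
    out[is.nan(out)] <- NA_real_
    out
}

#' Variant allele frequency of mutation records
#'
#' VAF = alt reads / (alt + ref reads); \code{NA} where either count is
#' missing or total depth is zero.
#'
#' @param tAlt,tRef numeric vectors of alt and ref read counts (or a MAF
#'   data.frame as first argument, from which \code{t_alt_count} /
#'   \code{t_ref_count} are taken).
#' @return numeric vector of VAFs in [0, 1] (with NAs).
#' @export
computeVaf <- function(tAlt, tRef = NULL) {
    if (is.data.frame(tAlt)) {
        tRef <- tAlt$t_ref_count
        tAlt <- tAlt$t_alt_count
    }
    depth <- tAlt + tRef
    ifelse(is.na(depth) | depth == 0, NA_real_, tAlt / depth)
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' MATH quantifies intratumor heterogeneity as the ratio of the width to
#' the center of the variant-allele-fraction distribution:
#' \code{100 * 1.4826 * median(|v - median(v)|) / median(v)}, i.e. 100
#' times the scaled median absolute deviation over the median. Requires
#' at least \code{minVafs} non-missing VAFs, otherwise (or when the
#' median VAF is zero) the score is unavailable (\code{NA}) with a
#' warning. The score is invariant under multiplicative VAF scaling.
#'
#' @param vafs numeric vector of VAFs.
#' @param minVafs minimum number of usable VAFs (default 5).
#' @return a single numeric MATH score, or \code{NA}.
#' @examples
#' mathScore(c(0.2, 0.25, 0.3, 0.35, 0.4))  # 24.71
#' @export
mathScore <- function(vafs, minVafs = 5L) {
    v <- vafs[!is.na(vafs)]
    if (length(v) < minVafs) {
        warning(sprintf("MATH unavailable: %d usable VAFs < %d",
                        length(v), minVafs), call. = FALSE)
        return(NA_real_)
    }
    med <- median(v)
    if (med == 0) {
        warning("MATH unavailable: median VAF is zero", call. = FALSE)
        return(NA_real_)
    }
    100 * mad(v, constant = 1.4826) / med
}

#' Per-sample mutation summary
#'
#' Convenience aggregation of the per-sample mutation statistics: MSI
#' status, nonsynonymous burden, substitution spectrum, and MATH score
#' over the sample's VAFs.
#'
#' @param maf data.frame of mutation records.
#' @param samples optional full sample roster.
#' @param mmrGenes mismatch-repair panel for MSI calling.
#' @return data.frame keyed by \code{sample_id} with \code{msi_status},
#'   \code{nonsyn_count}, \code{math_score} and the six spectrum fraction
#'   columns.
#' @export
mutationSummary <- function(maf, samples = NULL,
                            mmrGenes = c("MLH1", "MLH3", "MSH2", "MSH3",
                                         "MSH4", "MSH5", "MSH6", "PMS1",
                                         "PMS2")) {
    if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
    msi <- suppressWarnings(classifyMsiFromMaf(maf, mmrGenes, samples))
    burden <- nonsynBurden(maf, samples)
    spec <- mutationSpectrum(maf, samples)
    vaf <- computeVaf(maf)
    math <- vapply(samples, function(s) {
        suppressWarnings(mathScore(vaf[maf$Tumor_Sample_Barcode == s]))
    }, numeric(1))
    data.frame(sample_id = samples, msi_status = unname(msi[samples]),
               nonsyn_count = unname(burden[samples]),
               math_score = unname(math), spec, check.names = FALSE,
               stringsAsFactors = FALSE)
}

.presenceMatrix <- function(maf, genes, samples) {
    m <- matrix(FALSE, length(samples), length(genes),
                dimnames = list(samples, genes))
    keep <- maf$Hugo_Symbol %in% genes & maf$Tumor_Sample_Barcode %in% samples
    if (any(keep))
        m[cbind(maf$Tumor_Sample_Barcode[keep], maf$Hugo_Symbol[keep])] <- TRUE
    m
}

#' Pairwise Fisher test for co-occurring / exclusive mutations
#'
#' For every gene pair, builds the 2x2 table of samples mutated in
#' neither, one, or both genes and applies a two-sided Fisher exact test.
#' The association direction comes from the odds ratio: co-occurring when
#' the both/neither diagonal dominates, mutually exclusive otherwise.
#' Genes mutated in no or in all samples are skipped (their table is
#' degenerate). BH q-values are computed over all tested pairs.
#'
#' @param maf data.frame of mutation records.
#' @param genes genes to test pairwise.
#' @param samples optional full sample roster.
#' @return data.frame with \code{gene1}, \code{gene2}, \code{n_both},
#'   \code{direction} (\code{co-occurring}/\code{exclusive}/\code{none}),
#'   \code{p}, \code{q}; skipped pairs carry a \code{note}.
#' @export
pairwiseFisher <- function(maf, genes, samples = NULL) {
    stopifnot(length(genes) >= 2)
    if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
    pm <- .presenceMatrix(maf, genes, samples)
    frac <- colMeans(pm)
    usable <- names(frac)[frac > 0 & frac < 1]
    skipped <- setdiff(genes, usable)
    if (length(skipped))
        message("skipping gene(s) mutated in none or all samples: ",
                paste(skipped, collapse = ", "))
    pairs <- if (length(usable) >= 2) utils::combn(usable, 2) else
        matrix(character(), 2, 0)
    rows <- apply(pairs, 2, function(gp) {
        a <- pm[, gp[1]]; b <- pm[, gp[2]]
        tab <- matrix(c(sum(a & b), sum(a & !b),
                        sum(!a & b), sum(!a & !b)), 2, 2)
        ft <- fisher.test(tab, alternative = "two.sided")
        or <- unname(ft$estimate)
        data.frame(gene1 = gp[1], gene2 = gp[2], n_both = sum(a & b),
                   direction = if (or > 1) "co-occurring"
                               else if (or < 1) "exclusive" else "none",
                   p = ft$p.value, stringsAsFactors = FALSE)
    })
    if (!length(rows))
        return(data.frame(gene1 = character(), gene2 = character(),
                          n_both = integer(), direction = character(),
                          p = numeric(), q = numeric()))
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out
}

#' Gene mutation association with cytolytic strata
#'
#' Per gene, a two-sided Fisher exact test of mutated-vs-not against
#' CYT-high vs CYT-low membership (middle samples are excluded). The
#' enriched stratum is the one with the higher mutated fraction. BH
#' q-values are computed over the tested genes.
#'
#' @param maf data.frame of mutation records.
#' @param strata data.frame from \code{\link{stratifyCyt}}.
#' @param genes genes to test.
#' @return data.frame with \code{gene}, \code{n_high}, \code{n_low},
#'   \code{enriched_stratum}, \code{p}, \code{q}.
#' @export
geneStratumAssociation <- function(maf, strata, genes) {
    stopifnot(all(c("sample_id", "stratum") %in% colnames(strata)))
    hi <- strata$sample_id[strata$stratum == "CYT-high"]
    lo <- strata$sample_id[strata$stratum == "CYT-low"]
    pm <- .presenceMatrix(maf, genes, c(hi, lo))
    rows <- lapply(genes, function(g) {
        mutated <- pm[, g]
        tab <- matrix(c(sum(mutated[hi]), length(hi) - sum(mutated[hi]),
                        sum(mutated[lo]), length(lo) - sum(mutated[lo])),
                      2, 2)
        ft <- fisher.test(tab, alternative = "two.sided")
        fh <- mean(mutated[hi]); fl <- mean(mutated[lo])
        data.frame(gene = g, n_high = sum(mutated[hi]),
                   n_low = sum(mutated[lo]),
                   enriched_stratum = if (fh > fl) "CYT-high"
                                      else if (fl > fh) "CYT-low"
                                      else "none",
                   p = ft$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out
}
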