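.mafVocabulary <- c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
                    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins",
                    "In_Frame_Del", "Silent", "Translation_Start_Site",
                    "Nonstop_Mutation", "3'UTR", "5'UTR", "Intron", "RNA")

.ioStop <- function(path, ...) {
    stop(sprintf("%s: %s", path, sprintf(...)), call. = FALSE)
}

.requireCols <- function(tab, cols, path) {
    miss <- setdiff(cols, colnames(tab))
    if (length(miss))
        .ioStop(path, "missing mandatory column(s): %s",
                paste(miss, collapse = ", "))
}

#' Read an expression matrix with transcript lengths
#'
#' Reads a tab-delimited table whose first column (\code{gene}) holds gene
#' symbols, whose \code{max_transcript_length} column holds the per-gene
#' maximum transcript length in bp, and whose remaining columns are raw
#' counts, one per sample. An optional companion metadata table supplies
#' per-sample \code{tissue} (\code{tumor}/\code{normal}) and
#' \code{dataset} labels; without it every sample is treated as a tumor of
#' dataset \code{"other"}.
#'
#' @param path expression TSV path.
#' @param metaPath optional sample-metadata TSV with columns
#'   \code{sample_id}, \code{tissue}, and optionally \code{dataset}.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}, rowData \code{max_transcript_length}, and colData
#'   \code{tissue}/\code{dataset}; row and column order as on disk.
#' @seealso \code{\link{writeExpression}}
#' @export
readExpression <- function(path, metaPath = NULL) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    .requireCols(tab, c("gene", "max_transcript_length"), path)
    genes <- as.character(tab$gene)
    if (anyDuplicated(genes))
        .ioStop(path, "duplicate gene symbol(s): %s",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
    lens <- suppressWarnings(as.numeric(tab$max_transcript_length))
    if (anyNA(lens) || any(lens < 1))
        .ioStop(path, "gene length missing or < 1 at row(s) %s",
                paste(which(is.na(lens) | lens < 1), collapse = ", "))
    sampleCols <- setdiff(colnames(tab), c("gene", "max_transcript_length"))
    if (!length(sampleCols)) .ioStop(path, "no sample columns found")
    if (anyDuplicated(sampleCols))
        .ioStop(path, "duplicate sample ID(s): %s",
                paste(unique(sampleCols[duplicated(sampleCols)]),
                      collapse = ", "))
    counts <- as.matrix(tab[, sampleCols, drop = FALSE])
    suppressWarnings(storage.mode(counts) <- "numeric")
    bad <- which(rowSums(is.na(counts) | counts < 0) > 0)
    if (length(bad))
        .ioStop(path, "negative or non-numeric count at row(s) %s",
                paste(bad, collapse = ", "))
    rownames(counts) <- genes
    cd <- S4Vectors::DataFrame(tissue = rep("tumor", length(sampleCols)),
                               dataset = rep("other", length(sampleCols)),
                               row.names = sampleCols)
    if (!is.null(metaPath)) {
        meta <- read.delim(metaPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
        .requireCols(meta, c("sample_id", "tissue"), metaPath)
        miss <- setdiff(sampleCols, meta$sample_id)
        if (length(miss))
            .ioStop(metaPath, "sample(s) without tissue label: %s",
                    paste(miss, collapse = ", "))
        idx <- match(sampleCols, meta$sample_id)
        if (!all(meta$tissue[idx] %in% c("tumor", "normal")))
            .ioStop(metaPath, "field 'tissue' must be 'tumor' or 'normal'")
        cd$tissue <- meta$tissue[idx]
        if ("dataset" %in% colnames(meta)) cd$dataset <- meta$dataset[idx]
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(max_transcript_length = lens,
                                       row.names = genes),
        colData = cd)
}

#' Write an expression matrix with transcript lengths
#'
#' Inverse of \code{\link{readExpression}}: writes the counts assay with a
#' leading \code{gene} and \code{max_transcript_length} column, and the
#' sample metadata next to it when \code{metaPath} is given.
#'
#' @param se SummarizedExperiment as returned by
#'   \code{\link{readExpression}} or \code{\link{simulateCohort}}.
#' @param path output TSV path.
#' @param metaPath optional path for the sample metadata table.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(se, path, metaPath = NULL) {
    counts <- SummarizedExperiment::assay(se, "counts")
    tab <- data.frame(
        gene = rownames(se),
        max_transcript_length =
            SummarizedExperiment::rowData(se)$max_transcript_length,
        counts, check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metaPath)) {
        cd <- SummarizedExperiment::colData(se)
        meta <- data.frame(sample_id = rownames(cd), tissue = cd$tissue,
                           dataset = cd$dataset, stringsAsFactors = FALSE)
        write.table(meta, metaPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Read a MAF-style somatic mutation table
#'
#' Tab-delimited with TCGA column names; lines beginning \code{#} are
#' comments. Mandatory columns: \code{Hugo_Symbol},
#' \code{Variant_Classification}, \code{Tumor_Sample_Barcode}. Optional:
#' \code{Chromosome}, \code{Start_Position}, \code{Reference_Allele},
#' \code{Tumor_Seq_Allele2}, \code{t_ref_count}, \code{t_alt_count}.
#' Coordinates are 1-based inclusive. Variant classifications outside the
#' controlled vocabulary are retained verbatim but flagged (column
#' \code{known_classification}) and excluded from nonsynonymous counts.
#' Records without read counts are retained with VAF unavailable.
#'
#' @param path MAF path.
#' @return data.frame with one row per data line.
#' @export
readMaf <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "")
    .requireCols(tab, c("Hugo_Symbol", "Variant_Classification",
                        "Tumor_Sample_Barcode"), path)
    for (cc in c("t_ref_count", "t_alt_count"))
        if (!cc %in% colnames(tab)) tab[[cc]] <- NA_integer_
        else {
            v <- suppressWarnings(as.numeric(tab[[cc]]))
            if (any(v < 0, na.rm = TRUE))
                .ioStop(path, "negative read count in field '%s' at row(s) %s",
                        cc, paste(which(v < 0), collapse = ", "))
            tab[[cc]] <- v
        }
    tab$known_classification <-
        tab$Variant_Classification %in% .mafVocabulary
    if (!all(tab$known_classification))
        warning(sprintf(
            "%s: %d record(s) with classification outside the controlled vocabulary (retained, flagged)",
            path, sum(!tab$known_classification)), call. = FALSE)
    tab
}

#' @rdname readMaf
#' @param maf data.frame of mutation records.
#' @export
writeMaf <- function(maf, path) {
    write.table(maf[setdiff(colnames(maf), "known_classification")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read copy-number segments (SEG format)
#'
#' Tab-delimited with columns \code{Sample}, \code{Chromosome},
#' \code{Start}, \code{End}, \code{Num_Probes} (optional), and
#' \code{Segment_Mean} (log2-ratio scale). Coordinates are 1-based
#' inclusive.
#'
#' @param path SEG path.
#' @return data.frame of segments.
#' @export
readSegments <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
    .requireCols(tab, c("Sample", "Chromosome", "Start", "End",
                        "Segment_Mean"), path)
    if (!"Num_Probes" %in% colnames(tab)) tab$Num_Probes <- NA_integer_
    sm <- suppressWarnings(as.numeric(tab$Segment_Mean))
    if (anyNA(sm) | any(!is.finite(sm)))
        .ioStop(path, "non-finite Segment_Mean at row(s) %s",
                paste(which(is.na(sm) | !is.finite(sm)), collapse = ", "))
    tab$Segment_Mean <- sm
    bad <- which(tab$Start > tab$End)
    if (length(bad))
        .ioStop(path, "Start > End at row(s) %s",
                paste(bad, collapse = ", "))
    tab
}

#' @rdname readSegments
#' @param segments data.frame of segments.
#' @export
writeSegments <- function(segments, path) {
    write.table(segments, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a clinical follow-up table
#'
#' Tab-delimited with columns \code{sample_id}, \code{os_time}
#' (non-negative), and \code{os_event} (1 = death, 0 = censored); any
#' further covariate columns are retained.
#'
#' @param path TSV path.
#' @return data.frame of clinical records.
#' @export
readClinical <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    .requireCols(tab, c("sample_id", "os_time", "os_event"), path)
    if (any(!tab$os_event %in% c(0, 1)))
        .ioStop(path, "field 'os_event' must be 0 or 1 at row(s) %s",
                paste(which(!tab$os_event %in% c(0, 1)), collapse = ", "))
    if (any(is.na(tab$os_time) | tab$os_time < 0))
        .ioStop(path, "field 'os_time' must be >= 0 at row(s) %s",
                paste(which(is.na(tab$os_time) | tab$os_time < 0),
                      collapse = ", "))
    tab
}

#' @rdname readClinical
#' @param clinical data.frame of clinical records.
#' @export
writeClinical <- function(clinical, path) {
    write.table(clinical, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a peptide-affinity table
#'
#' Tab-delimited with columns \code{sample_id}, \code{peptide_id},
#' \code{mhc_class} (\code{I} or \code{II}), \code{mut_ic50} and
#' \code{wt_ic50} (predicted IC50 in nM, strictly positive), and
#' \code{variant_type} (\code{missense}, \code{frameshift}, \code{fusion}
#' or \code{indel}).
#'
#' @param path TSV path.
#' @return data.frame of affinity records.
#' @export
readAffinities <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    .requireCols(tab, c("sample_id", "peptide_id", "mhc_class",
                        "mut_ic50", "wt_ic50", "variant_type"), path)
    if (any(!tab$mhc_class %in% c("I", "II")))
        .ioStop(path, "field 'mhc_class' must be 'I' or 'II' at row(s) %s",
                paste(which(!tab$mhc_class %in% c("I", "II")),
                      collapse = ", "))
    for (cc in c("mut_ic50", "wt_ic50")) {
        v <- suppressWarnings(as.numeric(tab[[cc]]))
        if (any(is.na(v) | v <= 0))
            .ioStop(path, "field '%s' must be > 0 at row(s) %s", cc,
                    paste(which(is.na(v) | v <= 0), collapse = ", "))
        tab[[cc]] <- v
    }
    vt <- c("missense", "frameshift", "fusion", "indel")
    if (any(!tab$variant_type %in% vt))
        .ioStop(path, "field 'variant_type' must be one of %s at row(s) %s",
                paste(vt, collapse = "/"),
                paste(which(!tab$variant_type %in% vt), collapse = ", "))
    tab
}

#' @rdname readAffinities
#' @param affinities data.frame of affinity records.
#' @export
writeAffinities <- function(affinities, path) {
    write.table(affinities, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write a whole cohort to a directory
#'
#' Writes every present component of a \linkS4class{CytCohort} under its
#' standard file name (\code{expression.tsv}, \code{samples.tsv},
#' \code{mutations.maf}, \code{segments.seg}, \code{clinical.tsv},
#' \code{affinities.tsv}, \code{ground_truth.tsv}).
#'
#' @param cohort a \linkS4class{CytCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(cohort@expr))
        writeExpression(cohort@expr, file.path(dir, "expression.tsv"),
                        file.path(dir, "samples.tsv"))
    if (!is.null(cohort@maf))
        writeMaf(cohort@maf, file.path(dir, "mutations.maf"))
    if (!is.null(cohort@segments))
        writeSegments(cohort@segments, file.path(dir, "segments.seg"))
    if (!is.null(cohort@clinical))
        writeClinical(cohort@clinical, file.path(dir, "clinical.tsv"))
    if (!is.null(cohort@affinities))
        writeAffinities(cohort@affinities, file.path(dir, "affinities.tsv"))
    if (!is.null(cohort@groundTruth))
        write.table(cohort@groundTruth, file.path(dir, "ground_truth.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
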