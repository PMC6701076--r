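#' @import methods
#' @importFrom stats median mad p.adjust wilcox.test kruskal.test fisher.test
#'   cor.test pchisq rnorm rpois rbinom rnbinom rbeta runif rexp rgamma
#'   setNames complete.cases quantile
#' @importFrom utils read.delim write.table head modifyList
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Pipeline configuration
#'
#' Holds every analysis threshold used across the pipeline: the cytolytic
#' gene pair, the TPM offset, the quartile fraction used for CYT-high/low
#' stratification, the mismatch-repair gene panel for MSI calling, the
#' neoepitope IC50 and DAI cutoffs, copy-number segment-mean cutoffs, the
#' CPM expression filter, the differential-expression FDR, and the
#' histology dichotomization medians. Defaults are the values used
#' throughout the analysis; see \code{\link{cytConfig}}.
#'
#' @slot cytGenes character, genes whose geometric-mean TPM defines the
#'   cytolytic index (default \code{c("GZMA", "PRF1")}).
#' @slot tpmOffset numeric, offset added to every TPM entry so zero counts
#'   do not break logs and geometric means (default 0.01).
#' @slot quartileFraction numeric in (0, 0.5], fraction of samples assigned
#'   to each of CYT-high and CYT-low (default 0.25).
#' @slot mmrGenes character, mismatch-repair genes whose missense mutations
#'   define MSI status.
#' @slot checkpointGenes character, immune-checkpoint panel.
#' @slot nonsynClasses character, MAF variant classifications counted as
#'   nonsynonymous.
#' @slot cdnIc50Cutoff numeric nM, mutant-peptide binding cutoff for
#'   classically defined neoepitopes (default 50, strict \code{<}).
#' @slot daiCutoffMhc1,daiCutoffMhc2 numeric, differential agretopicity
#'   cutoffs for MHC-I and MHC-II (defaults 10 and 4, strict \code{>}).
#' @slot scnaAmpCutoff,scnaDelCutoff numeric, segment-mean cutoffs for
#'   amplification / deletion events (defaults 0.6 and -0.4, inclusive).
#' @slot cpmFilter,cpmSampleFraction numeric, keep a gene if its CPM is at
#'   least \code{cpmFilter} in at least \code{cpmSampleFraction} of samples
#'   (defaults 1 CPM, 0.5).
#' @slot deFdr numeric, BH FDR below which a gene is called differentially
#'   expressed (default 0.1).
#' @slot survivalAlpha numeric, significance threshold for log-rank tests
#'   (default 0.05).
#' @slot tilMedian,tanMedian numeric percent, cohort medians used to split
#'   TIL and TAN load into high/low (defaults 5 and 2).
#' @slot mmrPositivePct numeric percent, IHC positivity threshold per MMR
#'   protein (default 10).
#' @slot stainLowCut numeric percent, boundary between faint (1+) and
#'   moderate/strong (2+) staining (default 10).
#' @slot randomSeed integer, seed from which all pipeline randomness flows.
#' @aliases CytConfig-class
#' @exportClass CytConfig
setClass("CytConfig", representation(
    cytGenes          = "character",
    tpmOffset         = "numeric",
    quartileFraction  = "numeric",
    mmrGenes          = "character",
    checkpointGenes   = "character",
    nonsynClasses     = "character",
    cdnIc50Cutoff     = "numeric",
    daiCutoffMhc1     = "numeric",
    daiCutoffMhc2     = "numeric",
    scnaAmpCutoff     = "numeric",
    scnaDelCutoff     = "numeric",
    cpmFilter         = "numeric",
    cpmSampleFraction = "numeric",
    deFdr             = "numeric",
    survivalAlpha     = "numeric",
    tilMedian         = "numeric",
    tanMedian         = "numeric",
    mmrPositivePct    = "numeric",
    stainLowCut       = "numeric",
    randomSeed        = "integer"
))

setValidity("CytConfig", function(object) {
    msg <- character()
    chk1 <- function(x, nm) {
        if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
            msg <<- c(msg, sprintf("'%s' must be a single finite number", nm))
    }
    for (s in c("tpmOffset", "quartileFraction", "cdnIc50Cutoff",
                "daiCutoffMhc1", "daiCutoffMhc2", "scnaAmpCutoff",
                "scnaDelCutoff", "cpmFilter", "cpmSampleFraction", "deFdr",
                "survivalAlpha", "tilMedian", "tanMedian", "mmrPositivePct",
                "stainLowCut"))
        chk1(s, s)
    if (length(msg)) return(msg)
    if (object@quartileFraction <= 0 || object@quartileFraction > 0.5)
        msg <- c(msg, "'quartileFraction' must lie in (0, 0.5]")
    if (object@cpmSampleFraction <= 0 || object@cpmSampleFraction > 1)
        msg <- c(msg, "'cpmSampleFraction' must lie in (0, 1]")
    if (object@tpmOffset < 0)
        msg <- c(msg, "'tpmOffset' must be non-negative")
    if (object@cdnIc50Cutoff <= 0)
        msg <- c(msg, "'cdnIc50Cutoff' must be positive")
    if (object@daiCutoffMhc1 <= 0 || object@daiCutoffMhc2 <= 0)
        msg <- c(msg, "DAI cutoffs must be positive")
    if (!(object@scnaDelCutoff < 0 && 0 < object@scnaAmpCutoff))
        msg <- c(msg, "require scnaDelCutoff < 0 < scnaAmpCutoff")
    if (object@deFdr <= 0 || object@deFdr >= 1)
        msg <- c(msg, "'deFdr' must lie in (0, 1)")
    if (object@survivalAlpha <= 0 || object@survivalAlpha >= 1)
        msg <- c(msg, "'survivalAlpha' must lie in (0, 1)")
    if (object@mmrPositivePct < 0 || object@mmrPositivePct > 100)
        msg <- c(msg, "'mmrPositivePct' must lie in [0, 100]")
    if (object@stainLowCut <= 0 || object@stainLowCut > 100)
        msg <- c(msg, "'stainLowCut' must lie in (0, 100]")
    if (length(object@cytGenes) < 1L || anyDuplicated(object@cytGenes))
        msg <- c(msg, "'cytGenes' must be a non-empty set of distinct genes")
    if (length(object@mmrGenes) < 1L)
        msg <- c(msg, "'mmrGenes' must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort simulation parameters
#'
#' Parameters of the seeded generator that emulates a TCGA-like colorectal
#' cohort: negative-binomial expression with planted checkpoint
#' up-regulation in MSI samples, Poisson mutation burdens higher in MSI
#' tumors with Beta-distributed variant allele fractions, copy-number
#' segments with more extreme events in cytolytic-low tumors, log-normal
#' peptide affinities, and exponential survival with a hazard planted on
#' the low-cytolytic-activity half of the cohort. See
#' \code{\link{simConfig}} for defaults and \code{\link{simulateCohort}}.
#'
#' @slot nTumor,nNormal,nGenes integer sample and gene counts.
#' @slot msiFraction numeric in (0,1), fraction of MSI tumors.
#' @slot burdenMeanMsi,burdenMeanMss numeric Poisson means of nonsynonymous
#'   burden in MSI and MSS tumors.
#' @slot vafBetaShape1,vafBetaShape2 numeric Beta parameters of the variant
#'   allele fraction distribution.
#' @slot seqDepth integer sequencing depth used to thin VAFs into read
#'   counts (minimum 10).
#' @slot silentFraction numeric, silent records added per nonsynonymous
#'   record, as a fraction.
#' @slot checkpointGenes character, genes carrying the planted MSI shift.
#' @slot checkpointLog2fcMsi numeric, planted log2 fold-change of
#'   checkpoint genes in MSI samples.
#' @slot checkpointCytCoupling numeric, log2 shift of checkpoint expression
#'   per standard deviation of latent cytolytic activity.
#' @slot cytEffectOnBurden numeric, multiplicative burden factor applied to
#'   the top-quartile cytolytic tier.
#' @slot scnaRateCytlow,scnaRateCythigh numeric Poisson means of
#'   beyond-cutoff copy-number events in CYT-low-tier vs other tumors.
#' @slot neoRatePerMissense numeric, expected candidate peptides per
#'   missense mutation.
#' @slot hazardRatioCytlow numeric, hazard ratio applied to the
#'   below-median latent-activity hazard group.
#' @slot baselineHazard numeric, exponential event rate per month for the
#'   reference group.
#' @slot censorMax numeric, administrative censoring drawn uniformly on
#'   (0, censorMax] months.
#' @slot normalCytMultiplier numeric, cytolytic gene expression multiplier
#'   in normal-tissue samples.
#' @slot seed integer seed; identical configurations give identical
#'   cohorts.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nTumor                = "integer",
    nNormal               = "integer",
    nGenes                = "integer",
    msiFraction           = "numeric",
    burdenMeanMsi         = "numeric",
    burdenMeanMss         = "numeric",
    vafBetaShape1         = "numeric",
    vafBetaShape2         = "numeric",
    seqDepth              = "integer",
    silentFraction        = "numeric",
    checkpointGenes       = "character",
    checkpointLog2fcMsi   = "numeric",
    checkpointCytCoupling = "numeric",
    cytEffectOnBurden     = "numeric",
    scnaRateCytlow        = "numeric",
    scnaRateCythigh       = "numeric",
    neoRatePerMissense    = "numeric",
    hazardRatioCytlow     = "numeric",
    baselineHazard        = "numeric",
    censorMax             = "numeric",
    normalCytMultiplier   = "numeric",
    seed                  = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nTumor < 8L)
        msg <- c(msg, "'nTumor' must be >= 8 (quartiles degenerate below)")
    if (object@nNormal < 0L) msg <- c(msg, "'nNormal' must be >= 0")
    if (object@nGenes < length(object@checkpointGenes) + 20L)
        msg <- c(msg, "'nGenes' too small for the reserved gene panels")
    if (object@msiFraction <= 0 || object@msiFraction >= 1)
        msg <- c(msg, "'msiFraction' must lie in (0, 1)")
    for (s in c("burdenMeanMsi", "burdenMeanMss", "vafBetaShape1",
                "vafBetaShape2", "neoRatePerMissense", "hazardRatioCytlow",
                "baselineHazard", "censorMax", "normalCytMultiplier",
                "scnaRateCytlow", "scnaRateCythigh"))
        if (slot(object, s) <= 0)
            msg <- c(msg, sprintf("'%s' must be positive", s))
    if (object@seqDepth < 10L)
        msg <- c(msg, "'seqDepth' must be >= 10")
    if (object@silentFraction < 0)
        msg <- c(msg, "'silentFraction' must be >= 0")
    if (object@cytEffectOnBurden <= 0)
        msg <- c(msg, "'cytEffectOnBurden' must be positive")
    if (object@checkpointLog2fcMsi < 0)
        msg <- c(msg, "'checkpointLog2fcMsi' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Cohort container
#'
#' Bundles every input table of one cohort: an expression
#' \link[SummarizedExperiment]{SummarizedExperiment} (assay
#' \code{"counts"}, rowData \code{max_transcript_length}, colData
#' \code{tissue} and \code{dataset}), a MAF-style mutation table,
#' copy-number segments, clinical follow-up, peptide affinities, and (for
#' simulated cohorts) the generating ground truth. Any component other
#' than expression may be \code{NULL}; pipeline stages whose inputs are
#' absent are skipped.
#'
#' @slot expr SummarizedExperiment or NULL.
#' @slot maf data.frame of mutation records or NULL.
#' @slot segments data.frame of copy-number segments or NULL.
#' @slot clinical data.frame of survival records or NULL.
#' @slot affinities data.frame of peptide affinity records or NULL.
#' @slot groundTruth data.frame of per-tumor generating labels or NULL.
#' @aliases CytCohort-class
#' @exportClass CytCohort
setClass("CytCohort", representation(
    expr        = "ANY",
    maf         = "data.frameOrNULL",
    segments    = "data.frameOrNULL",
    clinical    = "data.frameOrNULL",
    affinities  = "data.frameOrNULL",
    groundTruth = "data.frameOrNULL"
))

setValidity("CytCohort", function(object) {
    msg <- character()
    if (!is.null(object@expr)) {
        if (!methods::is(object@expr, "SummarizedExperiment"))
            return("'expr' must be a SummarizedExperiment or NULL")
        if (!"counts" %in% SummarizedExperiment::assayNames(object@expr))
            msg <- c(msg, "'expr' must carry a 'counts' assay")
        if (!"max_transcript_length" %in%
                colnames(SummarizedExperiment::rowData(object@expr)))
            msg <- c(msg, "'expr' rowData must carry 'max_transcript_length'")
        if (!"tissue" %in%
                colnames(SummarizedExperiment::colData(object@expr)))
            msg <- c(msg, "'expr' colData must carry 'tissue'")
    }
    need <- list(maf = "Tumor_Sample_Barcode", segments = "Sample",
                 clinical = "sample_id", affinities = "sample_id")
    for (nm in names(need)) {
        tab <- slot(object, nm)
        if (!is.null(tab) && !need[[nm]] %in% colnames(tab))
            msg <- c(msg, sprintf("'%s' must carry column '%s'",
                                  nm, need[[nm]]))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CytCohort-class construct a cohort container.
#' @param expr,maf,segments,clinical,affinities,groundTruth components as
#'   described in the class slots.
#' @return a validated \code{CytCohort}.
#' @export
CytCohort <- function(expr = NULL, maf = NULL, segments = NULL,
                      clinical = NULL, affinities = NULL,
                      groundTruth = NULL) {
    methods::new("CytCohort", expr = expr, maf = maf, segments = segments,
                 clinical = clinical, affinities = affinities,
                 groundTruth = groundTruth)
}

setMethod("show", "CytCohort", function(object) {
    cat("CytCohort\n")
    if (!is.null(object@expr)) {
        d <- dim(object@expr)
        tis <- table(SummarizedExperiment::colData(object@expr)$tissue)
        cat(sprintf("  expression: %d genes x %d samples (%s)\n", d[1], d[2],
                    paste(sprintf("%s=%d", names(tis), tis), collapse = ", ")))
    } else cat("  expression: <absent>\n")
    for (nm in c("maf", "segments", "clinical", "affinities",
                 "groundTruth")) {
        tab <- slot(object, nm)
        cat(sprintf("  %s: %s\n", nm,
                    if (is.null(tab)) "<absent>"
                    else sprintf("%d records", nrow(tab))))
    }
})

setMethod("show", "CytConfig", function(object) {
    cat("CytConfig\n")
    cat("  cytolytic genes:", paste(object@cytGenes, collapse = ", "), "\n")
    cat(sprintf("  tpmOffset=%g quartileFraction=%g cdnIc50Cutoff=%g\n",
                object@tpmOffset, object@quartileFraction,
                object@cdnIc50Cutoff))
    cat(sprintf("  DAI cutoffs: MHC-I %g, MHC-II %g; SCNA cutoffs: [%g, %g]\n",
                object@daiCutoffMhc1, object@daiCutoffMhc2,
                object@scnaDelCutoff, object@scnaAmpCutoff))
    cat(sprintf("  CPM filter: >=%g in >=%g of samples; DE FDR %g\n",
                object@cpmFilter, object@cpmSampleFraction, object@deFdr))
    cat(sprintf("  MMR genes: %s\n", paste(object@mmrGenes, collapse = ", ")))
    cat(sprintf("  seed: %d\n", object@randomSeed))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  %d tumors, %d normals, %d genes, seed %d\n",
                object@nTumor, object@nNormal, object@nGenes, object@seed))
    cat(sprintf("  msiFraction=%g burden MSI/MSS=%g/%g cytEffectOnBurden=%g\n",
                object@msiFraction, object@burdenMeanMsi,
                object@burdenMeanMss, object@cytEffectOnBurden))
    cat(sprintf("  checkpoint log2FC (MSI)=%g coupling=%g\n",
                object@checkpointLog2fcMsi, object@checkpointCytCoupling))
    cat(sprintf("  SCNA rates low/other=%g/%g hazardRatioCytlow=%g\n",
                object@scnaRateCytlow, object@scnaRateCythigh,
                object@hazardRatioCytlow))
})

# accessors ------------------------------------------------------------

#' @rdname CytCohort-class
#' @param object,x a CytCohort.
#' @export
exprData <- function(x) x@expr

#' @rdname CytCohort-class
#' @export
mafTable <- function(x) x@maf

#' @rdname CytCohort-class
#' @export
segTable <- function(x) x@segments

#' @rdname CytCohort-class
#' @export
clinicalTable <- function(x) x@clinical

#' @rdname CytCohort-class
#' @export
affinityTable <- function(x) x@affinities

#' @rdname CytCohort-class
#' @export
groundTruth <- function(x) x@groundTruth

#' Tumor sample identifiers of a cohort
#'
#' @param x a CytCohort.
#' @return character vector of tumor sample IDs, from the expression
#'   component when present, otherwise the union of IDs seen in the other
#'   tables.
#' @export
tumorSamples <- function(x) {
    if (!is.null(x@expr)) {
        cd <- SummarizedExperiment::colData(x@expr)
        return(colnames(x@expr)[cd$tissue == "tumor"])
    }
    ids <- character()
    if (!is.null(x@maf)) ids <- c(ids, x@maf$Tumor_Sample_Barcode)
    if (!is.null(x@segments)) ids <- c(ids, x@segments$Sample)
    if (!is.null(x@clinical)) ids <- c(ids, x@clinical$sample_id)
    if (!is.null(x@affinities)) ids <- c(ids, x@affinities$sample_id)
    sort(unique(ids))
}
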