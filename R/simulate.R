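# Reserved gene panels of the synthetic cohort. Driver symbols give the
# association tests realistic targets; MMR genes are reserved for the
# planted MSI mutations.
.simCytGenes <- c("GZMA", "PRF1")
.simMmrGenes <- c("MLH1", "MLH3", "MSH2", "MSH3", "MSH4", "MSH5", "MSH6",
                  "PMS1", "PMS2")
.simDriverGenes <- c("APC", "TP53", "KRAS", "PIK3CA", "SMAD4", "BRAF",
                     "FBXW7", "TCF7L2", "ACVR1B", "SOX9", "ATM", "NRAS")

# log2 shift of GZMA/PRF1 per SD of latent cytolytic activity; large
# enough that the computed stratum recovers the planted tier for nearly
# all non-boundary samples.
.cytSignalLog2PerSd <- 2.5

#' Draw the per-tumor ground truth of a synthetic cohort
#'
#' Draws the latent structure every other component conditions on: MSI
#' labels (Bernoulli \code{msiFraction}), a standard-normal latent
#' cytolytic activity, the planted cytolytic tier (top/bottom quartile of
#' the latent activity), the survival hazard group (the below-median
#' latent-activity half), and the Poisson nonsynonymous burden (MSI vs
#' MSS mean, multiplied by \code{cytEffectOnBurden} in the high tier; MSI
#' burdens are at least 1 so the planted mismatch-repair mutation can be
#' carried).
#'
#' Draws from the current RNG stream; \code{\link{simulateCohort}} seeds
#' it from \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with \code{sample_id}, \code{msi_status},
#'   \code{cyt_latent}, \code{cyt_tier}, \code{hazard_group},
#'   \code{burden}.
#' @export
simulateTruth <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    n <- config@nTumor
    ids <- sprintf("TUM%04d", seq_len(n))
    msi <- runif(n) < config@msiFraction
    a <- rnorm(n)
    k <- floor(0.25 * n)
    ord <- order(-a, ids)
    tier <- rep("middle", n)
    tier[ord[seq_len(k)]] <- "high"
    tier[ord[seq.int(n - k + 1L, n)]] <- "low"
    lambda <- ifelse(msi, config@burdenMeanMsi, config@burdenMeanMss) *
        ifelse(tier == "high", config@cytEffectOnBurden, 1)
    burden <- rpois(n, lambda)
    burden[msi & burden == 0] <- 1L
    data.frame(sample_id = ids,
               msi_status = ifelse(msi, "MSI", "MSS"),
               cyt_latent = a, cyt_tier = tier,
               hazard_group = ifelse(a < median(a), "low", "reference"),
               burden = burden, stringsAsFactors = FALSE)
}

#' Simulate bulk expression counts
#'
#' Negative-binomial counts for \code{nGenes} genes (per-gene baseline
#' means log-normal, per-gene dispersion from a log-normal prior) over
#' the tumor samples of \code{truth} plus \code{nNormal} normal samples.
#' Planted structure: GZMA/PRF1 means scale with the latent cytolytic
#' activity; checkpoint genes scale with the same latent (coupling
#' \code{checkpointCytCoupling}) and are up-shifted by
#' \code{checkpointLog2fcMsi} log2 units in MSI tumors; normal samples
#' carry \code{normalCytMultiplier}-fold cytolytic gene expression and no
#' tumor effects. Library size factors vary at least two-fold across
#' samples. One gene (\code{NULLGENE1}) is all-zero by design and must be
#' removed by the CPM filter downstream.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth data.frame from \code{\link{simulateTruth}}.
#' @return SummarizedExperiment with assay \code{counts}, rowData
#'   \code{max_transcript_length}, colData \code{tissue}/\code{dataset}.
#' @export
simulateExpression <- function(config, truth) {
    nT <- nrow(truth); nN <- config@nNormal; nG <- config@nGenes
    special <- c(.simCytGenes, config@checkpointGenes, .simMmrGenes,
                 .simDriverGenes, "NULLGENE1")
    genes <- c(special,
               sprintf("GENE%04d", seq_len(nG - length(special))))
    mu0 <- exp(rnorm(nG, log(30), 1.5))
    names(mu0) <- genes
    mu0[.simCytGenes] <- 300
    mu0[config@checkpointGenes] <- 40
    mu0["NULLGENE1"] <- 0
    size <- 1 / exp(rnorm(nG, log(0.15), 0.5))
    names(size) <- genes
    size[.simCytGenes] <- 20   # marker genes measured tightly
    lens <- pmax(200, round(exp(rnorm(nG, log(2500), 0.5))))

    sf <- exp(rnorm(nT + nN, 0, 0.35))
    if (max(sf) / min(sf) < 2) {           # guarantee >= 2-fold spread
        lg <- log(sf)
        lg <- (lg - mean(lg)) * (log(2) / diff(range(lg)))
        sf <- exp(lg + log(2) / 2)
    }

    ids <- c(truth$sample_id, if (nN) sprintf("NOR%04d", seq_len(nN)))
    mu <- matrix(mu0, nG, nT + nN, dimnames = list(genes, ids))
    a <- truth$cyt_latent
    msi <- truth$msi_status == "MSI"
    mu[.simCytGenes, seq_len(nT)] <-
        sweep(mu[.simCytGenes, seq_len(nT), drop = FALSE], 2,
              2^(.cytSignalLog2PerSd * a), "*")
    cpShift <- 2^(config@checkpointCytCoupling * a +
                  config@checkpointLog2fcMsi * msi)
    mu[config@checkpointGenes, seq_len(nT)] <-
        sweep(mu[config@checkpointGenes, seq_len(nT), drop = FALSE], 2,
              cpShift, "*")
    if (nN)
        mu[.simCytGenes, nT + seq_len(nN)] <-
            mu[.simCytGenes, nT + seq_len(nN)] * config@normalCytMultiplier
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     nG, nT + nN, dimnames = dimnames(mu))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(max_transcript_length = lens,
                                       row.names = genes),
        colData = S4Vectors::DataFrame(
            tissue = c(rep("tumor", nT), rep("normal", nN)),
            dataset = rep("COAD", nT + nN),
            row.names = ids))
}

.simSpectrumProbs <- c("C>A" = 0.08, "C>G" = 0.06, "C>T" = 0.55,
                       "T>A" = 0.05, "T>C" = 0.16, "T>G" = 0.10)

.drawSnvAlleles <- function(n) {
    cls <- sample(names(.simSpectrumProbs), n, replace = TRUE,
                  prob = .simSpectrumProbs)
    ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
    flip <- runif(n) < 0.5                    # purine-strand representation
    ref[flip] <- .complementBase[ref[flip]]
    alt[flip] <- .complementBase[alt[flip]]
    list(ref = ref, alt = alt)
}

#' Simulate a MAF-style mutation table
#'
#' Gives each tumor exactly its ground-truth nonsynonymous burden
#' (missense-dominated, with nonsense, frameshift, splice-site, in-frame
#' and rarer classes) plus a Poisson number of silent records
#' (\code{silentFraction} of the burden in expectation). Every MSI tumor
#' carries at least one planted missense mutation in a mismatch-repair
#' gene; MSS tumors carry none (missense assignments exclude the MMR
#' panel). VAFs are Beta(\code{vafBetaShape1}, \code{vafBetaShape2})
#' draws thinned binomially into alt/ref read counts at depth
#' \code{seqDepth}, and SNV substitutions follow a C>T-dominated
#' spectrum.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth data.frame from \code{\link{simulateTruth}}.
#' @return MAF-style data.frame.
#' @export
simulateMutations <- function(config, truth) {
    nonsynPool <- c(.simDriverGenes,
                    sprintf("GENE%04d", seq_len(max(
                        50, config@nGenes - 40))))
    classes <- c("Missense_Mutation", "Nonsense_Mutation",
                 "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
                 "In_Frame_Del", "In_Frame_Ins",
                 "Translation_Start_Site", "Nonstop_Mutation")
    classProb <- c(0.70, 0.10, 0.05, 0.03, 0.05, 0.02, 0.02, 0.015, 0.035)
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
        nNon <- truth$burden[i]
        nSil <- rpois(1, config@silentFraction * nNon)
        cls <- c(sample(classes, nNon, replace = TRUE, prob = classProb),
                 rep("Silent", nSil))
        gene <- sample(nonsynPool, nNon + nSil, replace = TRUE)
        if (truth$msi_status[i] == "MSI") {
            nPlant <- min(nNon, 1L + rpois(1, 0.5))
            idx <- seq_len(nPlant)
            cls[idx] <- "Missense_Mutation"
            gene[idx] <- sample(.simMmrGenes, nPlant, replace = TRUE)
        }
        n <- nNon + nSil
        al <- .drawSnvAlleles(n)
        indel <- cls %in% c("Frame_Shift_Del", "In_Frame_Del")
        ins <- cls %in% c("Frame_Shift_Ins", "In_Frame_Ins")
        al$alt[indel] <- "-"; al$ref[ins] <- "-"
        vaf <- rbeta(n, config@vafBetaShape1, config@vafBetaShape2)
        tAlt <- rbinom(n, config@seqDepth, vaf)
        rows[[i]] <- data.frame(
            Hugo_Symbol = gene,
            Chromosome = sample(1:22, n, replace = TRUE),
            Start_Position = sample.int(2e8, n, replace = TRUE),
            Reference_Allele = al$ref, Tumor_Seq_Allele2 = al$alt,
            Variant_Classification = cls,
            Tumor_Sample_Barcode = truth$sample_id[i],
            t_ref_count = config@seqDepth - tAlt, t_alt_count = tAlt,
            stringsAsFactors = FALSE)
    }
    maf <- do.call(rbind, rows)
    maf$known_classification <- maf$Variant_Classification %in%
        .mafVocabulary
    maf
}

#' Simulate copy-number segments
#'
#' Each tumor receives a Poisson number of beyond-cutoff events
#' (\code{scnaRateCytlow} in the planted low tier, \code{scnaRateCythigh}
#' otherwise), split evenly between amplifications (segment mean 0.6 plus
#' an exponential excess) and deletions (-0.4 minus an exponential
#' excess), plus background segments whose means stay strictly inside the
#' cutoffs. The planted event count per sample is attached as attribute
#' \code{true_counts}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth data.frame from \code{\link{simulateTruth}}.
#' @return SEG-style data.frame with attribute \code{true_counts}.
#' @export
simulateSegments <- function(config, truth) {
    rows <- vector("list", nrow(truth))
    nEvents <- rpois(nrow(truth),
                     ifelse(truth$cyt_tier == "low",
                            config@scnaRateCytlow, config@scnaRateCythigh))
    for (i in seq_len(nrow(truth))) {
        nEv <- nEvents[i]
        nAmp <- rbinom(1, nEv, 0.5)
        nBg <- rpois(1, 30)
        means <- c(0.6 + rexp(nAmp, rate = 1 / 0.3),
                   -0.4 - rexp(nEv - nAmp, rate = 1 / 0.3),
                   pmax(-0.35, pmin(0.35, rnorm(nBg, 0, 0.12))))
        n <- length(means)
        start <- sample.int(2e8, n, replace = TRUE)
        rows[[i]] <- data.frame(
            Sample = truth$sample_id[i],
            Chromosome = sample(1:22, n, replace = TRUE),
            Start = start,
            End = start + sample.int(5e6, n, replace = TRUE),
            Num_Probes = 10L + rpois(n, 50),
            Segment_Mean = means, stringsAsFactors = FALSE)
    }
    seg <- do.call(rbind, rows)
    attr(seg, "true_counts") <- setNames(nEvents, truth$sample_id)
    seg
}

#' Simulate a peptide-affinity table
#'
#' Each tumor receives a Poisson number of candidate peptides with mean
#' \code{neoRatePerMissense} per missense mutation in the MAF. Mutant
#' IC50s are log-normal (median 500 nM, log-sd 1.8), putting about 10\%
#' below the 50 nM CDN cutoff; the wild-type IC50 is the mutant value
#' times a log-normal DAI (median 1, log-sd 1.2). MHC class and variant
#' type are drawn categorically. The planted peptide count per sample is
#' attached as attribute \code{true_counts}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth data.frame from \code{\link{simulateTruth}}.
#' @param maf data.frame from \code{\link{simulateMutations}}.
#' @return affinity data.frame with attribute \code{true_counts}.
#' @export
simulateAffinities <- function(config, truth, maf) {
    mis <- maf[maf$Variant_Classification == "Missense_Mutation", ]
    nMis <- table(factor(mis$Tumor_Sample_Barcode,
                         levels = truth$sample_id))
    nPep <- rpois(nrow(truth), config@neoRatePerMissense * as.integer(nMis))
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
        n <- nPep[i]
        if (!n) next
        mut <- exp(rnorm(n, log(500), 1.8))
        dai <- exp(rnorm(n, 0, 1.2))
        rows[[i]] <- data.frame(
            sample_id = truth$sample_id[i],
            peptide_id = sprintf("%s_p%05d", truth$sample_id[i],
                                 seq_len(n)),
            mhc_class = sample(c("I", "II"), n, replace = TRUE,
                               prob = c(0.6, 0.4)),
            mut_ic50 = mut, wt_ic50 = mut * dai,
            variant_type = sample(c("missense", "frameshift", "indel",
                                    "fusion"), n, replace = TRUE,
                                  prob = c(0.85, 0.10, 0.04, 0.01)),
            stringsAsFactors = FALSE)
    }
    aff <- do.call(rbind, rows)
    if (is.null(aff))
        aff <- data.frame(sample_id = character(), peptide_id = character(),
                          mhc_class = character(), mut_ic50 = numeric(),
                          wt_ic50 = numeric(), variant_type = character(),
                          stringsAsFactors = FALSE)
    attr(aff, "true_counts") <- setNames(nPep, truth$sample_id)
    aff
}

#' Simulate overall survival
#'
#' Exponential event times with rate \code{baselineHazard} (per month),
#' multiplied by \code{hazardRatioCytlow} for the planted low-activity
#' hazard group; administrative censoring uniform on
#' (0, \code{censorMax}].
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth data.frame from \code{\link{simulateTruth}}.
#' @return clinical data.frame with \code{sample_id}, \code{os_time},
#'   \code{os_event}, \code{stage}.
#' @export
simulateClinical <- function(config, truth) {
    n <- nrow(truth)
    rate <- config@baselineHazard *
        ifelse(truth$hazard_group == "low", config@hazardRatioCytlow, 1)
    tEvent <- rexp(n, rate)
    tCens <- runif(n, 0, config@censorMax)
    data.frame(sample_id = truth$sample_id,
               os_time = pmin(tEvent, tCens),
               os_event = as.integer(tEvent <= tCens),
               stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                              prob = c(0.15, 0.35, 0.3, 0.2)),
               stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Seeds the RNG from \code{config@seed} and draws, in fixed order, the
#' ground truth and every component table, so that identical
#' configurations give identical cohorts. The returned ground truth
#' carries the planted copy-number event and candidate-peptide counts in
#' addition to the labels from \code{\link{simulateTruth}}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CytCohort} with all components populated.
#' @examples
#' cohort <- simulateCohort(simConfig(nTumor = 20, nGenes = 120, seed = 3))
#' cohort
#' @export
simulateCohort <- function(config = simConfig()) {
    stopifnot(methods::is(config, "SimConfig"))
    set.seed(config@seed)
    truth <- simulateTruth(config)
    expr <- simulateExpression(config, truth)
    maf <- simulateMutations(config, truth)
    seg <- simulateSegments(config, truth)
    aff <- simulateAffinities(config, truth, maf)
    clin <- simulateClinical(config, truth)
    truth$scna_count <- as.integer(attr(seg, "true_counts")[truth$sample_id])
    truth$neo_count <- as.integer(attr(aff, "true_counts")[truth$sample_id])
    attr(seg, "true_counts") <- NULL
    attr(aff, "true_counts") <- NULL
    CytCohort(expr = expr, maf = maf, segments = seg, clinical = clin,
              affinities = aff, groundTruth = truth)
}
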