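#' Construct a pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' cytolytic genes GZMA and PRF1, a 0.01 TPM offset, 25\% quartile strata,
#' the nine mismatch-repair genes for MSI calling, a 50 nM IC50 cutoff for
#' classically defined neoepitopes, DAI cutoffs of 10 (MHC-I) and 4
#' (MHC-II), segment-mean cutoffs of 0.6 and -0.4, a 1-CPM-in-50\%-of-samples
#' expression filter, a 0.1 differential-expression FDR, a 0.05 log-rank
#' threshold, 5\%/2\% TIL/TAN medians, and 10\% IHC positivity.
#'
#' @param cytGenes,tpmOffset,quartileFraction,mmrGenes,checkpointGenes,nonsynClasses,cdnIc50Cutoff,daiCutoffMhc1,daiCutoffMhc2,scnaAmpCutoff,scnaDelCutoff,cpmFilter,cpmSampleFraction,deFdr,survivalAlpha,tilMedian,tanMedian,mmrPositivePct,stainLowCut,randomSeed
#'   see \linkS4class{CytConfig}.
#' @return a validated \linkS4class{CytConfig}.
#' @examples
#' cfg <- cytConfig()
#' cfg
#' @export
cytConfig <- function(cytGenes = c("GZMA", "PRF1"),
                      tpmOffset = 0.01,
                      quartileFraction = 0.25,
                      mmrGenes = c("MLH1", "MLH3", "MSH2", "MSH3", "MSH4",
                                   "MSH5", "MSH6", "PMS1", "PMS2"),
                      checkpointGenes = c("CD274", "CTLA4", "PDCD1", "LAG3",
                                          "TIGIT", "IDO1", "HAVCR2", "VISTA",
                                          "VTCN1", "IDO2", "ADORA2A",
                                          "PDCD1LG2"),
                      nonsynClasses = c("Missense_Mutation",
                                        "Nonsense_Mutation",
                                        "Nonstop_Mutation", "Splice_Site",
                                        "Translation_Start_Site",
                                        "Frame_Shift_Ins", "Frame_Shift_Del",
                                        "In_Frame_Ins", "In_Frame_Del"),
                      cdnIc50Cutoff = 50,
                      daiCutoffMhc1 = 10,
                      daiCutoffMhc2 = 4,
                      scnaAmpCutoff = 0.6,
                      scnaDelCutoff = -0.4,
                      cpmFilter = 1,
                      cpmSampleFraction = 0.5,
                      deFdr = 0.1,
                      survivalAlpha = 0.05,
                      tilMedian = 5,
                      tanMedian = 2,
                      mmrPositivePct = 10,
                      stainLowCut = 10,
                      randomSeed = 1L) {
    methods::new("CytConfig",
        cytGenes = as.character(cytGenes),
        tpmOffset = as.numeric(tpmOffset),
        quartileFraction = as.numeric(quartileFraction),
        mmrGenes = as.character(mmrGenes),
        checkpointGenes = as.character(checkpointGenes),
        nonsynClasses = as.character(nonsynClasses),
        cdnIc50Cutoff = as.numeric(cdnIc50Cutoff),
        daiCutoffMhc1 = as.numeric(daiCutoffMhc1),
        daiCutoffMhc2 = as.numeric(daiCutoffMhc2),
        scnaAmpCutoff = as.numeric(scnaAmpCutoff),
        scnaDelCutoff = as.numeric(scnaDelCutoff),
        cpmFilter = as.numeric(cpmFilter),
        cpmSampleFraction = as.numeric(cpmSampleFraction),
        deFdr = as.numeric(deFdr),
        survivalAlpha = as.numeric(survivalAlpha),
        tilMedian = as.numeric(tilMedian),
        tanMedian = as.numeric(tanMedian),
        mmrPositivePct = as.numeric(mmrPositivePct),
        stainLowCut = as.numeric(stainLowCut),
        randomSeed = as.integer(randomSeed))
}

# snake_case keys used in the on-disk YAML dialect <-> slot names
.configKeyMap <- c(
    cyt_genes = "cytGenes", tpm_offset = "tpmOffset",
    quartile_fraction = "quartileFraction", mmr_genes = "mmrGenes",
    checkpoint_genes = "checkpointGenes", nonsyn_classes = "nonsynClasses",
    cdn_ic50_cutoff = "cdnIc50Cutoff", dai_cutoff_mhc1 = "daiCutoffMhc1",
    dai_cutoff_mhc2 = "daiCutoffMhc2", scna_amp_cutoff = "scnaAmpCutoff",
    scna_del_cutoff = "scnaDelCutoff", cpm_filter = "cpmFilter",
    cpm_sample_fraction = "cpmSampleFraction", de_fdr = "deFdr",
    survival_alpha = "survivalAlpha", til_median = "tilMedian",
    tan_median = "tanMedian", mmr_positive_pct = "mmrPositivePct",
    stain_low_cut = "stainLowCut", random_seed = "randomSeed")

#' Read a pipeline configuration from a YAML file
#'
#' The file is flat YAML with snake_case keys (\code{cyt_genes},
#' \code{tpm_offset}, \code{quartile_fraction}, \code{mmr_genes},
#' \code{cdn_ic50_cutoff}, \code{dai_cutoff_mhc1}, \code{dai_cutoff_mhc2},
#' \code{scna_amp_cutoff}, \code{scna_del_cutoff}, \code{cpm_filter},
#' \code{cpm_sample_fraction}, \code{de_fdr}, \code{survival_alpha},
#' \code{til_median}, \code{tan_median}, \code{mmr_positive_pct},
#' \code{random_seed}, ...). Absent keys take their defaults; unknown keys
#' raise a warning; out-of-range values are rejected by the class validity.
#'
#' @param path path to a YAML file; an empty or absent-key file yields the
#'   full default configuration.
#' @return a validated \linkS4class{CytConfig}.
#' @seealso \code{\link{saveConfig}}
#' @export
loadConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), names(.configKeyMap))
    if (length(unknown))
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "), call. = FALSE)
    vals <- vals[intersect(names(vals), names(.configKeyMap))]
    names(vals) <- .configKeyMap[names(vals)]
    do.call(cytConfig, vals)
}

#' Write a pipeline configuration to a YAML file
#'
#' Writes every threshold under its snake_case key so that
#' \code{\link{loadConfig}} reproduces the object exactly; used to record
#' the effective configuration next to pipeline outputs.
#'
#' @param config a \linkS4class{CytConfig}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
    stopifnot(methods::is(config, "CytConfig"))
    vals <- lapply(.configKeyMap, function(s) slot(config, s))
    names(vals) <- names(.configKeyMap)
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' Construct synthetic-cohort simulation parameters
#'
#' Defaults define the study conditions the generator emulates: a
#' 200-tumor, 2,000-gene cohort with 15\% MSI tumors, Poisson
#' nonsynonymous burdens of 300 (MSI) and 60 (MSS) doubled in the
#' top-quartile cytolytic tier, Beta(5,5) variant allele fractions thinned
#' at depth 80, a planted 1.5 log2 checkpoint shift in MSI tumors,
#' Poisson copy-number event rates of 40 (CYT-low tier) vs 20, two
#' candidate peptides per missense mutation with ~10\% of mutant IC50s
#' under 50 nM, and exponential survival (baseline 0.025 events/month,
#' administrative censoring within 240 months) with a hazard ratio of 1.8
#' on the below-median cytolytic-activity half.
#'
#' @param nTumor,nNormal,nGenes,msiFraction,burdenMeanMsi,burdenMeanMss,vafBetaShape1,vafBetaShape2,seqDepth,silentFraction,checkpointGenes,checkpointLog2fcMsi,checkpointCytCoupling,cytEffectOnBurden,scnaRateCytlow,scnaRateCythigh,neoRatePerMissense,hazardRatioCytlow,baselineHazard,censorMax,normalCytMultiplier,seed
#'   see \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(nTumor = 40, nGenes = 200, seed = 7)
#' @export
simConfig <- function(nTumor = 200L, nNormal = 20L, nGenes = 2000L,
                      msiFraction = 0.15,
                      burdenMeanMsi = 300, burdenMeanMss = 60,
                      vafBetaShape1 = 5, vafBetaShape2 = 5,
                      seqDepth = 80L, silentFraction = 0.3,
                      checkpointGenes = c("CD274", "CTLA4", "PDCD1", "LAG3",
                                          "TIGIT", "IDO1", "HAVCR2", "VISTA",
                                          "VTCN1", "IDO2", "ADORA2A",
                                          "PDCD1LG2"),
                      checkpointLog2fcMsi = 1.5,
                      checkpointCytCoupling = 0.8,
                      cytEffectOnBurden = 2,
                      scnaRateCytlow = 40, scnaRateCythigh = 20,
                      neoRatePerMissense = 2,
                      hazardRatioCytlow = 1.8,
                      baselineHazard = 0.025, censorMax = 240,
                      normalCytMultiplier = 2,
                      seed = 1L) {
    methods::new("SimConfig",
        nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
        nGenes = as.integer(nGenes), msiFraction = as.numeric(msiFraction),
        burdenMeanMsi = as.numeric(burdenMeanMsi),
        burdenMeanMss = as.numeric(burdenMeanMss),
        vafBetaShape1 = as.numeric(vafBetaShape1),
        vafBetaShape2 = as.numeric(vafBetaShape2),
        seqDepth = as.integer(seqDepth),
        silentFraction = as.numeric(silentFraction),
        checkpointGenes = as.character(checkpointGenes),
        checkpointLog2fcMsi = as.numeric(checkpointLog2fcMsi),
        checkpointCytCoupling = as.numeric(checkpointCytCoupling),
        cytEffectOnBurden = as.numeric(cytEffectOnBurden),
        scnaRateCytlow = as.numeric(scnaRateCytlow),
        scnaRateCythigh = as.numeric(scnaRateCythigh),
        neoRatePerMissense = as.numeric(neoRatePerMissense),
        hazardRatioCytlow = as.numeric(hazardRatioCytlow),
        baselineHazard = as.numeric(baselineHazard),
        censorMax = as.numeric(censorMax),
        normalCytMultiplier = as.numeric(normalCytMultiplier),
        seed = as.integer(seed))
}

#' Null-effect variant of a simulation configuration
#'
#' Returns a copy with every planted effect removed: equal burden means,
#' no checkpoint MSI shift, no checkpoint-cytolytic coupling, no burden
#' inflation in the high tier, equal copy-number rates, and unit hazard
#' ratio. Used for null-control calibration of downstream tests.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig} with all effects nulled.
#' @export
nullEffects <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    config@burdenMeanMsi <- config@burdenMeanMss
    config@checkpointLog2fcMsi <- 0
    config@checkpointCytCoupling <- 0
    config@cytEffectOnBurden <- 1
    config@scnaRateCytlow <- config@scnaRateCythigh
    config@hazardRatioCytlow <- 1
    methods::validObject(config)
    config
}
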