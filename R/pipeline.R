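#' Run the full cytolytic-stratification pipeline on a cohort
#'
#' Orchestrates every stage whose inputs are present: TPM and cytolytic
#' index, quartile stratification, tumor-vs-normal comparison, MSI
#' calling and mutation summaries, copy-number event burden, neoepitope
#' classification and loads, low-expression filtering and differential
#' expression, checkpoint correlations, and survival analyses (strata
#' log-rank and two-gene synergy). Stages with absent inputs are skipped
#' and recorded in the manifest. Deterministic: the only randomness in
#' the pipeline itself is none — all stochastic structure lives in the
#' cohort.
#'
#' @param cohort a \linkS4class{CytCohort} (expression required).
#' @param config a \linkS4class{CytConfig}.
#' @param outDir optional directory; when given, the per-sample result
#'   table, the test table, the effective configuration and a run
#'   manifest are written there.
#' @return list with \code{samples} (per-tumor-sample data.frame),
#'   \code{tests} (cohort-level association results), \code{de}
#'   (differential-expression table or NULL), \code{curves} (KM curves or
#'   NULL), \code{manifest} (stages run/skipped and thresholds).
#' @examples
#' cohort <- simulateCohort(simConfig(nTumor = 24, nGenes = 150, seed = 2))
#' res <- runPipeline(cohort)
#' head(res$samples)
#' @export
runPipeline <- function(cohort, config = cytConfig(), outDir = NULL) {
    stopifnot(methods::is(cohort, "CytCohort"),
              methods::is(config, "CytConfig"))
    if (is.null(cohort@expr))
        stop("the pipeline requires the expression component", call. = FALSE)
    manifest <- list(stages = character(), skipped = character())
    tests <- list()

    se <- computeTpm(cohort@expr, config@tpmOffset)
    cyt <- computeCyt(se, config@cytGenes)
    tumors <- cyt$sample_id[cyt$tissue == "tumor"]
    .checkIds(cohort, tumors)
    cytTum <- cyt[cyt$tissue == "tumor", ]
    strata <- stratifyCyt(cytTum, config@quartileFraction)
    samples <- strata
    manifest$stages <- c(manifest$stages, "cyt")

    if (any(cyt$tissue == "normal")) {
        tests$tumor_vs_normal <- cbind(
            comparison = "cyt_tumor_vs_normal",
            compareCytGroups(list(cyt_index = cyt$cyt_index),
                             cyt$tissue)[, -1])
        manifest$stages <- c(manifest$stages, "tumor_vs_normal")
    }

    if (!is.null(cohort@maf)) {
        ms <- mutationSummary(cohort@maf, tumors, config@mmrGenes)
        samples <- merge(samples, ms, by = "sample_id", sort = FALSE)
        grpOk <- function(v) {
            tab <- tapply(!is.na(v), samples$msi_status, sum)
            length(tab) == 2 && all(tab >= 2)
        }
        vals <- list()
        if (grpOk(samples$nonsyn_count))
            vals$nonsyn_burden <- samples$nonsyn_count
        if (grpOk(samples$math_score))
            vals$math_score <- samples$math_score
        if (length(vals)) {
            bt <- compareCytGroups(vals, samples$msi_status)
            bt$comparison <- paste0(bt$comparison, "_msi_vs_mss")
            tests$burden_msi <- bt
        } else manifest$skipped <- c(manifest$skipped, "burden_msi")
        sub <- samples[samples$stratum != "middle", ]
        bs <- compareCytGroups(list(nonsyn_burden = sub$nonsyn_count),
                               droplevels(sub$stratum))
        bs$comparison <- "nonsyn_burden_high_vs_low"
        tests$burden_stratum <- bs
        manifest$stages <- c(manifest$stages, "mutations")
    } else manifest$skipped <- c(manifest$skipped, "mutations")

    if (!is.null(cohort@segments)) {
        scna <- countScnaEvents(cohort@segments, config@scnaAmpCutoff,
                                config@scnaDelCutoff, tumors)
        samples <- merge(samples,
                         scna[, c("sample_id", "amp_count", "del_count",
                                  "total_count")],
                         by = "sample_id", sort = FALSE)
        cmp <- compareScnaBurden(scna, strata)
        tests$scna <- data.frame(comparison = "scna_total_high_vs_low",
                                 test = "mann-whitney",
                                 statistic = cmp$U, p = cmp$p,
                                 q = cmp$p, stringsAsFactors = FALSE)
        manifest$stages <- c(manifest$stages, "scna")
    } else manifest$skipped <- c(manifest$skipped, "scna")

    if (!is.null(cohort@affinities)) {
        calls <- classifyNeoepitopes(cohort@affinities, config)
        loads <- neoepitopeLoad(calls, tumors)
        samples <- merge(samples, loads, by = "sample_id", sort = FALSE)
        corr <- correlateLoadCyt(loads, cytTum)
        tests$neo_cyt <- data.frame(
            comparison = paste0(corr$load_type, "_vs_cyt"),
            test = "pearson", statistic = corr$pearson_r, p = corr$p,
            q = p.adjust(corr$p, "BH"), stringsAsFactors = FALSE)
        manifest$stages <- c(manifest$stages, "neoepitopes")
    } else manifest$skipped <- c(manifest$skipped, "neoepitopes")

    de <- NULL
    filtered <- filterLowExpression(se[, tumors], config@cpmFilter,
                                    config@cpmSampleFraction)
    nHi <- sum(strata$stratum == "CYT-high")
    if (nHi >= 3) {
        de <- differentialExpression(filtered, strata, config@deFdr)
        manifest$stages <- c(manifest$stages, "de")
    } else manifest$skipped <- c(manifest$skipped, "de")

    cp <- checkpointCorrelation(se[, tumors], cytTum,
                                config@checkpointGenes)
    tests$checkpoint_cyt <- data.frame(
        comparison = paste0(cp$gene, "_vs_cyt"), test = "pearson",
        statistic = cp$pearson_r, p = cp$p,
        q = p.adjust(cp$p, "BH"), stringsAsFactors = FALSE)
    if (!is.null(cohort@maf) &&
        length(unique(samples$msi_status)) == 2) {
        msi <- setNames(samples$msi_status, samples$sample_id)
        cm <- checkpointByMsi(se[, tumors], msi, config@checkpointGenes)
        tests$checkpoint_msi <- data.frame(
            comparison = paste0(cm$gene, "_msi_vs_mss"),
            test = "mann-whitney", statistic = cm$U, p = cm$p, q = cm$q,
            direction = cm$direction, stringsAsFactors = FALSE)
    }
    manifest$stages <- c(manifest$stages, "checkpoints")

    curves <- NULL
    if (!is.null(cohort@clinical)) {
        clin <- cohort@clinical[cohort@clinical$sample_id %in% tumors, ]
        m <- merge(clin, strata[, c("sample_id", "stratum")],
                   by = "sample_id")
        sub <- m[m$stratum != "middle", ]
        lr <- logrankTest(sub, droplevels(sub$stratum))
        tests$survival_stratum <- data.frame(
            comparison = "os_high_vs_low_logrank", test = "logrank",
            statistic = lr$chi2, p = lr$p, q = lr$p,
            stringsAsFactors = FALSE)
        tpm <- SummarizedExperiment::assay(se, "tpm")
        syn <- synergyGroups(t(tpm[config@cytGenes[1:2], tumors]))
        samples <- merge(samples, syn, by = "sample_id", sort = FALSE)
        ss <- synergySurvival(clin, syn)
        if (!is.null(ss$tests))
            tests$survival_synergy <- data.frame(
                comparison = ss$tests$comparison, test = "logrank",
                statistic = ss$tests$chi2, p = ss$tests$p, q = ss$tests$p,
                stringsAsFactors = FALSE)
        curves <- ss$curves
        manifest$stages <- c(manifest$stages, "survival")
        samples <- merge(samples, clin[, c("sample_id", "os_time",
                                           "os_event")],
                         by = "sample_id", sort = FALSE)
    } else manifest$skipped <- c(manifest$skipped, "survival")

    tests <- do.call(rbind, c(lapply(unname(tests), function(d) {
        d[setdiff(c("comparison", "test", "statistic", "p", "q",
                    "direction"), colnames(d))] <- NA
        d[, c("comparison", "test", "statistic", "p", "q", "direction")]
    }), list(make.row.names = FALSE)))

    manifest$config <- lapply(.configKeyMap, function(s) slot(config, s))
    names(manifest$config) <- names(.configKeyMap)
    manifest$n_tumor <- length(tumors)

    out <- list(samples = samples, tests = tests, de = de,
                curves = curves, manifest = manifest)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        write.table(samples, file.path(outDir, "cohort_result.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(tests, file.path(outDir, "tests.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        if (!is.null(de))
            write.table(de, file.path(outDir, "differential_expression.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        saveConfig(config, file.path(outDir, "config.yaml"))
        yaml::write_yaml(manifest[c("stages", "skipped", "n_tumor")],
                         file.path(outDir, "manifest.yaml"))
    }
    out
}

.checkIds <- function(cohort, tumors) {
    bad <- list()
    if (!is.null(cohort@maf)) {
        extra <- setdiff(unique(cohort@maf$Tumor_Sample_Barcode), tumors)
        if (length(extra)) bad$maf <- extra
    }
    if (!is.null(cohort@segments)) {
        extra <- setdiff(unique(cohort@segments$Sample), tumors)
        if (length(extra)) bad$segments <- extra
    }
    if (!is.null(cohort@clinical)) {
        extra <- setdiff(cohort@clinical$sample_id, tumors)
        if (length(extra)) bad$clinical <- extra
    }
    if (!is.null(cohort@affinities)) {
        extra <- setdiff(unique(cohort@affinities$sample_id), tumors)
        if (length(extra)) bad$affinities <- extra
    }
    if (length(bad))
        stop("sample IDs not present among expression tumor samples: ",
             paste(vapply(names(bad), function(nm)
                 sprintf("%s (%s)", nm,
                         paste(head(bad[[nm]], 5), collapse = ", ")),
                 character(1)), collapse = "; "), call. = FALSE)
    invisible(TRUE)
}
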