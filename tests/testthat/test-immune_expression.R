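test_that("CPM filter keeps boundary genes and matches brute force", {
    # 4 samples, library sizes 1e6 so counts are CPM directly
    counts <- rbind(zero = c(0, 0, 0, 0),
                    boundary = c(1, 1, 0, 0),     # >=1 CPM in exactly 50%
                    below = c(1, 0, 0, 0),
                    high = c(500, 500, 500, 500))
    filler <- matrix(rep(1e6 - colSums(counts), each = 1), 1)
    rownames(filler) <- "filler"
    se <- toySe(rbind(counts, filler), rep(1000, 5))
    kept <- suppressMessages(filterLowExpression(se, 1, 0.5))
    expect_setequal(rownames(kept), c("boundary", "high", "filler"))

    # brute-force equality on a generated cohort
    cohort <- simulateCohort(simConfig(nTumor = 15, nGenes = 100, seed = 5))
    se2 <- exprData(cohort)
    got <- suppressMessages(filterLowExpression(se2))
    cts <- SummarizedExperiment::assay(se2, "counts")
    cpm <- t(t(cts) / colSums(cts)) * 1e6
    want <- rownames(cts)[rowMeans(cpm >= 1) >= 0.5]
    expect_identical(rownames(got), want)
    expect_false("NULLGENE1" %in% rownames(got))
})

test_that("differential expression is stratum-antisymmetric and errors on tiny groups", {
    cohort <- simulateCohort(simConfig(nTumor = 30, nGenes = 150, seed = 7))
    se <- suppressMessages(filterLowExpression(exprData(cohort)))
    se <- se[, SummarizedExperiment::colData(se)$tissue == "tumor"]
    strata <- data.frame(sample_id = colnames(se),
                         stratum = rep(c("CYT-high", "CYT-low"),
                                       length.out = ncol(se)))
    de <- differentialExpression(se, strata)
    expect_true(all(de$q >= de$p))
    expect_true(all(de$called == (de$q < 0.1)))

    swapped <- transform(strata,
                         stratum = ifelse(stratum == "CYT-high",
                                          "CYT-low", "CYT-high"))
    de2 <- differentialExpression(se, swapped)
    ord <- match(de$gene, de2$gene)
    expect_equal(de2$log2fc[ord], -de$log2fc)
    expect_equal(de2$p[ord], de$p)

    expect_error(differentialExpression(se, strata[1:4, ]), "at least 3")
})

test_that("planted checkpoint shifts are found by the DE test", {
    cfg <- simConfig(nTumor = 60, nGenes = 200, msiFraction = 0.5,
                     checkpointCytCoupling = 0, seed = 21)
    set.seed(cfg@seed)
    truth <- simulateTruth(cfg)
    truth$msi_status <- rep(c("MSI", "MSS"), length.out = nrow(truth))
    se <- simulateExpression(cfg, truth)[, truth$sample_id]
    strata <- data.frame(sample_id = truth$sample_id,
                         stratum = ifelse(truth$msi_status == "MSI",
                                          "CYT-high", "CYT-low"))
    de <- differentialExpression(
        suppressMessages(filterLowExpression(se)), strata)
    planted <- de[de$gene %in% cfg@checkpointGenes, ]
    expect_gte(mean(planted$called), 0.8)
    expect_true(all(planted$log2fc > 0))
})

test_that("checkpoint-cytolytic correlation has Pearson properties", {
    cohort <- simulateCohort(simConfig(nTumor = 40, nGenes = 150, seed = 9))
    se <- computeTpm(exprData(cohort))
    cyt <- computeCyt(se)
    cytT <- cyt[cyt$tissue == "tumor", ]
    seT <- se[, cytT$sample_id]

    # a gene that is an exact copy of GZMA correlates ~1 with the index
    se2 <- seT
    SummarizedExperiment::assay(se2, "tpm")["GENE0001", ] <-
        SummarizedExperiment::assay(seT, "tpm")["GZMA", ]
    out <- checkpointCorrelation(se2, cytT, c("GENE0001", "CD274"))
    expect_gt(out$pearson_r[out$gene == "GENE0001"], 0.97)

    # planted coupling makes checkpoint correlations positive
    expect_true(all(checkpointCorrelation(seT, cytT)$pearson_r > 0))

    # affine rescaling of the gene leaves r untouched
    se3 <- seT
    SummarizedExperiment::assay(se3, "tpm")["CD274", ] <-
        SummarizedExperiment::assay(seT, "tpm")["CD274", ]^2  # log-affine
    r1 <- checkpointCorrelation(seT, cytT, "CD274")$pearson_r
    r2 <- checkpointCorrelation(se3, cytT, "CD274")$pearson_r
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("checkpoint MSI comparison recovers the planted direction", {
    cohort <- simulateCohort(simConfig(nTumor = 80, nGenes = 150,
                                       seed = 12))
    se <- computeTpm(exprData(cohort))
    tr <- groundTruth(cohort)
    msi <- setNames(tr$msi_status, tr$sample_id)
    out <- checkpointByMsi(se[, tr$sample_id], msi)
    expect_gte(mean(out$direction == "MSI"), 0.9)
    expect_equal(out$q, oracleBH(out$p))
    expect_true(all(out$q >= out$p))
    expect_error(checkpointByMsi(se[, tr$sample_id],
                                 setNames(rep("MSS", nrow(tr)),
                                          tr$sample_id)),
                 "non-empty")
})
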