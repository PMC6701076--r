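test_that("identical seeds give identical cohorts, different seeds differ", {
    cfg <- simConfig(nTumor = 15, nGenes = 80, seed = 101)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(mafTable(c1), mafTable(c2))
    expect_identical(SummarizedExperiment::assay(exprData(c1), "counts"),
                     SummarizedExperiment::assay(exprData(c2), "counts"))
    expect_identical(segTable(c1), segTable(c2))
    expect_identical(clinicalTable(c1), clinicalTable(c2))
    expect_identical(groundTruth(c1), groundTruth(c2))

    c3 <- simulateCohort(simConfig(nTumor = 15, nGenes = 80, seed = 102))
    expect_false(identical(mafTable(c1), mafTable(c3)))
})

test_that("configuration invariants are enforced", {
    expect_error(simConfig(nTumor = 4), "nTumor")
    expect_error(simConfig(seqDepth = 5), "seqDepth")
    expect_error(simConfig(msiFraction = 1.2), "msiFraction")
    expect_error(simConfig(scnaRateCytlow = 0), "positive")
})

test_that("planted MSI structure matches its generating law", {
    cfg <- simConfig(seed = 55)  # n = 200, msiFraction 0.15
    cohort <- simulateCohort(cfg)
    tr <- groundTruth(cohort)
    nMsi <- sum(tr$msi_status == "MSI")
    # binomial 99.7% interval around 30 of 200
    expect_gt(nMsi, 30 - 3 * sqrt(200 * 0.15 * 0.85))
    expect_lt(nMsi, 30 + 3 * sqrt(200 * 0.15 * 0.85))

    # every MSI sample carries a missense MMR mutation; no MSS sample does
    called <- classifyMsiFromMaf(mafTable(cohort),
                                 samples = tr$sample_id)
    expect_equal(unname(called[tr$sample_id]), tr$msi_status)

    # burden ratio reflects the 300/60 means (high tier inflation aside)
    mid <- tr$cyt_tier != "high"
    ratio <- mean(tr$burden[mid & tr$msi_status == "MSI"]) /
        mean(tr$burden[mid & tr$msi_status == "MSS"])
    expect_equal(ratio, 5, tolerance = 0.2)

    # MAF burden equals the ground-truth draw exactly
    expect_equal(unname(nonsynBurden(mafTable(cohort),
                                     tr$sample_id)), tr$burden)
})

test_that("planted expression effects match their generating law", {
    cfg <- simConfig(seed = 77)
    set.seed(cfg@seed)
    truth <- simulateTruth(cfg)
    se <- simulateExpression(cfg, truth)
    counts <- SummarizedExperiment::assay(se, "counts")

    # checkpoint up-shift ~ 2^1.5 in MSI tumors (coupling noise aside)
    msi <- truth$sample_id[truth$msi_status == "MSI"]
    mss <- truth$sample_id[truth$msi_status == "MSS"]
    ratio <- mean(counts["CD274", msi]) / mean(counts["CD274", mss])
    expect_gt(ratio, 2^1.5 * 0.6)
    expect_lt(ratio, 2^1.5 * 1.9)

    # null planting: means equal within sampling error
    cfg0 <- simConfig(seed = 78, checkpointLog2fcMsi = 0,
                      checkpointCytCoupling = 0)
    set.seed(cfg0@seed)
    truth0 <- simulateTruth(cfg0)
    se0 <- simulateExpression(cfg0, truth0)
    c0 <- SummarizedExperiment::assay(se0, "counts")
    m0 <- truth0$sample_id[truth0$msi_status == "MSI"]
    s0 <- truth0$sample_id[truth0$msi_status == "MSS"]
    r0 <- mean(c0["CD274", m0]) / mean(c0["CD274", s0])
    expect_gt(r0, 0.7); expect_lt(r0, 1.4)

    # library sizes vary at least two-fold
    lib <- colSums(counts)
    expect_gte(max(lib) / min(lib), 2)

    # the designed all-zero gene survives I/O and dies at the CPM filter
    expect_true(all(counts["NULLGENE1", ] == 0))
    f <- tempfile(); writeExpression(se, f)
    expect_true("NULLGENE1" %in% rownames(readExpression(f)))
    expect_false("NULLGENE1" %in%
                 rownames(suppressMessages(filterLowExpression(se))))
})

test_that("VAF, segment and affinity draws follow their distributions", {
    cfg <- simConfig(seed = 91)
    cohort <- simulateCohort(cfg)
    maf <- mafTable(cohort)
    vaf <- computeVaf(maf)
    expect_equal(median(vaf, na.rm = TRUE), 0.5, tolerance = 0.05)
    expect_true(all(maf$t_ref_count + maf$t_alt_count == 80))

    tr <- groundTruth(cohort)
    scna <- countScnaEvents(segTable(cohort),
                            samples = tr$sample_id)
    expect_equal(scna$total_count, tr$scna_count)
    low <- tr$cyt_tier == "low"
    expect_equal(mean(tr$scna_count[low]) / mean(tr$scna_count[!low]), 2,
                 tolerance = 0.25)

    aff <- affinityTable(cohort)
    expect_gt(mean(aff$mut_ic50 < 50), 0.07)
    expect_lt(mean(aff$mut_ic50 < 50), 0.13)
    expect_equal(nrow(aff), sum(tr$neo_count))
})

test_that("computed strata recover the planted cytolytic tier", {
    cohort <- simulateCohort(simConfig(seed = 42))
    se <- computeTpm(exprData(cohort))
    cyt <- computeCyt(se)
    st <- stratifyCyt(cyt[cyt$tissue == "tumor", ])
    m <- merge(st, groundTruth(cohort), by = "sample_id")
    r <- rank(-m$cyt_latent)
    n <- nrow(m); k <- floor(n / 4)
    nonBoundary <- abs(r - k) > 5 & abs(r - (n - k)) > 5
    tierAsStratum <- c(high = "CYT-high", middle = "middle",
                       low = "CYT-low")[m$cyt_tier]
    agree <- tierAsStratum[nonBoundary] ==
        as.character(m$stratum)[nonBoundary]
    expect_gte(mean(agree), 0.95)

    # normals carry elevated cytolytic expression relative to tumors
    expect_gt(median(cyt$cyt_index[cyt$tissue == "normal"]),
              median(cyt$cyt_index[cyt$tissue == "tumor"]))
})
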