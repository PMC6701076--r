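test_that("expression reader/writer round-trips and preserves order", {
    cohort <- simulateCohort(simConfig(nTumor = 10, nNormal = 2,
                                       nGenes = 60, seed = 5))
    se <- exprData(cohort)
    f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
    writeExpression(se, f, fm)
    se2 <- readExpression(f, fm)
    expect_identical(rownames(se2), rownames(se))
    expect_identical(colnames(se2), colnames(se))
    expect_equal(SummarizedExperiment::assay(se2, "counts"),
                 SummarizedExperiment::assay(se, "counts"))
    expect_equal(SummarizedExperiment::rowData(se2)$max_transcript_length,
                 SummarizedExperiment::rowData(se)$max_transcript_length)
    expect_identical(SummarizedExperiment::colData(se2)$tissue,
                     as.character(SummarizedExperiment::colData(se)$tissue))
})

test_that("expression reader rejects malformed input with diagnostics", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("gene\tmax_transcript_length\tS1\tS2",
                 "GZMA\t1000\t1\t2",
                 "GZMA\t2000\t3\t4"), f)
    expect_error(readExpression(f), "GZMA")
    writeLines(c("gene\tmax_transcript_length\tS1\tS2",
                 "GZMA\t1000\t1\t2",
                 "PRF1\t2000\t-3\t4"), f)
    expect_error(readExpression(f), "row\\(s\\) 2")
    writeLines(c("gene\tmax_transcript_length\tS1\tS2",
                 "GZMA\t\t1\t2",
                 "PRF1\t2000\t3\t4"), f)
    expect_error(readExpression(f), "length")
    writeLines(c("gene\tS1", "GZMA\t1"), f)
    expect_error(readExpression(f), "max_transcript_length")
})

test_that("MAF reader parses records, skips comments, flags dialect drift", {
    f <- tempfile(fileext = ".maf")
    writeLines(c("#version 2.4",
                 paste("Hugo_Symbol", "Variant_Classification",
                       "Tumor_Sample_Barcode", "t_ref_count", "t_alt_count",
                       sep = "\t"),
                 "TP53\tMissense_Mutation\tS1\t10\t10",
                 "APC\tSilent\tS1\t5\t5",
                 "KRAS\tWeird_Class\tS2\t1\t1"), f)
    expect_warning(maf <- readMaf(f), "controlled vocabulary")
    expect_equal(nrow(maf), 3)
    expect_equal(maf$known_classification, c(TRUE, TRUE, FALSE))
    # unknown classifications are excluded from nonsynonymous counts
    expect_equal(unname(nonsynBurden(maf)["S2"]), 0L)

    # records without read counts retained, VAF unavailable
    f2 <- tempfile(fileext = ".maf")
    writeLines(c("Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode",
                 "TP53\tMissense_Mutation\tS1"), f2)
    maf2 <- readMaf(f2)
    expect_equal(nrow(maf2), 1)
    expect_true(is.na(computeVaf(maf2)))

    f3 <- tempfile(fileext = ".maf")
    writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode", "TP53\tS1"), f3)
    expect_error(readMaf(f3), "Variant_Classification")
})

test_that("SEG/clinical/affinity readers validate their invariants", {
    f <- tempfile()
    writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
                 "S1\t1\t100\t200\t10\t0.7"), f)
    seg <- readSegments(f)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$Segment_Mean, 0.7)
    writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
                 "S1\t1\t300\t200\t10\t0.7"), f)
    expect_error(readSegments(f), "Start > End")

    writeLines(c("sample_id\tos_time\tos_event", "S1\t10\t2"), f)
    expect_error(readClinical(f), "os_event")
    writeLines(c("sample_id\tos_time\tos_event", "S1\t10\t1"), f)
    expect_equal(readClinical(f)$os_time, 10)

    writeLines(c(paste("sample_id", "peptide_id", "mhc_class", "mut_ic50",
                       "wt_ic50", "variant_type", sep = "\t"),
                 "S1\tp1\tI\t0\t100\tmissense"), f)
    expect_error(readAffinities(f), "mut_ic50")
})

test_that("tabular writers round-trip through their readers", {
    cohort <- simulateCohort(simConfig(nTumor = 8, nNormal = 0,
                                       nGenes = 60, burdenMeanMss = 10,
                                       burdenMeanMsi = 40, seed = 9))
    d <- tempfile()
    writeCohort(cohort, d)
    expect_warning(maf2 <- readMaf(file.path(d, "mutations.maf")), NA)
    m1 <- mafTable(cohort)
    expect_equal(maf2$Hugo_Symbol, m1$Hugo_Symbol)
    expect_equal(maf2$t_alt_count, m1$t_alt_count)
    seg2 <- readSegments(file.path(d, "segments.seg"))
    expect_equal(seg2$Segment_Mean, segTable(cohort)$Segment_Mean)
    clin2 <- readClinical(file.path(d, "clinical.tsv"))
    expect_equal(clin2$os_time, clinicalTable(cohort)$os_time)
    aff2 <- readAffinities(file.path(d, "affinities.tsv"))
    expect_equal(aff2$mut_ic50, affinityTable(cohort)$mut_ic50)
    unlink(d, recursive = TRUE)
})

test_that("configuration loads defaults, rejects bad values, round-trips", {
    f <- tempfile(fileext = ".yaml")
    writeLines(character(), f)
    cfg <- loadConfig(f)
    expect_s4_class(cfg, "CytConfig")
    expect_equal(cfg@cdnIc50Cutoff, 50)
    expect_equal(cfg@mmrGenes,
                 c("MLH1", "MLH3", "MSH2", "MSH3", "MSH4", "MSH5", "MSH6",
                   "PMS1", "PMS2"))

    writeLines("quartile_fraction: 0.6", f)
    expect_error(loadConfig(f), "quartileFraction")

    writeLines("not_a_key: 3", f)
    expect_warning(loadConfig(f), "unknown config key")

    cfg2 <- cytConfig(quartileFraction = 0.2, deFdr = 0.05,
                      randomSeed = 42L)
    saveConfig(cfg2, f)
    cfg3 <- loadConfig(f)
    for (s in methods::slotNames("CytConfig"))
        expect_equal(methods::slot(cfg3, s), methods::slot(cfg2, s),
                     info = s)
})
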