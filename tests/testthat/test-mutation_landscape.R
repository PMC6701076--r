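test_that("MSI calling applies the literal missense-in-MMR rule", {
    maf <- toyMaf()
    # S1 has a missense in MSH2 -> MSI; S2 only a nonsense in MLH1 -> MSS
    msi <- classifyMsiFromMaf(maf)
    expect_equal(unname(msi[c("S1", "S2")]), c("MSI", "MSS"))

    # empty MAF: everyone MSS, with a warning about absent samples
    empty <- maf[0, ]
    expect_warning(msi2 <- classifyMsiFromMaf(empty,
                                              samples = c("S1", "S2")),
                   "absent")
    expect_equal(unname(msi2), c("MSS", "MSS"))

    # the panel is configurable
    expect_equal(unname(classifyMsiFromMaf(maf, mmrGenes = "PMS2")["S1"]),
                 "MSS")
})

test_that("nonsynonymous burden counts non-silent coding records only", {
    maf <- toyMaf()
    b <- nonsynBurden(maf)
    expect_equal(unname(b[c("S1", "S2")]), c(3L, 2L))
    expect_equal(unname(nonsynBurden(maf[0, ], samples = "S9")), 0L)

    # equality with a brute-force filter on a generated cohort
    cohort <- simulateCohort(simConfig(nTumor = 12, nGenes = 80, seed = 4))
    maf2 <- mafTable(cohort)
    nonsyn <- cytConfig()@nonsynClasses
    brute <- vapply(sort(unique(maf2$Tumor_Sample_Barcode)), function(s)
        sum(maf2$Tumor_Sample_Barcode == s &
            maf2$Variant_Classification %in% nonsyn), integer(1))
    expect_equal(nonsynBurden(maf2), brute)
})

test_that("substitution spectra collapse to pyrimidine-reference classes", {
    maf <- data.frame(
        Hugo_Symbol = "X", Tumor_Sample_Barcode = "S1",
        Reference_Allele = c("C", "C", "G", "T"),
        Tumor_Seq_Allele2 = c("T", "T", "A", "G"),
        Variant_Classification = "Missense_Mutation",
        stringsAsFactors = FALSE)
    sp <- mutationSpectrum(maf)
    expect_equal(sp["S1", "C>T"], 0.75)   # G>A complements into C>T
    expect_equal(sp["S1", "T>G"], 0.25)
    expect_equal(sum(sp["S1", ]), 1)

    one <- maf[1, ]
    expect_equal(mutationSpectrum(one)["S1", "C>T"], 1)

    # invariant to record order; non-SNVs skipped
    maf$Reference_Allele[2] <- "-"
    sp1 <- mutationSpectrum(maf)
    sp2 <- mutationSpectrum(maf[sample(nrow(maf)), ])
    expect_equal(sp1, sp2)
    expect_equal(sum(sp1["S1", ]), 1)
})

test_that("VAF arithmetic and availability contract", {
    expect_equal(computeVaf(5, 5), 0.5)
    expect_equal(computeVaf(0, 30), 0)
    expect_equal(computeVaf(3, 7), 0.3)
    expect_true(is.na(computeVaf(0, 0)))
    expect_true(is.na(computeVaf(NA, 10)))
    expect_equal(computeVaf(toyMaf())[1:2], c(0.5, 0.3))
})

test_that("MATH equals the scaled-MAD/median formula and its invariances", {
    expect_equal(mathScore(c(0.2, 0.25, 0.3, 0.35, 0.4)),
                 100 * 1.4826 * 0.05 / 0.3, tolerance = 1e-12)
    expect_equal(mathScore(rep(0.3, 6)), 0)
    v <- c(0.1, 0.22, 0.31, 0.35, 0.48, 0.5)
    expect_equal(mathScore(v), mathScore(v * 0.37))      # scale invariance
    expect_equal(mathScore(v), mathScore(rev(v)))        # order invariance
    expect_warning(expect_true(is.na(mathScore(c(0.1, 0.2)))), "5")
    expect_warning(expect_true(is.na(mathScore(rep(0, 6)))), "zero")
})

test_that("pairwise Fisher matches hypergeometric enumeration", {
    # perfect co-occurrence 3/3 vs 0/3
    maf <- data.frame(
        Hugo_Symbol = rep(c("A", "B"), each = 3),
        Tumor_Sample_Barcode = rep(c("S1", "S2", "S3"), 2),
        Variant_Classification = "Missense_Mutation",
        stringsAsFactors = FALSE)
    out <- pairwiseFisher(maf, c("A", "B"),
                          samples = paste0("S", 1:6))
    expect_equal(out$p, 0.1)
    expect_equal(out$direction, "co-occurring")

    # independent 50/50 pattern: p = 1
    maf2 <- data.frame(
        Hugo_Symbol = c("A", "A", "B", "B"),
        Tumor_Sample_Barcode = c("S1", "S2", "S1", "S3"),
        Variant_Classification = "Missense_Mutation",
        stringsAsFactors = FALSE)
    out2 <- pairwiseFisher(maf2, c("A", "B"),
                           samples = paste0("S", 1:4))
    expect_equal(out2$p, 1)

    # genes mutated everywhere or nowhere are skipped
    expect_message(
        out3 <- pairwiseFisher(maf, c("A", "B", "ZZZ"),
                               samples = paste0("S", 1:6)), "ZZZ")
    expect_equal(nrow(out3), 1)

    # random presence patterns, n <= 12: p equals the enumeration oracle
    set.seed(7)
    for (rep in 1:25) {
        n <- sample(4:12, 1)
        pa <- rbinom(n, 1, 0.5); pb <- rbinom(n, 1, 0.5)
        if (sum(pa) %in% c(0, n) || sum(pb) %in% c(0, n)) next
        sm <- paste0("S", 1:n)
        maf4 <- rbind(
            data.frame(Hugo_Symbol = "A", Tumor_Sample_Barcode = sm[pa == 1],
                       Variant_Classification = "Missense_Mutation"),
            data.frame(Hugo_Symbol = "B", Tumor_Sample_Barcode = sm[pb == 1],
                       Variant_Classification = "Missense_Mutation"))
        got <- pairwiseFisher(maf4, c("A", "B"), samples = sm)$p
        want <- oracleFisher2x2(sum(pa & pb), sum(pa & !pb),
                                sum(!pa & pb), sum(!pa & !pb))
        expect_equal(got, want, tolerance = 1e-9)
    }
})

test_that("gene-stratum association is symmetric and directed", {
    strata <- data.frame(sample_id = paste0("S", 1:6),
                         stratum = rep(c("CYT-high", "CYT-low"), each = 3))
    maf <- data.frame(Hugo_Symbol = "ACVR1B",
                      Tumor_Sample_Barcode = c("S1", "S2", "S3"),
                      Variant_Classification = "Missense_Mutation",
                      stringsAsFactors = FALSE)
    out <- geneStratumAssociation(maf, strata, "ACVR1B")
    expect_equal(out$p, 0.1)
    expect_equal(out$enriched_stratum, "CYT-high")

    # equal fractions: p = 1, no direction
    maf2 <- data.frame(Hugo_Symbol = "TP53",
                       Tumor_Sample_Barcode = c("S1", "S4"),
                       Variant_Classification = "Missense_Mutation",
                       stringsAsFactors = FALSE)
    out2 <- geneStratumAssociation(maf2, strata, "TP53")
    expect_equal(out2$p, 1)
    expect_equal(out2$enriched_stratum, "none")

    # swapping the labels flips the direction, not the p-value
    swapped <- strata
    swapped$stratum <- rev(strata$stratum)
    out3 <- geneStratumAssociation(maf, swapped, "ACVR1B")
    expect_equal(out3$p, out$p)
    expect_equal(out3$enriched_stratum, "CYT-low")
})
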