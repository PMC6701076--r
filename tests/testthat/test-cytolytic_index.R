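test_that("TPM normalization matches hand computation and records offset", {
    se <- toySe(matrix(c(10, 20, 30), 3, 1,
                       dimnames = list(c("A", "B", "C"), "S1")),
                c(1000, 2000, 3000))
    tpm <- SummarizedExperiment::assay(computeTpm(se, offset = 0), "tpm")
    expect_equal(as.numeric(tpm), rep(1e6 / 3, 3))  # equal coverages

    # single gene is forced to 1e6 (+ offset)
    se1 <- toySe(matrix(7, 1, 1, dimnames = list("A", "S1")), 500)
    expect_equal(as.numeric(
        SummarizedExperiment::assay(computeTpm(se1, 0.01), "tpm")),
        1e6 + 0.01)

    # a zero-count gene in a non-zero sample lands exactly on the offset
    se2 <- toySe(matrix(c(0, 50), 2, 1, dimnames = list(c("A", "B"), "S1")),
                 c(1000, 1000))
    out <- computeTpm(se2, 0.01)
    expect_identical(S4Vectors::metadata(out)$tpm_offset, 0.01)
    expect_equal(SummarizedExperiment::assay(out, "tpm")["A", "S1"], 0.01)

    # all-zero sample rejected by name
    se3 <- toySe(matrix(c(1, 0), 1, 2, dimnames = list("A", c("S1", "S2"))),
                 1000)
    expect_error(computeTpm(se3), "S2")
})

test_that("TPM columns sum to 1e6 before the offset on generated cohorts", {
    cohort <- simulateCohort(simConfig(nTumor = 15, nGenes = 120, seed = 3))
    tpm0 <- SummarizedExperiment::assay(
        computeTpm(exprData(cohort), offset = 0), "tpm")
    expect_equal(colSums(tpm0), setNames(rep(1e6, ncol(tpm0)),
                                         colnames(tpm0)),
                 tolerance = 1e-9)
})

test_that("cytolytic index is the geometric mean of the marker TPMs", {
    mk <- function(v1, v2) {
        se <- toySe(matrix(1, 2, length(v1),
                           dimnames = list(c("GZMA", "PRF1"),
                                           paste0("S", seq_along(v1)))),
                    c(1000, 1000))
        SummarizedExperiment::assay(se, "tpm") <-
            matrix(c(rbind(v1, v2)), 2, length(v1),
                   dimnames = dimnames(se))
        se
    }
    expect_equal(computeCyt(mk(4, 9))$cyt_raw, 6)           # sqrt(36)
    expect_equal(computeCyt(mk(5, 5))$cyt_raw, 5)           # idempotence
    expect_equal(computeCyt(mk(100, 0.01))$cyt_raw, 1)      # sqrt(1)
    expect_equal(computeCyt(mk(4, 9))$cyt_index, log2(7))
    expect_error(computeCyt(mk(4, 9), c("GZMA", "CD8A")), "CD8A")

    # scale equivariance and AM-GM on a generated cohort
    cohort <- simulateCohort(simConfig(nTumor = 12, nGenes = 80, seed = 8))
    se <- computeTpm(exprData(cohort))
    cyt <- computeCyt(se)
    tpm <- SummarizedExperiment::assay(se, "tpm")
    se2 <- se
    SummarizedExperiment::assay(se2, "tpm")[c("GZMA", "PRF1"), ] <-
        tpm[c("GZMA", "PRF1"), ] * 3
    expect_equal(computeCyt(se2)$cyt_raw, cyt$cyt_raw * 3)
    am <- colMeans(tpm[c("GZMA", "PRF1"), ])
    expect_true(all(cyt$cyt_raw <= am + 1e-12))
})

test_that("quartile stratification sizes, ties and permutations behave", {
    set.seed(11)
    cyt <- data.frame(sample_id = sprintf("S%03d", 1:400),
                      cyt_raw = sample(runif(400)))
    st <- stratifyCyt(cyt, 0.25)
    expect_equal(as.vector(table(st$stratum)), c(100, 200, 100))
    expect_true(min(st$cyt_raw[st$stratum == "CYT-high"]) >=
                max(st$cyt_raw[st$stratum == "CYT-low"]))

    # all-equal values: deterministic lexicographic tie-break
    tie <- data.frame(sample_id = paste0("S", 1:8), cyt_raw = 1)
    st1 <- stratifyCyt(tie, 0.25)
    expect_equal(st1$stratum[st1$sample_id %in% c("S1", "S2")],
                 factor(c("CYT-high", "CYT-high"),
                        levels = levels(st1$stratum)))
    expect_equal(sum(st1$stratum == "CYT-low"), 2)

    # permutation invariance
    perm <- sample(nrow(cyt))
    st2 <- stratifyCyt(cyt[perm, ], 0.25)
    expect_equal(st2$stratum[match(cyt$sample_id, st2$sample_id)],
                 st$stratum)

    expect_error(stratifyCyt(tie[1:5, ], 0.25), "at least 8")

    # per-dataset stratification operates within each level
    cyt$ds <- rep(c("COAD", "READ"), each = 200)
    st3 <- stratifyCyt(cyt, 0.25, by = cyt$ds)
    expect_equal(as.vector(table(st3$stratum[cyt$ds == "COAD"])),
                 c(50, 100, 50))
})

test_that("group comparisons use the right test and adjust as a batch", {
    # exact Mann-Whitney on fully separated small groups
    out <- compareCytGroups(list(x = c(1, 2, 3, 10, 11, 12)),
                            rep(c("low", "high"), each = 3))
    expect_equal(out$test, "mann-whitney")
    expect_equal(out$p, 0.1)  # 2 / choose(6, 3)
    expect_true(out$statistic %in% c(0, 9))

    # identical groups are null
    out2 <- compareCytGroups(rep(1:3, 2), rep(c("a", "b"), each = 3))
    expect_equal(out2$p, 1)

    # three groups route to Kruskal-Wallis
    out3 <- compareCytGroups(c(1, 2, 10, 11, 20, 21),
                             rep(c("a", "b", "c"), each = 2))
    expect_equal(out3$test, "kruskal-wallis")

    # batch BH equals the hand step-up
    set.seed(2)
    vals <- lapply(1:4, function(i)
        c(rnorm(8), rnorm(8, mean = i / 2)))
    out4 <- compareCytGroups(setNames(vals, paste0("v", 1:4)),
                             rep(c("g1", "g2"), each = 8))
    expect_equal(out4$q, oracleBH(out4$p))

    expect_error(compareCytGroups(1:3, c("a", "a", "b")),
                 "at least two samples")
})
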