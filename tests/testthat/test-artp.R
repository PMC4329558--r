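test_that("rank truncated product arithmetic", {
    expect_equal(rtpStatistic(c(0.01, 0.5, 0.9), 1), -log(0.01))
    expect_equal(rtpStatistic(rep(1, 4), 4), 0)
    p <- c(0.02, 0.3, 0.7)
    for (j in 1:3)
        expect_equal(rtpStatistic(c(p, 1), j), rtpStatistic(p, j))
    expect_equal(rtpStatistic(p, 2), oracleRtp(p, 2))
    expect_error(rtpStatistic(c(0, 0.5), 1), "positive")
    expect_error(rtpStatistic(p, 4), "1..length")
})

test_that("the ensemble is deterministic and row 1 is the observed scan", {
    fx <- perm8Setup()
    y <- fx$design$status
    e1 <- buildEnsemble(fx$dataset, fx$design, B = 10, seed = 99,
                        strata = NULL)
    e2 <- buildEnsemble(fx$dataset, fx$design, B = 10, seed = 99,
                        strata = NULL)
    expect_identical(pMatrix(e1), pMatrix(e2))
    obs <- scoreTestPvalues(t(dosages(fx$dataset)), y, fx$design$matrix)
    expect_equal(pMatrix(e1)[1, ], obs)
    expect_true(all(pMatrix(e1) > 0 & pMatrix(e1) <= 1))
})

test_that("an all-case stratum is a shuffling no-op and warns", {
    d <- matrix(rbinom(3 * 12, 2, 0.3), nrow = 3)
    ds <- tinyDataset(d, status = c(rep("case", 4),
                                    rep(c("case", "control"), 4)),
                      study = rep(c("A", "B"), c(4, 8)))
    design <- buildDesign(ds)
    expect_warning(buildEnsemble(ds, design, B = 5, seed = 1,
                                 strata = "study"),
                   "all-case or all-control")
})

test_that("random-permutation p-values agree with exhaustive relabeling", {
    fx <- perm8Setup()
    exact <- pMatrix(fx$ensemble)
    # per-SNP exact permutation p over all 70 relabelings
    big <- buildEnsemble(fx$dataset, fx$design, B = 4000, seed = 7,
                         strata = NULL)
    bm <- pMatrix(big)
    for (s in colnames(exact)) {
        pExact <- mean(exact[, s] <= exact[1, s])
        pHat <- mean(bm[, s] <= bm[1, s])
        se <- sqrt(pExact * (1 - pExact) / 4001)
        expect_lt(abs(pHat - pExact), 3 * se + 1e-9)
    }
})

test_that("single SNP, single truncation point reduces to the simple
           permutation p", {
    fx <- perm8Setup()
    pm <- pMatrix(fx$ensemble)[, "gA_s1", drop = FALSE]
    res <- artpAdjustedP(pm, truncation = 1L)
    simple <- mean(pm[, 1] <= pm[1, 1])
    expect_equal(pAdjusted(res), simple)
})

test_that("gene-level ARTP equals brute-force enumeration exactly", {
    fx <- perm8Setup()
    pm <- pMatrix(fx$ensemble)
    for (g in c("geneA", "geneB", "geneC")) {
        snps <- geneToSnps(fx$map)[[g]]
        mine <- artpAdjustedP(pm[, snps, drop = FALSE])
        oracle <- oracleArtpUnit(pm[, snps, drop = FALSE],
                                 seq_len(length(snps)))
        expect_identical(pAdjusted(mine), oracle$padj)
    }
    # three-SNP unit with a non-trivial truncation set
    snps3 <- c("gA_s1", "gB_s1", "gC_s1")
    mine3 <- artpAdjustedP(pm[, snps3], truncation = c(1L, 3L))
    oracle3 <- oracleArtpUnit(pm[, snps3], c(1, 3))
    expect_identical(pAdjusted(mine3), oracle3$padj)
})

test_that("pathway ARTP equals brute-force enumeration exactly", {
    fx <- perm8Setup()
    pm <- pMatrix(fx$ensemble)
    res <- artpPathwayP(fx$ensemble, fx$map, fx$pathway)
    oracle <- oracleArtpPathway(pm, geneToSnps(fx$map)[fx$pathway])
    expect_identical(pAdjusted(res$pathway), oracle$padj)
    # per-gene adjusted p equals the oracle's observed-row gene p
    for (g in seq_along(fx$pathway))
        expect_identical(pAdjusted(res$genes[[fx$pathway[g]]]),
                         oracle$geneP[1, g])
})

test_that("a one-gene pathway collapses to that gene's adjusted p", {
    fx <- perm8Setup()
    res <- artpPathwayP(fx$ensemble, fx$map, "geneA")
    gene <- artpGeneP(fx$ensemble, fx$map, "geneA")$geneA
    expect_equal(pAdjusted(res$pathway), pAdjusted(gene))
})

test_that("adjusted p respects the 1/(B+1) floor and MinP monotonicity", {
    fx <- perm8Setup()
    pm <- pMatrix(fx$ensemble)
    B <- fx$ensemble@B
    for (g in c("geneA", "geneB", "geneC")) {
        res <- artpAdjustedP(pm[, geneToSnps(fx$map)[[g]], drop = FALSE])
        expect_gte(pAdjusted(res), 1 / (B + 1))
    }
    # dragging the observed p-values toward 1 never strengthens the result
    snps <- geneToSnps(fx$map)$geneA
    sub <- pm[, snps, drop = FALSE]
    before <- pAdjusted(artpAdjustedP(sub))
    worse <- sub
    worse[1, ] <- 1 - (1 - worse[1, ]) / 4
    after <- pAdjusted(artpAdjustedP(worse))
    expect_gte(after, before)
})

test_that("leave-gene-out removes shared SNPs everywhere and is local", {
    fx <- perm8Setup()
    base <- artpPathwayP(fx$ensemble, fx$map, fx$pathway)
    lo <- leaveGeneOut(fx$ensemble, fx$map, fx$pathway, "geneB")
    expect_identical(sort(lo$genesUsed), c("geneA", "geneC"))
    expect_setequal(lo$removedSnps, c("gB_s1", "gB_s2"))
    # untouched genes keep their adjusted p (same ensemble columns)
    expect_identical(pAdjusted(lo$genes$geneA), pAdjusted(base$genes$geneA))
    expect_identical(pAdjusted(lo$genes$geneC), pAdjusted(base$genes$geneC))

    # overlapping windows: excluding one gene removes the shared SNP from
    # the other gene too
    ov <- loadCohortFixture("overlap_windows")
    st <- rep(c("case", "control"), 2)
    dso <- ov$dataset
    SummarizedExperiment::colData(dso)$status <-
        factor(st, levels = c("control", "case"))
    mapo <- mapSnpsToGenes(dso, ov$genes)
    enso <- buildExhaustiveEnsemble(dso, buildDesign(dso))
    loo <- leaveGeneOut(enso, mapo, c("gLeft", "gRight"), "gLeft")
    expect_true("snp_shared" %in% loo$removedSnps)
    expect_identical(loo$genes$gRight@nItems, 1L)  # only snp_right left

    expect_error(leaveGeneOut(fx$ensemble, fx$map, fx$pathway,
                              c("geneA", "geneB", "geneC")),
                 "empties")
})

test_that("empty or invalid truncation inputs are rejected", {
    pm <- matrix(runif(20, 0.1, 1), nrow = 10)
    expect_error(artpAdjustedP(pm, truncation = c(2L, 1L)), "increasing")
    expect_error(artpAdjustedP(pm, truncation = 3L), "increasing|1..L")
    expect_error(artpAdjustedP(matrix(nrow = 10, ncol = 0)), "empty")
})
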