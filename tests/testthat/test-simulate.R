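test_that("genotypes follow Hardy-Weinberg proportions at rho = 0", {
    cfg <- simConfig(nCases = 100L, nControls = 100L,
                     blocks = list(list(nSnps = 1L,
                                        mafRange = c(0.3, 0.3), rho = 0)),
                     missingRate = 0, seed = 61L)
    pool <- simulateGenotypes(cfg, n = 10000)
    g <- dosages(pool)[1, ]
    props <- table(factor(g, levels = 0:2)) / length(g)
    expected <- c(0.49, 0.42, 0.09)
    se <- sqrt(expected * (1 - expected) / length(g))
    expect_true(all(abs(props - expected) < 3 * se))
})

test_that("adjacent-SNP LD is high at rho = 0.9 and decays with distance", {
    cfg <- simConfig(nCases = 100L, nControls = 100L,
                     blocks = list(list(nSnps = 6L,
                                        mafRange = c(0.3, 0.3), rho = 0.9)),
                     missingRate = 0, seed = 62L)
    pool <- simulateGenotypes(cfg, n = 4000)
    d <- dosages(pool)
    adj <- mean(vapply(1:5, function(j) ldR2(d[j, ], d[j + 1, ]), 0))
    far <- ldR2(d[1, ], d[6, ])
    expect_gt(adj, 0.5)
    expect_lt(far, adj)
})

test_that("generated allele frequencies converge to the configured MAFs", {
    cfg <- simConfig(nCases = 100L, nControls = 100L,
                     blocks = list(list(nSnps = 4L,
                                        mafRange = c(0.2, 0.2), rho = 0)),
                     missingRate = 0, seed = 63L)
    pool <- simulateGenotypes(cfg, n = 10000)
    f <- rowMeans(dosages(pool)) / 2
    se <- sqrt(0.2 * 0.8 / (2 * 10000))
    expect_true(all(abs(f - 0.2) < 3 * se))
})

test_that("simulation is deterministic given the seed", {
    cfg <- simConfig(nCases = 50L, nControls = 50L, missingRate = 0.02,
                     seed = 64L)
    s1 <- simulateCohort(cfg)
    s2 <- simulateCohort(cfg)
    expect_identical(dosages(s1$dataset), dosages(s2$dataset))
    expect_identical(as.data.frame(sampleInfo(s1$dataset)),
                     as.data.frame(sampleInfo(s2$dataset)))
})

test_that("a null cohort carries no genotype-phenotype association", {
    cfg <- simConfig(nCases = 300L, nControls = 300L,
                     blocks = rep(list(list(nSnps = 5L,
                                            mafRange = c(0.2, 0.4),
                                            rho = 0.3)), 4),
                     missingRate = 0, seed = 65L)
    sim <- simulateCohort(cfg)
    assoc <- snpAssociation(sim$dataset, buildDesign(sim$dataset))
    # betas scatter around zero (20 SNPs, so the mean is itself noisy)
    expect_lt(abs(mean(assoc$beta)), 0.1)
    expect_gt(min(assoc$p), 1e-4)  # nothing wildly significant among 20
})

test_that("requested cohort sizes and study quotas are met exactly", {
    cfg <- simConfig(nCases = 120L, nControls = 80L,
                     studyFractions = c(u = 0.55, v = 0.45),
                     missingRate = 0.01, seed = 66L)
    sim <- simulateCohort(cfg)
    cd <- sampleInfo(sim$dataset)
    expect_identical(sum(cd$status == "case"), 120L)
    expect_identical(sum(cd$status == "control"), 80L)
    byStudy <- table(cd$study, cd$status)
    expect_equal(sum(byStudy["u", ]) + sum(byStudy["v", ]), 200)
    expect_true(all(byStudy > 0))
})

test_that("an unattainable case quota raises a parameter error", {
    cfg <- simConfig(nCases = 1000L, nControls = 10L, poolMultiplier = 1,
                     seed = 67L)
    pool <- simulateGenotypes(cfg, n = 200)
    expect_error(simulatePhenotype(pool, cfg), "quota|unattainable")
})

test_that("the fixture suite regenerates byte-identically", {
    d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
    makeFixtureSuite(d1); makeFixtureSuite(d2)
    files <- list.files(d1, recursive = TRUE)
    expect_identical(files, list.files(d2, recursive = TRUE))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    # the 8-sample fixture admits exactly choose(8,4) = 70 relabelings
    man <- jsonlite::read_json(file.path(d1, "perm8", "manifest.json"))
    expect_equal(choose(man$n_samples, man$n_cases), man$n_relabelings)
})
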