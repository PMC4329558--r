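test_that("logistic fit recovers the closed-form 2x2 odds ratio", {
    # cases: 30 carriers / 70 non; controls: 10 / 90 -> OR = 27/7
    g <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
    status <- rep(c("case", "control"), each = 100)
    ds <- tinyDataset(matrix(g, nrow = 1), status = status)
    fit <- fitSnpLogistic(g, buildDesign(ds))
    expect_equal(fit$or_, 27 / 7, tolerance = 1e-6)
    expect_equal(fit$beta, log(27 / 7), tolerance = 1e-6)
    expect_equal(fit$or_, exp(fit$beta))
    expect_equal(fit$ci_low, exp(fit$beta - 1.959964 * fit$se))
    expect_equal(fit$ci_high, exp(fit$beta + 1.959964 * fit$se))
})

test_that("fit matches an independent Newton IRLS on random fixtures", {
    set.seed(41)
    for (rep in 1:50) {
        n <- 120
        g <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
        x1 <- rnorm(n)
        y <- rbinom(n, 1, plogis(-0.3 + 0.4 * g + 0.2 * x1))
        if (length(unique(y)) < 2 || length(unique(g)) < 2) next
        ds <- tinyDataset(matrix(g, nrow = 1),
                          status = ifelse(y == 1, "case", "control"))
        SummarizedExperiment::colData(ds)$x1 <- x1
        fit <- fitSnpLogistic(g, buildDesign(ds, "x1"))
        X <- cbind(1, x1, g)
        ref <- oracleLogistic(X, y)
        expect_lt(abs(fit$beta - ref[3]), 1e-6)
    }
})

test_that("degenerate fits are flagged, not crashed", {
    status <- rep(c("case", "control"), each = 10)
    ds <- tinyDataset(matrix(1, 1, 20), status = status)
    design <- buildDesign(ds)
    expect_identical(fitSnpLogistic(rep(1, 20), design)$status,
                     "monomorphic")
    # perfect separation
    g <- c(rep(2, 10), rep(0, 10))
    expect_identical(fitSnpLogistic(g, design)$status, "unstable")
})

test_that("swapping case and control labels flips beta exactly", {
    set.seed(42)
    g <- sample(0:2, 80, replace = TRUE)
    y <- rbinom(80, 1, plogis(0.5 * g - 0.3))
    ds1 <- tinyDataset(matrix(g, 1), status = ifelse(y == 1, "case",
                                                     "control"))
    ds2 <- tinyDataset(matrix(g, 1), status = ifelse(y == 1, "control",
                                                     "case"))
    f1 <- fitSnpLogistic(g, buildDesign(ds1))
    f2 <- fitSnpLogistic(g, buildDesign(ds2))
    expect_equal(f1$beta, -f2$beta, tolerance = 1e-9)
})

test_that("Wald p-values are near-uniform under the global null", {
    set.seed(43)
    n <- 1000
    status <- rep(c("case", "control"), each = n / 2)
    d <- matrix(rbinom(500 * n, 2, 0.3), nrow = 500)
    ds <- tinyDataset(d, status = status)
    assoc <- snpAssociation(ds, buildDesign(ds))
    p <- assoc$p[assoc$status == "ok"]
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("score test agrees with the Wald fit in rank", {
    set.seed(44)
    n <- 500
    status <- rep(c("case", "control"), each = n / 2)
    y <- as.integer(status == "case")
    d <- matrix(rbinom(200 * n, 2, runif(200, 0.1, 0.4)), nrow = 200,
                byrow = FALSE)
    ds <- tinyDataset(d, status = status)
    design <- buildDesign(ds)
    wald <- snpAssociation(ds, design)$p
    score <- scoreTestPvalues(t(dosages(ds)), y, design$matrix)
    expect_gt(cor(wald, score, method = "spearman"), 0.99)
})

test_that("a dosage orthogonal to the null residuals scores zero", {
    y <- c(1, 1, 0, 0)
    X <- matrix(1, 4, 1)
    G <- cbind(orth = c(1, 2, 2, 1), const = c(1, 1, 1, 1))
    p <- scoreTestPvalues(G, y, X)
    expect_equal(unname(p), c(1, 1))
})

test_that("without covariates the score statistic is the trend statistic", {
    set.seed(45)
    g <- sample(0:2, 150, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    y <- rbinom(150, 1, plogis(-0.2 + 0.35 * g))
    X <- matrix(1, 150, 1)
    p <- scoreTestPvalues(matrix(g, ncol = 1), y, X)
    tab <- rbind(table(factor(g[y == 0], levels = 0:2)),
                 table(factor(g[y == 1], levels = 0:2)))
    stat <- oracleTrendStat(tab)
    expect_equal(unname(p), pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
})

test_that("PC1 separates two simulated subpopulations", {
    cfg <- simConfig(nCases = 100L, nControls = 100L,
                     blocks = rep(list(list(nSnps = 40L,
                                            mafRange = c(0.1, 0.4),
                                            rho = 0)), 5),
                     stratification = list(delta = 0.3, offset = 0,
                                           fraction = 0.5),
                     missingRate = 0.01, seed = 46L)
    pool <- simulateGenotypes(cfg, n = 300)
    pcs <- computePCs(pool, 2)
    subpop <- as.integer(sampleInfo(pool)$subpop)
    expect_gt(abs(cor(pcs[, 1], subpop)), 0.9)
})

test_that("duplicated samples land on identical PC coordinates", {
    set.seed(47)
    d <- matrix(rbinom(30 * 20, 2, 0.3), nrow = 30)
    dd <- cbind(d, d[, 1])  # sample 21 duplicates sample 1
    ds <- tinyDataset(dd)
    pcs <- computePCs(ds, 2)
    expect_equal(unname(pcs[1, ]), unname(pcs[21, ]), tolerance = 1e-8)
})

test_that("k = 0 gives an empty PC matrix and an unadjusted design", {
    d <- matrix(rbinom(10 * 12, 2, 0.3), nrow = 10)
    ds <- tinyDataset(d, status = rep(c("case", "control"), 6))
    pcs <- computePCs(ds, 0)
    expect_identical(dim(pcs), c(12L, 0L))
    design <- buildDesign(ds, pcs = pcs)
    expect_identical(ncol(design$matrix), 1L)
    expect_error(computePCs(ds, 12), "smaller")
})

test_that("PCs are invariant to SNP order up to sign", {
    set.seed(48)
    d <- matrix(rbinom(25 * 30, 2, 0.25), nrow = 25)
    ds1 <- tinyDataset(d)
    perm <- sample(25)
    ds2 <- tinyDataset(d[perm, ])
    p1 <- computePCs(ds1, 2); p2 <- computePCs(ds2, 2)
    for (k in 1:2)
        expect_equal(abs(cor(p1[, k], p2[, k])), 1, tolerance = 1e-8)
})

test_that("rank-deficient covariate encodings are rejected", {
    d <- matrix(rbinom(5 * 20, 2, 0.3), nrow = 5)
    ds <- tinyDataset(d, status = rep(c("case", "control"), 10))
    SummarizedExperiment::colData(ds)$dup <-
        as.integer(sampleInfo(ds)$status == "case")
    # 'dup' duplicates the outcome but collides with itself when doubled
    SummarizedExperiment::colData(ds)$dup2 <-
        SummarizedExperiment::colData(ds)$dup
    expect_error(buildDesign(ds, c("dup", "dup2")), "rank")
})
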