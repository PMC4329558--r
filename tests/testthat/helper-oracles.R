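# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# HWE: conditional probability of each heterozygote count given the allele
# totals, obtained by normalizing multinomial probabilities (any HWE
# parameter works under the conditioning; 0.5 is used).
oracleHweP <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nBB + nAB
    hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    probs <- vapply(hs, function(h) {
        naa <- (2 * n - nA - h) / 2
        nbb <- (nA - h) / 2
        stats::dmultinom(c(naa, h, nbb), prob = c(0.25, 0.5, 0.25))
    }, 0)
    probs <- probs / sum(probs)
    pObs <- probs[hs == nAB]
    sum(probs[probs <= pObs * (1 + 1e-9)])
}

# Newton-Raphson logistic regression, written independently of glm.fit.
oracleLogistic <- function(X, y, tol = 1e-12, maxit = 50) {
    beta <- rep(0, ncol(X))
    for (i in seq_len(maxit)) {
        eta <- as.vector(X %*% beta)
        mu <- 1 / (1 + exp(-eta))
        w <- mu * (1 - mu)
        score <- as.vector(t(X) %*% (y - mu))
        info <- t(X) %*% (X * w)
        step <- solve(info, score)
        beta <- beta + step
        if (max(abs(step)) < tol) break
    }
    beta
}

# Rank truncated product by direct arithmetic.
oracleRtp <- function(p, j) {
    sp <- p[order(p)]
    acc <- 0
    for (i in 1:j) acc <- acc - log(sp[i])
    acc
}

# ARTP over the rows of a pooled p-value matrix (row 1 observed), by
# explicit counting. Returns per-row MinP, per-row adjusted p, and the
# observed adjusted p.
oracleArtpUnit <- function(pm, ts) {
    N <- nrow(pm)
    S <- matrix(0, N, length(ts))
    for (b in 1:N)
        for (k in seq_along(ts)) S[b, k] <- oracleRtp(pm[b, ], ts[k])
    shat <- matrix(0, N, length(ts))
    for (b in 1:N)
        for (k in seq_along(ts))
            shat[b, k] <- sum(S[, k] >= S[b, k]) / N
    minp <- apply(shat, 1, min)
    perRow <- vapply(1:N, function(b) sum(minp <= minp[b]) / N, 0)
    list(minp = minp, perRow = perRow, padj = perRow[1])
}

# Two-stage pathway ARTP by explicit counting over the same pooled matrix.
oracleArtpPathway <- function(pm, geneLists, tsGeneMax = 10,
                              tsPathMax = 10) {
    N <- nrow(pm)
    geneP <- matrix(0, N, length(geneLists))
    for (g in seq_along(geneLists)) {
        sub <- pm[, geneLists[[g]], drop = FALSE]
        ts <- 1:min(ncol(sub), tsGeneMax)
        geneP[, g] <- oracleArtpUnit(sub, ts)$perRow
    }
    ts2 <- 1:min(ncol(geneP), tsPathMax)
    list(padj = oracleArtpUnit(geneP, ts2)$padj, geneP = geneP)
}

# All distinct case/control relabelings of n samples with k cases, observed
# labelling first; per-SNP p-values recomputed per relabeling with the
# package's score test (the quantity under test is the ARTP counting, not
# the score test, which has its own oracle).
oracleExhaustivePm <- function(G, y, X) {
    combs <- utils::combn(length(y), sum(y))
    pm <- NULL
    obsFirst <- NULL
    for (j in seq_len(ncol(combs))) {
        yp <- rep(0L, length(y)); yp[combs[, j]] <- 1L
        row <- scoreTestPvalues(G, yp, X)
        if (identical(yp, as.integer(y))) obsFirst <- row
        else pm <- rbind(pm, row)
    }
    rbind(obsFirst, pm, deparse.level = 0)
}

# Cochran-Armitage style trend statistic from a 2 x 3 genotype table,
# variance under the pooled (null) binomial model.
oracleTrendStat <- function(tab) {
    scores <- c(0, 1, 2)
    n <- sum(tab)
    nCase <- sum(tab[2, ])
    phat <- nCase / n
    colN <- colSums(tab)
    num <- sum(scores * (tab[2, ] - phat * colN))
    gbar <- sum(scores * colN) / n
    v <- phat * (1 - phat) * sum(colN * (scores - gbar)^2)
    num^2 / v
}
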