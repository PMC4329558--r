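#' @importFrom stats runif rbinom plogis
NULL

#' Simulation configuration
#'
#' Describes a synthetic multi-study case-control cohort: block-structured
#' genotypes in Hardy-Weinberg proportions with first-order-Markov LD,
#' uniform missingness, optional two-subpopulation stratification, and a
#' retrospective case-control outcome from an additive logistic model with
#' planted per-allele odds ratios.
#'
#' @param nCases,nControls target sample counts (defaults 2000/2000, a
#'   mid-sized GWAS cohort)
#' @param studyFractions named numeric vector of per-study sample
#'   fractions (must sum to 1); default one study
#' @param blocks list of blocks, each \code{list(nSnps, mafRange, rho)}:
#'   SNP count, the (0, 0.5] range MAFs are drawn from, and the
#'   adjacent-pair haplotype correlation in [0, 1). Default 10 blocks of 5
#'   SNPs, MAF in [0.1, 0.4], rho 0.5.
#' @param effectSnps list of \code{list(block, index, or)} planted
#'   per-allele odds ratios (all > 0); default none (global null)
#' @param missingRate per-call missing probability (default 0.02)
#' @param stratification NULL, or \code{list(delta, offset, fraction)}:
#'   two subpopulations whose per-SNP allele frequencies differ by
#'   \code{delta}, a subpopulation disease log-odds offset, and the
#'   fraction of individuals in subpopulation 2
#' @param sexEffect,ageEffect log-odds per unit for the sex indicator and
#'   the (centred) age-stratum index; defaults 0
#' @param nAgeStrata number of age strata (default 5)
#' @param poolMultiplier virtual-population size as a multiple of
#'   nCases + nControls from which cases/controls are sampled to quota
#'   (default 3)
#' @param seed integer seed; all generation is deterministic given it
#' @return validated config list
#' @export
simConfig <- function(nCases = 2000L, nControls = 2000L,
                      studyFractions = c(study1 = 1),
                      blocks = rep(list(list(nSnps = 5L,
                                             mafRange = c(0.1, 0.4),
                                             rho = 0.5)), 10),
                      effectSnps = list(), missingRate = 0.02,
                      stratification = NULL, sexEffect = 0,
                      ageEffect = 0, nAgeStrata = 5L,
                      poolMultiplier = 3, seed = 1L) {
    stopifnot(nCases >= 1, nControls >= 1, missingRate >= 0,
              missingRate < 1, poolMultiplier >= 1)
    if (abs(sum(studyFractions) - 1) > 1e-8)
        stop("studyFractions must sum to 1")
    for (b in blocks) {
        stopifnot(b$nSnps >= 1, b$rho >= 0, b$rho < 1)
        if (any(b$mafRange <= 0) || any(b$mafRange > 0.5))
            stop("mafRange must lie in (0, 0.5]")
    }
    for (e in effectSnps) {
        stopifnot(e$block >= 1, e$block <= length(blocks),
                  e$index >= 1, e$index <= blocks[[e$block]]$nSnps)
        if (e$or <= 0) stop("odds ratios must be positive")
    }
    if (!is.null(stratification))
        stopifnot(stratification$delta >= 0,
                  stratification$fraction > 0, stratification$fraction < 1)
    list(nCases = as.integer(nCases), nControls = as.integer(nControls),
         studyFractions = studyFractions, blocks = blocks,
         effectSnps = effectSnps, missingRate = missingRate,
         stratification = stratification, sexEffect = sexEffect,
         ageEffect = ageEffect, nAgeStrata = as.integer(nAgeStrata),
         poolMultiplier = poolMultiplier, seed = as.integer(seed))
}

# Per-SNP layout implied by a config: one block per "gene region", all on
# chromosome 1, blocks 1 Mb apart, SNPs 2 kb apart.
.simSnpLayout <- function(config) {
    rows <- list()
    for (b in seq_along(config$blocks)) {
        m <- config$blocks[[b]]$nSnps
        rows[[b]] <- DataFrame(
            snp_id = sprintf("b%d_s%d", b, seq_len(m)),
            chromosome = "1",
            position = (b - 1L) * 1000000L + 100000L + (seq_len(m) - 1L) * 2000L,
            allele_minor = "A", allele_major = "G",
            block = b, index = seq_len(m))
    }
    do.call(rbind, rows)
}

#' Gene table matching a simulated cohort
#'
#' One gene per LD block, its body spanning the block's SNPs, on + strand;
#' blocks are 1 Mb apart so default 20 kb/10 kb windows never overlap.
#'
#' @param config from \code{\link{simConfig}}
#' @return \code{GRanges} with one gene per block (named gene1, gene2, ...)
#' @export
simGeneTable <- function(config) {
    layout <- .simSnpLayout(config)
    sp <- split(layout$position, layout$block)
    gr <- GRanges(seqnames = "1",
                  ranges = IRanges(vapply(sp, min, 0) - 1000L,
                                   vapply(sp, max, 0) + 1000L),
                  strand = "+")
    names(gr) <- paste0("gene", seq_along(sp))
    gr
}

# Haplotype block: 2n haplotypes x m SNPs, first-order Markov with
# adjacent-pair dependence rho; marginal allele frequency f[j] per SNP
# (f may be a matrix 2n x m for subpopulation-specific frequencies).
.simHaplotypes <- function(nHap, f, rho) {
    m <- if (is.matrix(f)) ncol(f) else length(f)
    fj <- function(j) if (is.matrix(f)) f[, j] else rep(f[j], nHap)
    u <- matrix(NA_real_, nHap, m)
    u[, 1] <- runif(nHap)
    if (m > 1) for (j in 2:m) {
        keep <- runif(nHap) < rho
        u[, j] <- ifelse(keep, u[, j - 1], runif(nHap))
    }
    h <- matrix(0L, nHap, m)
    for (j in seq_len(m)) h[, j] <- as.integer(u[, j] < fj(j))
    h
}

#' Simulate pool genotypes
#'
#' Generates \code{n} individuals' genotypes under the config's block
#' structure: per block, MAFs are drawn from \code{mafRange}, haplotypes
#' follow a first-order Markov chain with adjacent correlation \code{rho},
#' and two independent haplotypes are paired per individual, so every SNP
#' is in Hardy-Weinberg proportions by construction. Missing calls are
#' sprinkled uniformly at \code{missingRate}. With stratification enabled,
#' subpopulation labels are drawn first and each subpopulation uses allele
#' frequencies f -/+ delta/2 (clamped to [0.02, 0.98]).
#'
#' @param config from \code{\link{simConfig}}
#' @param n number of individuals (default: poolMultiplier * (nCases +
#'   nControls))
#' @return a \linkS4class{GenotypeDataset}; subpopulation labels (if any)
#'   are in \code{colData$subpop}, block/index in \code{rowData}
#' @export
simulateGenotypes <- function(config, n = NULL) {
    if (is.null(n))
        n <- ceiling(config$poolMultiplier *
                     (config$nCases + config$nControls))
    set.seed(config$seed)
    layout <- .simSnpLayout(config)
    strat <- config$stratification
    subpop <- if (is.null(strat)) rep(1L, n)
              else 1L + rbinom(n, 1L, strat$fraction)
    dos <- matrix(NA_real_, nrow(layout), n)
    for (b in seq_along(config$blocks)) {
        blk <- config$blocks[[b]]
        m <- blk$nSnps
        f <- runif(m, blk$mafRange[1], blk$mafRange[2])
        if (is.null(strat)) {
            fh <- f
        } else {
            # haplotype rows alternate h1/h2 per individual; frequency row
            # follows the owner's subpopulation
            fs <- rbind(pmax(0.02, f - strat$delta / 2),
                        pmin(0.98, f + strat$delta / 2))
            owner <- rep(subpop, each = 2L)
            fh <- fs[owner, , drop = FALSE]
        }
        h <- .simHaplotypes(2L * n, fh, blk$rho)
        g <- h[seq(1, 2 * n, by = 2), , drop = FALSE] +
             h[seq(2, 2 * n, by = 2), , drop = FALSE]
        dos[layout$block == b, ] <- t(g)
    }
    if (config$missingRate > 0) {
        miss <- matrix(runif(length(dos)) < config$missingRate,
                       nrow(dos), ncol(dos))
        dos[miss] <- NA_real_
    }
    samples <- DataFrame(sample_id = sprintf("ind%05d", seq_len(n)))
    if (!is.null(strat)) samples$subpop <- factor(subpop)
    GenotypeDataset(dos, layout, samples)
}

# alpha such that the pool's expected case fraction matches the target.
.tuneIntercept <- function(eta, target) {
    lo <- -30; hi <- 30
    fr <- function(a) mean(plogis(a + eta)) - target
    if (fr(lo) > 0 || fr(hi) < 0) stop("case fraction unattainable")
    for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (fr(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Simulate the case-control outcome and sample to quota
#'
#' Assigns covariates (study, sex, age stratum), computes each pool
#' individual's disease probability from the additive logistic model
#' logit(p) = alpha + sum(beta_s g_s) + sex/age terms + subpopulation
#' offset with beta_s = log(OR_s), tunes alpha by bisection so the
#' expected case fraction matches nCases/(nCases + nControls), draws
#' disease status, and then samples cases and controls retrospectively to
#' the exact requested counts within each study. Missing dosages at effect
#' SNPs contribute their SNP mean to the linear predictor.
#'
#' @param genotypes pool dataset from \code{\link{simulateGenotypes}}
#' @param config from \code{\link{simConfig}}
#' @return list: \code{dataset} (a \linkS4class{GenotypeDataset} of
#'   nCases + nControls samples with status/study/sex/age_stratum in
#'   \code{colData}) and \code{truth} (planted SNPs, betas, subpopulation
#'   labels, the tuned alpha)
#' @export
simulatePhenotype <- function(genotypes, config) {
    n <- ncol(genotypes)
    set.seed(config$seed + 1L)
    study <- factor(sample(names(config$studyFractions), n, replace = TRUE,
                           prob = config$studyFractions),
                    levels = names(config$studyFractions))
    sex <- factor(sample(c("F", "M"), n, replace = TRUE),
                  levels = c("F", "M"))
    age <- factor(sample(paste0("age", seq_len(config$nAgeStrata)), n,
                         replace = TRUE),
                  levels = paste0("age", seq_len(config$nAgeStrata)))
    eta <- rep(0, n)
    layout <- snpInfo(genotypes)
    truthSnps <- character(); truthBetas <- numeric()
    for (e in config$effectSnps) {
        id <- layout$snp_id[layout$block == e$block & layout$index == e$index]
        g <- dosages(genotypes)[id, ]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        beta <- log(e$or)
        eta <- eta + beta * g
        truthSnps <- c(truthSnps, id); truthBetas <- c(truthBetas, beta)
    }
    eta <- eta + config$sexEffect * (sex == "M") +
        config$ageEffect * (as.integer(age) - (config$nAgeStrata + 1) / 2)
    strat <- config$stratification
    subpop <- sampleInfo(genotypes)$subpop
    if (!is.null(strat) && !is.null(subpop))
        eta <- eta + strat$offset * (subpop == "2")
    target <- config$nCases / (config$nCases + config$nControls)
    alpha <- .tuneIntercept(eta, target)
    status <- rbinom(n, 1L, plogis(alpha + eta))

    # per-study quotas, largest-remainder allocation
    quota <- function(total) {
        raw <- config$studyFractions * total
        base <- floor(raw)
        rem <- total - sum(base)
        if (rem > 0) {
            extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
            base[extra] <- base[extra] + 1
        }
        base
    }
    qCase <- quota(config$nCases); qControl <- quota(config$nControls)
    pick <- integer()
    for (s in names(config$studyFractions)) {
        inS <- which(study == s)
        cs <- inS[status[inS] == 1L]; ct <- inS[status[inS] == 0L]
        if (length(cs) < qCase[s] || length(ct) < qControl[s])
            stop("pool too small to fill case/control quota for study ", s,
                 "; raise poolMultiplier")
        pick <- c(pick, sample(cs, qCase[s]), sample(ct, qControl[s]))
    }
    pick <- sort(pick)
    out <- genotypes[, pick]
    cd <- sampleInfo(out)
    cd$status <- factor(ifelse(status[pick] == 1L, "case", "control"),
                        levels = c("control", "case"))
    cd$study <- study[pick]; cd$sex <- sex[pick]; cd$age_stratum <- age[pick]
    colData(out) <- cd
    truth <- list(effectSnps = truthSnps, betas = truthBetas,
                  alpha = alpha,
                  subpop = if (is.null(subpop)) NULL else subpop[pick])
    list(dataset = out, truth = truth)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: pool genotypes + phenotype + quota sampling.
#'
#' @param config from \code{\link{simConfig}}
#' @return as \code{\link{simulatePhenotype}}
#' @export
simulateCohort <- function(config) {
    simulatePhenotype(simulateGenotypes(config), config)
}
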