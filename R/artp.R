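#' Default truncation set
#'
#' Candidate truncation points 1, 2, ..., min(L, maxPoints): the adaptive
#' statistic considers products of the 1 up to min(L, 10) smallest
#' p-values. Capping at 10 keeps the search cheap even for genes with
#' hundreds of SNPs while spanning the signal configurations (one strong
#' SNP through many moderate ones) the adaptivity is meant to cover.
#'
#' @param L number of p-values available (SNPs in the gene, or genes in the
#'   pathway)
#' @param maxPoints cap on the number of candidate points (default 10)
#' @return strictly increasing integer vector
#' @export
defaultTruncation <- function(L, maxPoints = 10L) {
    if (L < 1) stop("need at least one item to combine")
    seq_len(min(L, maxPoints))
}

.checkTruncation <- function(ts, L) {
    ts <- as.integer(ts)
    if (!length(ts) || any(ts < 1) || any(diff(ts) <= 0) || max(ts) > L)
        stop("truncation points must be strictly increasing integers in 1..L")
    ts
}

#' Rank truncated product statistic
#'
#' The log-domain product of the j smallest p-values:
#' -sum(log(p_(1)), ..., log(p_(j))). Larger values indicate stronger
#' evidence. p-values of exactly 1 contribute nothing, so appending a 1
#' never changes the statistic at a fixed truncation point.
#'
#' @param pvalues vector of p-values in (0, 1]
#' @param j truncation point, 1 <= j <= length(pvalues)
#' @return the statistic (non-negative)
#' @export
rtpStatistic <- function(pvalues, j) {
    if (any(pvalues <= 0)) stop("p-values must be strictly positive")
    if (j < 1 || j > length(pvalues)) stop("j must lie in 1..length(pvalues)")
    -sum(log(sort(pvalues)[seq_len(j)]))
}

# (B+1) x K matrix of RTP statistics: row b, truncation point ts[k].
.rtpMatrix <- function(pm, ts) {
    maxJ <- max(ts)
    lp <- log(pm)
    cums <- t(apply(lp, 1L, function(r) cumsum(sort(r)[seq_len(maxJ)])))
    if (maxJ == 1L) cums <- matrix(cums, ncol = 1L)
    -cums[, ts, drop = FALSE]
}

# Per-row, per-truncation estimated p: share of rows (pooled, self
# included) whose statistic is >= this row's.
.estimatedP <- function(S) {
    N <- nrow(S)
    apply(S, 2L, function(v) (N - (rank(v, ties.method = "min") - 1)) / N)
}

# MinP per row and the estimated-p matrix.
.artpCore <- function(pm, ts) {
    S <- .rtpMatrix(pm, ts)
    shat <- .estimatedP(S)
    if (is.null(dim(shat))) shat <- matrix(shat, ncol = length(ts))
    list(shat = shat, minp = apply(shat, 1L, min))
}

#' Adaptive rank truncated product test for one unit
#'
#' Runs the ARTP combination over the columns of a (B+1)-row p-value matrix
#' (row 1 = observed labels, rows 2..B+1 = permuted labels). For every row
#' b and truncation point k the RTP statistic S_k(b) is computed; its
#' estimated p-value is the pooled share of rows with a statistic at least
#' as large (ties count, the row itself counts, denominator B+1). The
#' adaptive statistic MinP(b) is the minimum estimated p over the
#' truncation set, and the reported adjusted p-value is the pooled share of
#' rows whose MinP is at most the observed MinP — which accounts for the
#' adaptive minimization and bounds the result below by 1/(B+1).
#'
#' @param pm numeric matrix (B+1) x L of per-SNP (or per-gene) p-values
#' @param truncation integer vector of candidate truncation points;
#'   defaults to \code{\link{defaultTruncation}(L)}
#' @param unitName label carried into the result
#' @param level \code{"gene"} or \code{"pathway"}
#' @return an \linkS4class{ArtpResult}
#' @export
artpAdjustedP <- function(pm, truncation = NULL, unitName = "unit",
                          level = "gene") {
    if (is.null(dim(pm)) || ncol(pm) == 0)
        stop("empty unit: no p-values to combine")
    ts <- if (is.null(truncation)) defaultTruncation(ncol(pm))
          else .checkTruncation(truncation, ncol(pm))
    core <- .artpCore(pm, ts)
    padj <- mean(core$minp <= core$minp[1])
    best <- ts[which.min(core$shat[1, ])]
    new("ArtpResult", unitName = unitName, level = level,
        pAdjusted = padj, bestTruncation = as.integer(best),
        truncationSet = as.integer(ts),
        perTruncationP = core$shat[1, ], nItems = ncol(pm),
        B = nrow(pm) - 1L)
}

#' Build the shared permutation ensemble
#'
#' Fits the covariate-only null model and computes Rao score-test p-values
#' for every SNP under the observed case/control labels (row 1) and under B
#' label permutations (rows 2..B+1). Labels are shuffled within each
#' stratum (the study, by default), preserving per-study case/control
#' ratios under the null; the null model is refitted per permutation.
#' Deterministic given \code{seed}.
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @param design from \code{\link{buildDesign}}
#' @param B number of permutations (default 20000)
#' @param seed integer seed for the permutation stream
#' @param strata factor of stratum labels (one per sample), a
#'   \code{colData} column name, or NULL for unstratified shuffling
#' @param snpIds optional subset of SNPs to include
#' @return a \linkS4class{PermutationEnsemble}
#' @export
buildEnsemble <- function(x, design, B = 20000L, seed = 1L,
                          strata = "study", snpIds = NULL) {
    if (B < 1) stop("B must be >= 1")
    d <- dosages(x)
    if (!is.null(snpIds)) d <- d[snpIds, , drop = FALSE]
    G <- t(.imputeDosages(d))
    X <- design$matrix; y <- design$status
    strata <- .resolveStrata(strata, x)
    idxList <- split(seq_along(y), strata)
    for (s in names(idxList)) {
        ys <- y[idxList[[s]]]
        if (length(unique(ys)) < 2)
            warning("stratum '", s, "' is all-case or all-control; ",
                    "its shuffles are no-ops")
    }
    pm <- matrix(NA_real_, nrow = B + 1L, ncol = ncol(G),
                 dimnames = list(NULL, colnames(G)))
    pm[1L, ] <- scoreTestPvalues(G, y, X)
    set.seed(seed)
    for (b in seq_len(B)) {
        yp <- y
        for (idx in idxList) yp[idx] <- y[idx][sample.int(length(idx))]
        pm[b + 1L, ] <- scoreTestPvalues(G, yp, X)
    }
    new("PermutationEnsemble", pMatrix = pm, B = as.integer(B),
        seed = as.integer(seed), strata = strata)
}

.resolveStrata <- function(strata, x) {
    n <- ncol(x)
    if (is.null(strata)) return(factor(rep("all", n)))
    if (is.character(strata) && length(strata) == 1L) {
        col <- sampleInfo(x)[[strata]]
        if (is.null(col)) return(factor(rep("all", n)))
        return(factor(col))
    }
    if (length(strata) != n)
        stop("strata must have one label per sample")
    factor(strata)
}

#' Exhaustive relabeling ensemble
#'
#' For small samples, replaces random permutations with the complete set of
#' distinct case/control assignments (single stratum, choose(n, n_cases)
#' labelings; the observed assignment is row 1). With this ensemble the
#' ARTP counting estimators are exact and reproducible by direct
#' enumeration.
#'
#' @inheritParams buildEnsemble
#' @return a \linkS4class{PermutationEnsemble} with B = choose(n, k) - 1
#' @export
buildExhaustiveEnsemble <- function(x, design, snpIds = NULL) {
    d <- dosages(x)
    if (!is.null(snpIds)) d <- d[snpIds, , drop = FALSE]
    G <- t(.imputeDosages(d))
    X <- design$matrix; y <- design$status
    n <- length(y); k <- sum(y)
    combs <- utils::combn(n, k)
    labelings <- apply(combs, 2L, function(idx) {
        v <- integer(n); v[idx] <- 1L; v
    })
    obs <- which(apply(labelings, 2L, identical, as.integer(y)))
    ord <- c(obs, setdiff(seq_len(ncol(labelings)), obs))
    pm <- t(apply(labelings[, ord, drop = FALSE], 2L, function(yp)
        scoreTestPvalues(G, yp, X)))
    if (ncol(G) == 1L) pm <- matrix(pm, ncol = 1L,
                                    dimnames = list(NULL, colnames(G)))
    new("PermutationEnsemble", pMatrix = pm,
        B = ncol(labelings) - 1L, seed = NA_integer_,
        strata = factor(rep("all", n)))
}

#' Gene-level ARTP tests from a shared ensemble
#'
#' @param ensemble a \linkS4class{PermutationEnsemble}
#' @param map a \linkS4class{GeneSnpMap}
#' @param pathway character vector of gene names to test
#' @param truncation gene-level truncation set, or NULL for the default
#' @return named list of \linkS4class{ArtpResult}, one per gene with >= 1
#'   SNP; genes without SNPs are skipped
#' @export
artpGeneP <- function(ensemble, map, pathway = NULL, truncation = NULL) {
    g2s <- geneToSnps(map)
    if (is.null(pathway)) pathway <- names(g2s)
    pm <- pMatrix(ensemble)
    out <- list()
    for (g in pathway) {
        snps <- intersect(g2s[[g]], colnames(pm))
        if (!length(snps)) next
        out[[g]] <- artpAdjustedP(pm[, snps, drop = FALSE],
                                  truncation = truncation,
                                  unitName = g, level = "gene")
    }
    out
}

# Per-row gene-level estimated p-values: for each row b, the gene's
# adjusted p treating row b as the reference within the pooled rows.
.genePerRowP <- function(pm, snps, truncation) {
    sub <- pm[, snps, drop = FALSE]
    ts <- if (is.null(truncation)) defaultTruncation(ncol(sub))
          else .checkTruncation(truncation, ncol(sub))
    minp <- .artpCore(sub, ts)$minp
    rank(minp, ties.method = "max") / length(minp)
}

# One gene's full ARTP bundle: ArtpResult plus its per-row estimated p.
.geneArtpBundle <- function(pm, snps, truncation, unitName) {
    sub <- pm[, snps, drop = FALSE]
    ts <- if (is.null(truncation)) defaultTruncation(ncol(sub))
          else .checkTruncation(truncation, ncol(sub))
    core <- .artpCore(sub, ts)
    perRow <- rank(core$minp, ties.method = "max") / length(core$minp)
    res <- new("ArtpResult", unitName = unitName, level = "gene",
               pAdjusted = perRow[1], bestTruncation =
                   as.integer(ts[which.min(core$shat[1, ])]),
               truncationSet = as.integer(ts),
               perTruncationP = core$shat[1, ], nItems = ncol(sub),
               B = nrow(sub) - 1L)
    list(result = res, perRow = perRow)
}

#' Pathway-level ARTP test
#'
#' Two-stage combination on one shared ensemble (no second permutation
#' layer). Stage 1 turns each gene's SNP columns into a per-row gene-level
#' estimated p-value: for every row b, the pooled share of rows whose
#' gene-level MinP is at most row b's. Stage 2 applies the same RTP/MinP
#' machinery across genes to the resulting (B+1) x n_genes matrix, and the
#' pathway's adjusted p-value is the pooled share of rows whose stage-2
#' MinP is at most the observed one.
#'
#' @inheritParams artpGeneP
#' @param geneTruncation truncation set used within each gene (NULL =
#'   default per gene size)
#' @param pathwayTruncation truncation set used across genes (NULL =
#'   default)
#' @param pathwayName label for the result
#' @return list with \code{pathway} (an \linkS4class{ArtpResult}),
#'   \code{genes} (named list of gene \linkS4class{ArtpResult}) and
#'   \code{genesUsed}
#' @export
artpPathwayP <- function(ensemble, map, pathway, geneTruncation = NULL,
                         pathwayTruncation = NULL,
                         pathwayName = "pathway") {
    pm <- pMatrix(ensemble)
    g2s <- geneToSnps(map)
    used <- pathway[vapply(pathway, function(g)
        length(intersect(g2s[[g]], colnames(pm))) > 0, TRUE)]
    if (!length(used)) stop("empty pathway: no gene has any SNP")
    bundles <- lapply(used, function(g)
        .geneArtpBundle(pm, intersect(g2s[[g]], colnames(pm)),
                        geneTruncation, g))
    names(bundles) <- used
    geneP <- vapply(bundles, function(b) b$perRow, numeric(nrow(pm)))
    res <- artpAdjustedP(geneP, truncation = pathwayTruncation,
                         unitName = pathwayName, level = "pathway")
    list(pathway = res, genes = lapply(bundles, `[[`, "result"),
         genesUsed = used)
}

#' Pathway ARTP after removing genes
#'
#' Sensitivity rerun: removes the named genes and every SNP mapped to them
#' (a SNP shared with another gene through overlapping windows is removed
#' from that gene too), then recomputes the pathway ARTP on the same
#' ensemble columns that remain.
#'
#' @inheritParams artpPathwayP
#' @param genes gene names to exclude
#' @return as \code{\link{artpPathwayP}}; additionally \code{removedSnps}
#' @export
leaveGeneOut <- function(ensemble, map, pathway, genes,
                         geneTruncation = NULL, pathwayTruncation = NULL) {
    absent <- setdiff(genes, pathway)
    if (length(absent))
        warning("gene(s) to exclude not in pathway: ",
                paste(absent, collapse = ", "))
    g2s <- geneToSnps(map)
    removedSnps <- unique(unlist(g2s[intersect(genes, names(g2s))]))
    keepPathway <- setdiff(pathway, genes)
    newG2s <- lapply(g2s, function(s) setdiff(s, removedSnps))
    newMap <- new("GeneSnpMap", geneToSnps = newG2s,
                  snpToGenes = lapply(snpToGenes(map)[
                      setdiff(names(snpToGenes(map)), removedSnps)],
                      function(g) setdiff(g, genes)),
                  emptyGenes = names(newG2s)[lengths(newG2s) == 0],
                  windows = map@windows)
    keepPathway <- keepPathway[lengths(newG2s[keepPathway]) > 0]
    if (!length(keepPathway)) stop("excluding these genes empties the pathway")
    out <- artpPathwayP(ensemble, newMap, keepPathway,
                        geneTruncation = geneTruncation,
                        pathwayTruncation = pathwayTruncation)
    out$removedSnps <- removedSnps
    out
}
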