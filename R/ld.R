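#' Pairwise linkage disequilibrium r-squared
#'
#' Genotype-correlation (composite) LD: the squared Pearson correlation of
#' minor-allele dosages over pairwise-complete observations, conventionally
#' computed among controls so case enrichment cannot masquerade as LD. The
#' value is invariant to which allele is labelled minor at either locus. A
#' SNP monomorphic within the subset has undefined LD (NA).
#'
#' @param a,b dosage vectors of two SNPs (same samples)
#' @return r-squared in [0, 1], or NA if undefined
#' @export
ldR2 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return(NA_real_)
    if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2)
        return(NA_real_)
    cor(a[ok], b[ok])^2
}

#' LD matrix among controls
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @param subset which samples to use: \code{"controls"} (default) or
#'   \code{"all"}
#' @return symmetric matrix of r-squared values (NA where undefined),
#'   with attribute \code{subset}
#' @export
ldMatrix <- function(x, subset = c("controls", "all")) {
    subset <- match.arg(subset)
    d <- dosages(x)
    if (subset == "controls") {
        st <- sampleInfo(x)$status
        if (is.null(st)) stop("dataset has no status column")
        d <- d[, which(st == "control"), drop = FALSE]
    }
    r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
    r2 <- r^2
    mono <- apply(d, 1L, function(v) length(unique(v[!is.na(v)])) < 2)
    r2[mono, ] <- NA; r2[, mono] <- NA
    diag(r2)[!mono] <- 1
    attr(r2, "subset") <- subset
    r2
}

#' Group SNPs into independent association signals
#'
#' Single-linkage clustering of the graph whose edges connect SNP pairs
#' with r-squared at or above the threshold (0.8 by default; a pair at
#' exactly the threshold is linked). Each connected component is one
#' independent signal. All SNPs are expected to lie on one chromosome.
#'
#' @param snpIds SNPs to cluster
#' @param ld r-squared matrix covering them (e.g. \code{\link{ldMatrix}})
#' @param threshold linkage threshold on r-squared (default 0.8)
#' @return list of character vectors, one per signal, ordered by the
#'   position of their first SNP in \code{snpIds}
#' @export
independentSignals <- function(snpIds, ld, threshold = 0.8) {
    if (!length(snpIds)) return(list())
    sub <- ld[snpIds, snpIds, drop = FALSE]
    adj <- !is.na(sub) & sub >= threshold
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    unname(split(snpIds, factor(comp, levels = unique(comp))))
}

#' Write pairwise LD in long format
#'
#' @param ld matrix from \code{\link{ldMatrix}}
#' @param path output path (tab-separated: snp_a, snp_b, r2)
#' @return the path, invisibly
#' @export
writeLdTable <- function(ld, path) {
    ids <- rownames(ld)
    idx <- which(upper.tri(ld), arr.ind = TRUE)
    tab <- data.frame(snp_a = ids[idx[, 1]], snp_b = ids[idx[, 2]],
                      r2 = ld[idx])
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
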