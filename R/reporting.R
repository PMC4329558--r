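#' Bonferroni-corrected significance threshold
#'
#' The exact quotient fwer / family_size. The family for SNP-level
#' correction counts distinct SNPs (a SNP mapped to two overlapping genes
#' counts once); the gene-level family counts analyzed genes.
#'
#' @param familySize number of tests in the family (>= 1)
#' @param fwer family-wise error rate (default 0.05)
#' @return the threshold (exact; use \code{\link{formatThreshold}} for the
#'   3-significant-figure display form)
#' @export
bonferroniThreshold <- function(familySize, fwer = 0.05) {
    if (length(familySize) != 1 || is.na(familySize) || familySize < 1 ||
        familySize != round(familySize))
        stop("familySize must be a positive integer")
    fwer / familySize
}

#' Display form of a threshold
#'
#' Scientific notation at 3 significant figures (round-half-even, R's
#' default), e.g. 0.05/1421 prints as "3.52e-05".
#'
#' @param x numeric value(s)
#' @return character vector
#' @export
formatThreshold <- function(x) {
    sprintf("%.2e", signif(x, 3))
}

#' Label association and ARTP results for significance
#'
#' Applies the three significance conventions: nominal (< 0.05) for gene-
#' and pathway-level p-values, a reporting cut (< 0.001) for SNP-level
#' p-values, and the Bonferroni threshold for each family. All comparisons
#' are strict.
#'
#' @param snpResults data.frame from \code{\link{snpAssociation}}
#' @param geneResults named list of \linkS4class{ArtpResult} from
#'   \code{\link{artpGeneP}}
#' @param snpFamilySize,geneFamilySize Bonferroni family sizes
#' @param fwer family-wise error rate (default 0.05)
#' @param nominal gene/pathway significance level (default 0.05)
#' @param snpReportCut SNP-level reporting threshold (default 0.001)
#' @return list with labelled \code{snps} and \code{genes} data.frames and
#'   the \code{thresholds} used
#' @export
labelSignificance <- function(snpResults, geneResults,
                              snpFamilySize = nrow(snpResults),
                              geneFamilySize = length(geneResults),
                              fwer = 0.05, nominal = 0.05,
                              snpReportCut = 0.001) {
    snpThr <- bonferroniThreshold(snpFamilySize, fwer)
    geneThr <- bonferroniThreshold(geneFamilySize, fwer)
    snps <- snpResults
    snps$sig_report <- !is.na(snps$p) & snps$p < snpReportCut
    snps$sig_bonferroni <- !is.na(snps$p) & snps$p < snpThr
    genes <- data.frame(
        gene = vapply(geneResults, function(r) r@unitName, ""),
        p = vapply(geneResults, pAdjusted, 0),
        n_snps = vapply(geneResults, function(r) r@nItems, 0L),
        stringsAsFactors = FALSE, row.names = NULL)
    genes$sig_nominal <- genes$p < nominal
    genes$sig_bonferroni <- genes$p < geneThr
    list(snps = snps, genes = genes,
         thresholds = list(snp_bonferroni = snpThr,
                           gene_bonferroni = geneThr,
                           nominal = nominal,
                           snp_report = snpReportCut))
}

#' Gene summary table
#'
#' One row per gene with gene-level adjusted p below the cut (default
#' 0.05), sorted by p ascending, each with its SNP count and its most
#' significant SNP with that SNP's association p-value — the shape of a
#' per-cancer gene results table.
#'
#' @param geneResults named list of \linkS4class{ArtpResult}
#' @param snpResults data.frame from \code{\link{snpAssociation}}
#' @param map a \linkS4class{GeneSnpMap}
#' @param cut report genes with p below this (default 0.05; \code{Inf} for
#'   all)
#' @return data.frame: gene, gene_p, n_snps, top_snp, top_snp_p
#' @export
geneSummaryTable <- function(geneResults, snpResults, map, cut = 0.05) {
    g2s <- geneToSnps(map)
    rows <- lapply(geneResults, function(r) {
        snps <- g2s[[r@unitName]]
        sub <- snpResults[snpResults$snp_id %in% snps & !is.na(snpResults$p), ]
        top <- if (nrow(sub)) sub[which.min(sub$p), ] else
            data.frame(snp_id = NA_character_, p = NA_real_)
        data.frame(gene = r@unitName, gene_p = pAdjusted(r),
                   n_snps = r@nItems, top_snp = top$snp_id,
                   top_snp_p = top$p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tab <- tab[!is.na(tab$gene_p) & tab$gene_p < cut, , drop = FALSE]
    tab[order(tab$gene_p), , drop = FALSE]
}

#' Pathway summary row
#'
#' @param name configuration/cohort label
#' @param pathwayResult \linkS4class{ArtpResult} for the pathway
#' @param nGenes,nSnps analyzed gene and distinct SNP counts
#' @param covariates character description of the adjustment factors
#' @return one-row data.frame
#' @export
pathwaySummaryRow <- function(name, pathwayResult, nGenes, nSnps,
                              covariates = "") {
    data.frame(config = name, n_genes = nGenes, n_snps = nSnps,
               adjustment = covariates, pathway_p = pAdjusted(pathwayResult),
               stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' @param path output path
#' @param ... named scalar entries (seed, counts, thresholds, ...)
#' @return the path, invisibly
#' @export
writeRunManifest <- function(path, ...) {
    jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(path)
}
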