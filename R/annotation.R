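#' Flanked gene window
#'
#' Expands each gene interval by an asymmetric flank: 20 kb upstream and
#' 10 kb downstream by default, with "upstream" measured against the
#' transcription direction. On the + strand the window is
#' [start - upstream, end + downstream]; on the - strand it is
#' [start - downstream, end + upstream]. With \code{strandAware = FALSE}
#' every gene is treated as + strand (upstream flank on the left), for
#' compatibility with strand-agnostic pipelines. Ends are inclusive and the
#' lower bound is clipped at 1.
#'
#' @param genes \code{GRanges} of gene bodies (names = gene names)
#' @param upstream,downstream flank sizes in bp (defaults 20000 / 10000)
#' @param strandAware logical; measure flanks along transcription direction
#' @return \code{GRanges} of windows, same names and order as \code{genes}
#' @export
geneWindow <- function(genes, upstream = 20000, downstream = 10000,
                       strandAware = TRUE) {
    minus <- strandAware & as.character(strand(genes)) == "-"
    left <- ifelse(minus, downstream, upstream)
    right <- ifelse(minus, upstream, downstream)
    win <- GRanges(seqnames = seqnames(genes),
                   ranges = IRanges(pmax(1, start(genes) - left),
                                    end(genes) + right),
                   strand = strand(genes))
    names(win) <- names(genes)
    win
}

#' Map SNPs to genes through flanking windows
#'
#' A SNP is assigned to a gene when it lies on the same chromosome and its
#' position falls inside the gene's flanked window (inclusive ends). A SNP
#' inside two overlapping windows is assigned to both genes — the double
#' counting the overlap rule implies; genes that receive no SNPs stay in the
#' map and are flagged.
#'
#' @param x a QC-filtered \linkS4class{GenotypeDataset}
#' @param genes \code{GRanges} from \code{\link{readGeneTable}}
#' @inheritParams geneWindow
#' @return a \linkS4class{GeneSnpMap}
#' @export
mapSnpsToGenes <- function(x, genes, upstream = 20000, downstream = 10000,
                           strandAware = TRUE) {
    win <- geneWindow(genes, upstream, downstream, strandAware)
    si <- snpInfo(x)
    snpGr <- GRanges(seqnames = si$chromosome,
                     ranges = IRanges(si$position, si$position))
    names(snpGr) <- si$snp_id
    hits <- findOverlaps(snpGr, win, ignore.strand = TRUE)
    g2s <- rep(list(character()), length(genes))
    names(g2s) <- names(genes)
    s2g <- split(names(win)[S4Vectors::subjectHits(hits)],
                 names(snpGr)[S4Vectors::queryHits(hits)])
    byGene <- split(names(snpGr)[S4Vectors::queryHits(hits)],
                    names(win)[S4Vectors::subjectHits(hits)])
    # keep per-gene SNPs ordered by genomic position
    pos <- setNames(si$position, si$snp_id)
    byGene <- lapply(byGene, function(s) s[order(pos[s])])
    g2s[names(byGene)] <- byGene
    new("GeneSnpMap", geneToSnps = g2s, snpToGenes = as.list(s2g),
        emptyGenes = names(g2s)[lengths(g2s) == 0], windows = win)
}

#' Remove named genes from a pathway
#'
#' Used, e.g., to drop X-chromosome genes from an autosomal analysis.
#' Excluding a gene that is not in the pathway leaves the pathway unchanged
#' and raises a warning.
#'
#' @param pathway character vector of gene names
#' @param exclude character vector of gene names to remove
#' @return the reduced pathway (order preserved)
#' @export
excludeGenes <- function(pathway, exclude) {
    absent <- setdiff(exclude, pathway)
    if (length(absent))
        warning("excluded gene(s) not in pathway: ",
                paste(absent, collapse = ", "))
    pathway[!pathway %in% exclude]
}

#' Drop genes with no mapped SNPs from a pathway
#'
#' Genes whose flanked windows captured no QC-passing SNPs cannot
#' contribute to gene- or pathway-level tests and are removed from the
#' analysis pathway (and reported).
#'
#' @param map a \linkS4class{GeneSnpMap}
#' @param pathway character vector of gene names
#' @return the reduced pathway, with the dropped genes in attribute
#'   \code{dropped}; a zero-length result means every gene was empty
#' @export
dropSnplessGenes <- function(map, pathway) {
    counts <- lengths(geneToSnps(map))[pathway]
    counts[is.na(counts)] <- 0L
    dropped <- pathway[counts == 0L]
    out <- pathway[counts > 0L]
    if (length(dropped))
        message("gene(s) without mapped SNPs dropped from pathway: ",
                paste(dropped, collapse = ", "))
    attr(out, "dropped") <- dropped
    out
}

#' Write a gene-to-SNP map
#'
#' @param map a \linkS4class{GeneSnpMap}
#' @param path output path (two-column tab-separated: gene, snp)
#' @return the path, invisibly
#' @export
writeGeneSnpMap <- function(map, path) {
    g2s <- geneToSnps(map)
    tab <- data.frame(gene = rep(names(g2s), lengths(g2s)),
                      snp = unlist(g2s, use.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
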