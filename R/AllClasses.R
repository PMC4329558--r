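#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<- rowData<-
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom IRanges IRanges
NULL

#' Case-control genotype dataset
#'
#' A \linkS4class{SummarizedExperiment} holding a minor-allele dosage matrix
#' (SNPs in rows, samples in columns; values 0, 1, 2 or \code{NA} for a
#' missing call) together with per-SNP metadata (\code{rowData}: chromosome,
#' 1-based position, minor and major allele) and per-sample metadata
#' (\code{colData}: case/control status, study, sex, age stratum, and any
#' extra numeric covariates such as principal components).
#'
#' Dosages always count the minor allele, defined over cases and controls
#' combined: after construction through \code{\link{GenotypeDataset}} or any
#' reader, each SNP's dosage-implied allele frequency is at most 0.5 (ties at
#' exactly 0.5 are left in their input orientation).
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("GenotypeDataset", contains = "SummarizedExperiment")

.validGenotypeDataset <- function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        ok <- is.na(d) | d == 0 | d == 1 | d == 2
        if (!all(ok))
            msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "SNP identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    rd <- rowData(object)
    need <- c("chromosome", "position", "allele_minor", "allele_major")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (all(c("allele_minor", "allele_major") %in% colnames(rd)) &&
        nrow(rd) > 0 && any(rd$allele_minor == rd$allele_major))
        msg <- c(msg, "minor and major allele must differ")
    if ("position" %in% colnames(rd) && nrow(rd) > 0 &&
        any(rd$position < 1))
        msg <- c(msg, "positions are 1-based and must be >= 1")
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeDataset", .validGenotypeDataset)

#' Construct a GenotypeDataset
#'
#' @param dosages numeric matrix, SNPs x samples, entries in
#'   \{0, 1, 2, NA\}. Dosages are re-oriented to count the minor allele
#'   (allele labels swapped and dosage reflected as \code{2 - d}) wherever
#'   the implied allele frequency exceeds 0.5.
#' @param snps \code{DataFrame}/\code{data.frame} with columns
#'   \code{snp_id}, \code{chromosome}, \code{position}, \code{allele_minor},
#'   \code{allele_major}.
#' @param samples \code{DataFrame}/\code{data.frame} with column
#'   \code{sample_id} and optionally \code{status} (factor with levels
#'   \code{control}, \code{case}), \code{study}, \code{sex},
#'   \code{age_stratum} and numeric covariate columns.
#' @return a \linkS4class{GenotypeDataset}
#' @export
GenotypeDataset <- function(dosages, snps, samples) {
    dosages <- as.matrix(dosages)
    mode(dosages) <- "double"
    snps <- as(snps, "DataFrame")
    samples <- as(samples, "DataFrame")
    stopifnot(nrow(dosages) == nrow(snps), ncol(dosages) == nrow(samples))
    rownames(dosages) <- as.character(snps$snp_id)
    colnames(dosages) <- as.character(samples$sample_id)
    ori <- .orientMinor(dosages, snps)
    se <- SummarizedExperiment(assays = list(dosage = ori$dosages),
                               rowData = ori$snps, colData = samples)
    new("GenotypeDataset", se)
}

# Flip dosage orientation so the counted allele is the minor one
# (frequency <= 0.5 over all samples; exact ties left untouched).
.orientMinor <- function(dosages, snps) {
    f <- rowMeans(dosages, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    if (any(flip)) {
        dosages[flip, ] <- 2 - dosages[flip, ]
        tmp <- snps$allele_minor[flip]
        snps$allele_minor[flip] <- snps$allele_major[flip]
        snps$allele_major[flip] <- tmp
    }
    list(dosages = dosages, snps = snps)
}

#' Quality-control report
#'
#' Per-SNP and per-sample statistics with pass/fail flags, the primary
#' removal reason for every excluded item, and retained/removed counts after
#' each filtering step (sample completion, then SNP call rate, minor allele
#' frequency and Hardy-Weinberg equilibrium in controls).
#'
#' @slot snpStats per-SNP \code{DataFrame}: call rate, MAF, HWE p, flag,
#'   reason.
#' @slot sampleStats per-sample \code{DataFrame}: completion rate, flag,
#'   reason.
#' @slot counts named list of retained/removed tallies per step.
#' @slot thresholds the \code{QcThresholds} used.
#' @export
setClass("QcReport",
         representation(snpStats = "DataFrame", sampleStats = "DataFrame",
                        counts = "list", thresholds = "list"))

#' Gene-to-SNP assignment map
#'
#' Records which QC-passing SNPs fall inside each gene's flanking window and,
#' inversely, which genes each SNP maps to. A SNP lying in two genes'
#' overlapping windows appears under both (double counting); genes with no
#' assigned SNPs are retained in the map and flagged.
#'
#' @slot geneToSnps named list: per gene, character vector of snp_ids
#'   ordered by position.
#' @slot snpToGenes named list: per SNP, character vector of gene names.
#' @slot emptyGenes character vector of genes with zero mapped SNPs.
#' @slot windows \code{GRanges} of the flanked gene windows used.
#' @export
setClass("GeneSnpMap",
         representation(geneToSnps = "list", snpToGenes = "list",
                        emptyGenes = "character", windows = "GRanges"))

.validGeneSnpMap <- function(object) {
    msg <- character()
    if (!setequal(object@emptyGenes,
                  names(object@geneToSnps)[lengths(object@geneToSnps) == 0]))
        msg <- c(msg, "emptyGenes must list exactly the genes with no SNPs")
    if (length(msg)) msg else TRUE
}
setValidity("GeneSnpMap", .validGeneSnpMap)

#' Permutation ensemble of per-SNP p-values
#'
#' A (B+1) x n_snps matrix of score-test p-values: row 1 is computed under
#' the observed case/control labels, rows 2..B+1 under labels permuted
#' within study strata. All gene- and pathway-level ARTP quantities are
#' counting statistics over this shared ensemble.
#'
#' @slot pMatrix numeric matrix, (B+1) x n_snps, entries in (0, 1].
#' @slot B number of permutations.
#' @slot seed integer seed that generated the permutations.
#' @slot strata factor of stratum labels used for constrained shuffling.
#' @export
setClass("PermutationEnsemble",
         representation(pMatrix = "matrix", B = "integer", seed = "integer",
                        strata = "factor"))

.validPermutationEnsemble <- function(object) {
    msg <- character()
    if (nrow(object@pMatrix) != object@B + 1L)
        msg <- c(msg, "pMatrix must have B + 1 rows")
    p <- object@pMatrix
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        msg <- c(msg, "all p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
}
setValidity("PermutationEnsemble", .validPermutationEnsemble)

#' ARTP test result
#'
#' Result of an adaptive rank truncated product test for one unit (a gene or
#' a pathway): the permutation-adjusted p-value, the winning truncation
#' point, and the per-truncation estimated p-values for the observed data.
#'
#' @slot unitName gene or pathway name.
#' @slot level \code{"gene"} or \code{"pathway"}.
#' @slot pAdjusted adjusted p-value; always >= 1/(B+1).
#' @slot bestTruncation truncation point attaining the observed MinP.
#' @slot truncationSet candidate truncation points used.
#' @slot perTruncationP estimated p-value at each truncation point (observed
#'   row).
#' @slot nItems number of p-values combined (SNPs for a gene, genes for a
#'   pathway).
#' @slot B permutations used.
#' @export
setClass("ArtpResult",
         representation(unitName = "character", level = "character",
                        pAdjusted = "numeric", bestTruncation = "integer",
                        truncationSet = "integer", perTruncationP = "numeric",
                        nItems = "integer", B = "integer"))

.validArtpResult <- function(object) {
    msg <- character()
    if (length(object@pAdjusted) == 1 && !is.na(object@pAdjusted) &&
        object@pAdjusted < 1 / (object@B + 1) - 1e-12)
        msg <- c(msg, "adjusted p cannot lie below the permutation floor")
    if (length(object@bestTruncation) == 1 && !is.na(object@bestTruncation) &&
        !object@bestTruncation %in% object@truncationSet)
        msg <- c(msg, "bestTruncation must belong to the truncation set")
    if (length(msg)) msg else TRUE
}
setValidity("ArtpResult", .validArtpResult)

setMethod("show", "GenotypeDataset", function(object) {
    cat(sprintf("GenotypeDataset: %d SNPs x %d samples\n",
                nrow(object), ncol(object)))
    st <- colData(object)$status
    if (!is.null(st))
        cat(sprintf("  cases: %d  controls: %d\n",
                    sum(st == "case", na.rm = TRUE),
                    sum(st == "control", na.rm = TRUE)))
    d <- assay(object, "dosage")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
    invisible(NULL)
})

setMethod("show", "QcReport", function(object) {
    cat("QcReport\n")
    for (nm in names(object@counts)) {
        x <- object@counts[[nm]]
        cat(sprintf("  %-18s retained %d, removed %d\n",
                    nm, x["retained"], x["removed"]))
    }
    invisible(NULL)
})

setMethod("show", "GeneSnpMap", function(object) {
    cat(sprintf("GeneSnpMap: %d genes, %d SNP assignments (%d distinct SNPs)\n",
                length(object@geneToSnps), sum(lengths(object@geneToSnps)),
                length(object@snpToGenes)))
    if (length(object@emptyGenes))
        cat("  genes without SNPs:",
            paste(object@emptyGenes, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "PermutationEnsemble", function(object) {
    cat(sprintf("PermutationEnsemble: B = %d permutations, %d SNPs, seed %d\n",
                object@B, ncol(object@pMatrix), object@seed))
    invisible(NULL)
})

setMethod("show", "ArtpResult", function(object) {
    cat(sprintf("ArtpResult [%s] %s\n", object@level, object@unitName))
    cat(sprintf("  adjusted p = %.3g (B = %d, floor %.3g)\n",
                object@pAdjusted, object@B, 1 / (object@B + 1)))
    cat(sprintf("  items combined = %d, best truncation = %d\n",
                object@nItems, object@bestTruncation))
    invisible(NULL)
})
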