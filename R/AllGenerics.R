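#' Dosage matrix accessor
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @return numeric matrix of minor-allele dosages, SNPs x samples
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeDataset", function(x) assay(x, "dosage"))

#' SNP metadata accessor
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @return \code{DataFrame} of SNP metadata (one row per SNP)
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeDataset", function(x) rowData(x))

#' Sample metadata accessor
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @return \code{DataFrame} of sample metadata (one row per sample)
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "GenotypeDataset", function(x) colData(x))

#' Adjusted p-value accessor
#'
#' @param x an \linkS4class{ArtpResult}
#' @return the permutation-adjusted p-value
#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))

#' @rdname pAdjusted
#' @export
setMethod("pAdjusted", "ArtpResult", function(x) x@pAdjusted)

#' Per-gene SNP lists of a GeneSnpMap
#'
#' @param x a \linkS4class{GeneSnpMap}
#' @return named list mapping gene name to character vector of snp_ids
#' @export
setGeneric("geneToSnps", function(x) standardGeneric("geneToSnps"))

#' @rdname geneToSnps
#' @export
setMethod("geneToSnps", "GeneSnpMap", function(x) x@geneToSnps)

#' Per-SNP gene lists of a GeneSnpMap
#'
#' @param x a \linkS4class{GeneSnpMap}
#' @return named list mapping snp_id to character vector of gene names
#' @export
setGeneric("snpToGenes", function(x) standardGeneric("snpToGenes"))

#' @rdname snpToGenes
#' @export
setMethod("snpToGenes", "GeneSnpMap", function(x) x@snpToGenes)

#' Permutation p-value matrix accessor
#'
#' @param x a \linkS4class{PermutationEnsemble}
#' @return numeric (B+1) x n_snps matrix; row 1 is the observed labelling
#' @export
setGeneric("pMatrix", function(x) standardGeneric("pMatrix"))

#' @rdname pMatrix
#' @export
setMethod("pMatrix", "PermutationEnsemble", function(x) x@pMatrix)
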