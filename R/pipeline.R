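#' Run the full pathway analysis pipeline
#'
#' Orchestrates every stage in fixed order: read inputs, sample/SNP QC,
#' SNP-to-gene mapping, gene exclusions, principal components, per-SNP
#' logistic association, the shared permutation ensemble, gene- and
#' pathway-level ARTP, significance labelling and output tables, plus a
#' JSON run manifest. Identical config and seed give identical outputs.
#'
#' The config is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{genotypes}{either \code{list(geno=, snps=)} for the text
#'     dialect or \code{list(bed=, bim=, fam=)} / \code{list(prefix=)} for
#'     binary PLINK}
#'   \item{covariates}{covariate table path}
#'   \item{genes}{gene table path}
#'   \item{pathways}{GMT file path}
#'   \item{qc}{optional overrides for \code{\link{qcThresholds}}}
#'   \item{flanks}{optional \code{list(upstream=20000, downstream=10000,
#'     strandAware=TRUE)}}
#'   \item{covariateNames}{colData columns entering the design (default
#'     none)}
#'   \item{nPcs}{principal components to include (default 0)}
#'   \item{B}{permutations (default 20000)}
#'   \item{seed}{integer seed (default 1)}
#'   \item{strata}{stratification column for permutations (default
#'     "study" when present)}
#'   \item{geneTruncation, pathwayTruncation}{optional truncation sets}
#'   \item{excludeGenes}{genes removed from the pathway up front (e.g.
#'     X-chromosome genes)}
#'   \item{leaveOutGenes}{genes for a sensitivity rerun with all their
#'     SNPs removed}
#'   \item{excludeSamples}{precomputed sample exclusion list}
#' }
#'
#' @param config named list or path to a YAML config file
#' @param outDir output directory
#' @return invisibly, a list with the fitted objects (dataset, qc report,
#'   map, association table, ensemble, gene/pathway results, file paths)
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- function(name, default = NULL)
        if (!is.null(config[[name]])) config[[name]] else default

    ## 1. read
    gt <- config$genotypes
    ds <- if (!is.null(gt$prefix)) readPlink(gt$prefix)
          else if (!is.null(gt$bed)) readPlink(gt$bed, gt$bim, gt$fam)
          else readGenotypeTable(gt$geno, gt$snps)
    covs <- readCovariates(config$covariates)
    ds <- attachCovariates(ds, covs)
    genes <- readGeneTable(config$genes)
    pathways <- readGmt(config$pathways, genes = genes)
    pathwayName <- names(pathways)[1]
    pathway <- pathways[[1]]

    ## 2. qc
    th <- do.call(qcThresholds, cfg("qc", list()))
    qc <- applyQc(ds, th, excludeSamples = cfg("excludeSamples", character()))
    ds <- qc$dataset
    if (nrow(ds) == 0 || ncol(ds) == 0)
        stop("pipeline stage qc: no data left after filtering")
    writeQcReport(qc$report, outDir)

    ## 3. map SNPs to genes
    fl <- cfg("flanks", list())
    map <- mapSnpsToGenes(ds,
                          genes[names(genes) %in% pathway],
                          upstream = fl$upstream %||% 20000,
                          downstream = fl$downstream %||% 10000,
                          strandAware = fl$strandAware %||% TRUE)
    pathway <- excludeGenes(pathway, cfg("excludeGenes", character()))
    pathway <- dropSnplessGenes(map, pathway)
    if (!length(pathway)) stop("pipeline stage map: pathway has no genes left")
    writeGeneSnpMap(map, file.path(outDir, "gene_snp_map.tsv"))
    mappedSnps <- unique(unlist(geneToSnps(map)[pathway]))
    ds <- ds[rownames(ds) %in% mappedSnps, ]

    ## 4. covariates + PCs, association
    nPcs <- cfg("nPcs", 0L)
    pcs <- computePCs(ds, nPcs)
    covariateNames <- intersect(cfg("covariateNames", character()),
                                colnames(sampleInfo(ds)))
    design <- buildDesign(ds, covariateNames, pcs = pcs)
    assoc <- snpAssociation(ds, design)
    write.table(assoc, file.path(outDir, "association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## 5. permutation ensemble + ARTP
    B <- cfg("B", 20000L)
    seed <- cfg("seed", 1L)
    strata <- cfg("strata",
                  if ("study" %in% colnames(sampleInfo(ds))) "study"
                  else NULL)
    ensemble <- buildEnsemble(ds, design, B = B, seed = seed,
                              strata = strata)
    res <- artpPathwayP(ensemble, map, pathway,
                        geneTruncation = cfg("geneTruncation"),
                        pathwayTruncation = cfg("pathwayTruncation"),
                        pathwayName = pathwayName)
    loGenes <- cfg("leaveOutGenes", character())
    leaveOut <- if (length(loGenes))
        leaveGeneOut(ensemble, map, pathway, loGenes,
                     geneTruncation = cfg("geneTruncation"),
                     pathwayTruncation = cfg("pathwayTruncation"))
    else NULL

    ## 6. report
    labelled <- labelSignificance(assoc, res$genes,
                                  snpFamilySize = length(mappedSnps),
                                  geneFamilySize = length(res$genesUsed))
    geneTab <- geneSummaryTable(res$genes, assoc, map, cut = Inf)
    write.table(geneTab, file.path(outDir, "gene_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pathTab <- pathwaySummaryRow(pathwayName, res$pathway,
                                 nGenes = length(res$genesUsed),
                                 nSnps = length(mappedSnps),
                                 covariates = paste(
                                     c(covariateNames,
                                       if (nPcs > 0) sprintf("%d PCs", nPcs)),
                                     collapse = ", "))
    if (!is.null(leaveOut))
        pathTab <- rbind(pathTab, pathwaySummaryRow(
            paste0(pathwayName, " (excl. ",
                   paste(loGenes, collapse = ","), ")"),
            leaveOut$pathway, nGenes = length(leaveOut$genesUsed),
            nSnps = length(mappedSnps) - length(leaveOut$removedSnps),
            covariates = ""))
    write.table(pathTab, file.path(outDir, "pathway_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunManifest(file.path(outDir, "manifest.json"),
                     seed = seed, B = B,
                     n_samples = ncol(ds), n_snps = length(mappedSnps),
                     n_genes = length(res$genesUsed),
                     thresholds = labelled$thresholds,
                     qc_counts = qc$report@counts,
                     pathway_p = pAdjusted(res$pathway))
    invisible(list(dataset = ds, qcReport = qc$report, map = map,
                   pathway = pathway, association = assoc,
                   ensemble = ensemble, geneResults = res$genes,
                   pathwayResult = res$pathway, leaveOut = leaveOut,
                   labelled = labelled, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
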