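# Shared fixture builders. Everything is generated in code at test time.

# Minimal dataset from a dosage matrix (SNPs x samples).
tinyDataset <- function(d, status = NULL, chromosome = "1",
                        position = NULL, study = NULL) {
    if (is.null(rownames(d))) rownames(d) <- paste0("snp", seq_len(nrow(d)))
    if (is.null(position)) position <- seq(1000L, by = 1000L,
                                           length.out = nrow(d))
    snps <- data.frame(snp_id = rownames(d), chromosome = chromosome,
                       position = position, allele_minor = "A",
                       allele_major = "G")
    samples <- S4Vectors::DataFrame(
        sample_id = sprintf("s%03d", seq_len(ncol(d))))
    if (!is.null(status))
        samples$status <- factor(status, levels = c("control", "case"))
    if (!is.null(study)) samples$study <- factor(study)
    GenotypeDataset(d, snps, samples)
}

# One generated fixture suite per test session.
fixtureDir <- local({
    dir <- NULL
    function() {
        if (is.null(dir)) {
            dir <<- file.path(tempdir(), "pathARTP-fixtures")
            makeFixtureSuite(dir)
        }
        dir
    }
})

loadCohortFixture <- function(name) {
    d <- file.path(fixtureDir(), name)
    ds <- readGenotypeTable(file.path(d, "genotypes.tsv"),
                            file.path(d, "snps.tsv"))
    if (file.exists(file.path(d, "covariates.tsv")))
        ds <- attachCovariates(ds,
                               readCovariates(file.path(d, "covariates.tsv")))
    genes <- if (file.exists(file.path(d, "genes.tsv")))
        readGeneTable(file.path(d, "genes.tsv")) else NULL
    pathway <- if (file.exists(file.path(d, "pathway.gmt")))
        readGmt(file.path(d, "pathway.gmt"))[[1]] else NULL
    manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                    simplifyVector = TRUE)
    list(dataset = ds, genes = genes, pathway = pathway,
         manifest = manifest, dir = d)
}

# The 8-sample cohort with its exhaustive 70-relabeling ensemble.
perm8Setup <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            fx <- loadCohortFixture("perm8")
            map <- mapSnpsToGenes(fx$dataset, fx$genes)
            design <- buildDesign(fx$dataset)
            ens <- buildExhaustiveEnsemble(fx$dataset, design)
            cache <<- c(fx, list(map = map, design = design,
                                 ensemble = ens))
        }
        cache
    }
})
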