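#' Write the canonical small test fixtures
#'
#' Generates, deterministically, the plain-text fixtures the test-suite and
#' examples use: a QC-violation dataset in which exactly one sample and one
#' SNP fail each filter, an 8-sample cohort whose choose(8,4) = 70
#' case/control relabelings can be enumerated exhaustively, a gene table
#' with overlapping flanking windows, and a small null and planted-effect
#' simulated cohort. Every fixture directory carries a
#' \code{manifest.json} of its expected properties. Regeneration from the
#' same code yields byte-identical files.
#'
#' @param outDir output directory (created if needed)
#' @return named vector of fixture directories, invisibly
#' @export
makeFixtureSuite <- function(outDir) {
    dirs <- c(qc = file.path(outDir, "qc_violation"),
              perm8 = file.path(outDir, "perm8"),
              overlap = file.path(outDir, "overlap_windows"),
              null = file.path(outDir, "null_cohort"),
              planted = file.path(outDir, "planted_cohort"))
    for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
    .fixtureQc(dirs["qc"])
    .fixturePerm8(dirs["perm8"])
    .fixtureOverlap(dirs["overlap"])
    .fixtureCohort(dirs["null"], simConfig(
        nCases = 100L, nControls = 100L,
        blocks = rep(list(list(nSnps = 4L, mafRange = c(0.15, 0.4),
                               rho = 0.3)), 5),
        missingRate = 0.01, seed = 401L))
    .fixtureCohort(dirs["planted"], simConfig(
        nCases = 100L, nControls = 100L,
        blocks = rep(list(list(nSnps = 4L, mafRange = c(0.15, 0.4),
                               rho = 0.3)), 5),
        effectSnps = list(list(block = 1L, index = 1L, or = 2.0)),
        missingRate = 0.01, seed = 402L))
    invisible(dirs)
}

.writeManifest <- function(dir, ...) {
    jsonlite::write_json(list(...), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.writeCovariates <- function(dir, ids, status, study = NULL) {
    tab <- data.frame(sample_id = ids,
                      status = ifelse(status == "case", 2L, 1L))
    if (!is.null(study)) tab$study <- study
    write.table(tab, file.path(dir, "covariates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
}

# 80 samples (40 controls then 40 cases), 10 SNPs; engineered so that one
# sample fails completion (<0.94) and one SNP fails each of call rate,
# MAF and HWE-in-controls, while everything else passes.
.fixtureQc <- function(dir) {
    n <- 80L
    ids <- sprintf("S%03d", seq_len(n))
    status <- rep(c("control", "case"), each = 40L)
    fill <- rep(c(0, 1, 1, 0, 2, 0, 1, 0), 10)  # maf 0.3125, HWE-friendly
    d <- t(vapply(1:17, function(i) fill[((seq_len(n) + i - 2) %% n) + 1],
                  numeric(n)))
    rownames(d) <- paste0("snp_fill", 1:17)
    lowcall <- fill; lowcall[seq(5, by = 6, length.out = 12)] <- NA
    lowmaf <- rep(0, n); lowmaf[c(10, 30, 50)] <- 1      # maf 3/160
    hwe <- c(rep(1, 40), fill[41:80])                    # all-het controls
    d <- rbind(d, snp_lowcall = lowcall, snp_lowmaf = lowmaf, snp_hwe = hwe)
    # sample S041 (a case) misses 3 of 20 SNPs -> completion 0.85 < 0.94;
    # every other sample misses at most 1 of 20 (0.95, retained)
    d[1:2, 41] <- NA
    snps <- data.frame(snp_id = rownames(d), chromosome = "1",
                       position = seq(100000L, by = 5000L,
                                      length.out = nrow(d)),
                       allele_minor = "A", allele_major = "G")
    ds <- GenotypeDataset(d, snps, DataFrame(sample_id = ids))
    writeGenotypeTable(ds, file.path(dir, "genotypes.tsv"),
                       file.path(dir, "snps.tsv"))
    .writeCovariates(dir, ids, status)
    .writeManifest(dir,
        n_samples = n, n_snps = nrow(d),
        expected = list(samples_removed_completion = 1,
                        snps_removed_call_rate = 1,
                        snps_removed_maf = 1, snps_removed_hwe = 1,
                        samples_retained = n - 1,
                        snps_retained = nrow(d) - 3,
                        failing_sample = "S041",
                        failing_snps = c("snp_lowcall", "snp_lowmaf",
                                         "snp_hwe")))
}

# 8 samples (4 cases), 6 SNPs in 3 well-separated genes: the complete
# relabeling set has choose(8, 4) = 70 elements.
.fixturePerm8 <- function(dir) {
    ids <- paste0("P", 1:8)
    status <- rep(c("case", "control"), each = 4L)
    d <- rbind(gA_s1 = c(2, 1, 1, 0, 0, 1, 0, 0),
               gA_s2 = c(1, 2, 0, 1, 0, 0, 1, 0),
               gB_s1 = c(0, 1, 2, 1, 1, 0, 0, 1),
               gB_s2 = c(1, 0, 1, 2, 0, 1, 1, 0),
               gC_s1 = c(0, 0, 1, 1, 2, 1, 0, 1),
               gC_s2 = c(1, 1, 0, 0, 1, 2, 1, 0))
    pos <- c(101000L, 105000L, 301000L, 305000L, 501000L, 505000L)
    snps <- data.frame(snp_id = rownames(d), chromosome = "1",
                       position = pos, allele_minor = "A",
                       allele_major = "G")
    ds <- GenotypeDataset(d, snps, DataFrame(sample_id = ids))
    writeGenotypeTable(ds, file.path(dir, "genotypes.tsv"),
                       file.path(dir, "snps.tsv"))
    .writeCovariates(dir, ids, status)
    genes <- data.frame(gene_name = c("geneA", "geneB", "geneC"),
                        chromosome = "1", strand = "+",
                        start = c(100000L, 300000L, 500000L),
                        end = c(110000L, 310000L, 510000L))
    write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines("pathway1\ttest pathway\tgeneA\tgeneB\tgeneC",
               file.path(dir, "pathway.gmt"))
    .writeManifest(dir, n_samples = 8, n_cases = 4, n_snps = 6,
                   n_relabelings = 70, genes_per_pathway = 3,
                   snps_per_gene = 2)
}

# Two + strand genes whose default 20kb/10kb windows overlap in
# [120000, 130000]; one SNP sits in the overlap, one in each private
# window, one on another chromosome at an in-range coordinate.
.fixtureOverlap <- function(dir) {
    genes <- data.frame(gene_name = c("gLeft", "gRight"),
                        chromosome = "1", strand = "+",
                        start = c(100000L, 140000L),
                        end = c(120000L, 160000L))
    write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d <- rbind(snp_left = c(0, 1, 2, 1), snp_shared = c(1, 0, 1, 2),
               snp_right = c(2, 1, 0, 1), snp_otherchr = c(1, 1, 0, 2))
    snps <- data.frame(snp_id = rownames(d),
                       chromosome = c("1", "1", "1", "2"),
                       position = c(85000L, 125000L, 165000L, 125000L),
                       allele_minor = "A", allele_major = "G")
    ds <- GenotypeDataset(d, snps,
                          DataFrame(sample_id = paste0("O", 1:4)))
    writeGenotypeTable(ds, file.path(dir, "genotypes.tsv"),
                       file.path(dir, "snps.tsv"))
    .writeManifest(dir,
        expected = list(gLeft = c("snp_left", "snp_shared"),
                        gRight = c("snp_shared", "snp_right"),
                        unmapped = "snp_otherchr"))
}

.fixtureCohort <- function(dir, config) {
    sim <- simulateCohort(config)
    ds <- sim$dataset
    writeGenotypeTable(ds, file.path(dir, "genotypes.tsv"),
                       file.path(dir, "snps.tsv"))
    cd <- as.data.frame(sampleInfo(ds))
    tab <- data.frame(sample_id = cd$sample_id,
                      status = ifelse(cd$status == "case", 2L, 1L),
                      study = cd$study, sex = cd$sex,
                      age_stratum = cd$age_stratum)
    write.table(tab, file.path(dir, "covariates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    genes <- simGeneTable(config)
    gtab <- data.frame(gene_name = names(genes),
                       chromosome = as.character(seqnames(genes)),
                       strand = "+", start = start(genes),
                       end = end(genes))
    write.table(gtab, file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(paste(c("pathway1", "simulated pathway", names(genes)),
                     collapse = "\t"),
               file.path(dir, "pathway.gmt"))
    .writeManifest(dir, seed = config$seed, n_cases = config$nCases,
                   n_controls = config$nControls,
                   n_snps = nrow(ds), n_genes = length(genes),
                   effect_snps = if (length(sim$truth$effectSnps))
                       sim$truth$effectSnps else character())
}
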