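test_that("binary PLINK write->read round trips on random fixtures", {
    set.seed(11)
    for (rep in 1:3) {
        n <- sample(5:17, 1); m <- sample(3:9, 1)
        d <- matrix(sample(c(0, 1, 2, NA), n * m, replace = TRUE,
                           prob = c(0.45, 0.3, 0.2, 0.05)),
                    nrow = m)
        ds <- tinyDataset(d, status = sample(c("case", "control"), n,
                                             replace = TRUE))
        prefix <- tempfile()
        writePlink(ds, prefix)
        back <- readPlink(prefix)
        expect_identical(unname(dosages(back)), unname(dosages(ds)))
        expect_identical(rownames(back), rownames(ds))
        expect_identical(colnames(back), colnames(ds))
        expect_identical(as.character(sampleInfo(back)$status),
                         as.character(sampleInfo(ds)$status))
    }
})

test_that("a missing call survives the bed codec", {
    d <- rbind(snpA = c(0, 1, NA), snpB = c(2, 1, 0))
    ds <- tinyDataset(d, status = c("case", "control", "control"))
    prefix <- tempfile()
    writePlink(ds, prefix)
    back <- readPlink(prefix)
    expect_identical(sum(is.na(dosages(back))), 1L)
    expect_true(is.na(dosages(back)["snpA", 3]))
})

test_that("dosages are re-oriented to the minor allele on load", {
    # counted-allele frequency 0.7 -> flip so reported MAF is 0.3
    d <- matrix(c(2, 2, 2, 1, 1, 2, 0, 2, 1, 1), nrow = 1)
    snps <- data.frame(snp_id = "s1", chromosome = "1", position = 100,
                       allele_minor = "A", allele_major = "G")
    ds <- GenotypeDataset(d, snps,
                          S4Vectors::DataFrame(sample_id = paste0("i", 1:10)))
    expect_equal(minorAlleleFrequency(dosages(ds)[1, ]), 0.3)
    expect_identical(snpInfo(ds)$allele_minor, "G")  # labels swapped
    expect_identical(snpInfo(ds)$allele_major, "A")
})

test_that("every loaded SNP has dosage-implied frequency at most 0.5", {
    set.seed(12)
    d <- matrix(sample(0:2, 200, replace = TRUE, prob = c(0.1, 0.3, 0.6)),
                nrow = 10)
    ds <- tinyDataset(d)
    f <- rowMeans(dosages(ds)) / 2
    expect_true(all(f <= 0.5))
})

test_that("the text genotype dialect round trips", {
    set.seed(13)
    d <- matrix(sample(c(0:2, NA), 40, replace = TRUE), nrow = 5)
    ds <- tinyDataset(d)
    g <- tempfile(); s <- tempfile()
    writeGenotypeTable(ds, g, s)
    back <- readGenotypeTable(g, s)
    expect_equal(unname(dosages(back)), unname(dosages(ds)))
    expect_identical(rownames(back), rownames(ds))
})

test_that("covariate reading maps PLINK status codes and rejects bad input", {
    path <- tempfile()
    writeLines(c("sample_id\tstatus\tstudy",
                 "s1\t1\tA", "s2\t2\tA", "s3\t2\tB"), path)
    cov <- readCovariates(path)
    expect_identical(as.character(cov$status), c("control", "case", "case"))

    dup <- tempfile()
    writeLines(c("sample_id\tstatus", "s1\t1", "s1\t2"), dup)
    expect_error(readCovariates(dup), "duplicated")

    nostatus <- tempfile()
    writeLines(c("sample_id\tsex", "s1\tM"), nostatus)
    expect_error(readCovariates(nostatus), "status")
})

test_that("samples without covariates are reported and excluded", {
    d <- matrix(sample(0:2, 12, replace = TRUE), nrow = 3)
    ds <- tinyDataset(d)  # samples s001..s004
    path <- tempfile()
    writeLines(c("sample_id\tstatus",
                 "s001\t1", "s002\t2", "s003\t1", "ghost\t2"), path)
    cov <- readCovariates(path)
    expect_warning(out <- attachCovariates(ds, cov), "s004")
    expect_identical(colnames(out), c("s001", "s002", "s003"))
    um <- S4Vectors::metadata(out)$unmatched
    expect_identical(um$genotyped_without_covariates, "s004")
    expect_identical(um$covariates_without_genotypes, "ghost")
})

test_that("gene table validates coordinates", {
    path <- tempfile()
    writeLines(c("gene_name\tchromosome\tstrand\tstart\tend",
                 "g1\t1\t+\t100\t50"), path)
    expect_error(readGeneTable(path), "start > end")
})

test_that("GMT parsing: size, empty sets, unresolved genes", {
    path <- tempfile()
    genes76 <- paste0("G", sprintf("%02d", 1:76))
    writeLines(paste(c("big_pathway", "desc", genes76), collapse = "\t"),
               path)
    pw <- readGmt(path)
    expect_length(pw$big_pathway, 76)

    bad <- tempfile()
    writeLines("empty_pathway\tdesc", bad)
    expect_error(readGmt(bad), "genes")

    gtab <- tempfile()
    writeLines(c("gene_name\tchromosome\tstrand\tstart\tend",
                 paste0(genes76[1:75], "\t1\t+\t1\t10", collapse = "\n")),
               gtab)
    genes <- readGeneTable(gtab)
    expect_warning(pw2 <- readGmt(path, genes = genes), "G76")
    expect_identical(attr(pw2, "missing")$big_pathway, "G76")
})
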