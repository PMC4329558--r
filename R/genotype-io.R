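#' @importFrom utils read.table write.table
NULL

# 2-bit PLINK bed codes (within-byte, least significant pair first):
# 00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
# Dosage below counts copies of A1 (bim column 5); minor-allele
# re-orientation happens in the GenotypeDataset constructor.
.bedDecodeTable <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            code2dose <- c(2, NA, 1, 0)
            m <- matrix(NA_real_, 256L, 4L)
            for (b in 0:255)
                for (k in 0:3)
                    m[b + 1L, k + 1L] <-
                        code2dose[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
            tab <<- m
        }
        tab
    }
})

.doseEncodeByte <- function(d4) {
    # d4: 4 dosages (A1 counts, NA = missing) -> one byte
    code <- ifelse(is.na(d4), 1L, c(0L, 2L, 3L)[3L - d4])
    sum(code * 4L^(0:3))
}

#' Read a binary PLINK fileset
#'
#' Reads a SNP-major \code{.bed}/\code{.bim}/\code{.fam} triplet into a
#' \linkS4class{GenotypeDataset}. Coordinates are 1-based inclusive (the bim
#' convention). Dosages are re-oriented to count the minor allele, with
#' minor/major determined from allele frequency over all samples (cases and
#' controls combined); missing calls become \code{NA}. The fam phenotype
#' column is mapped 1 = control, 2 = case (0/-9 = missing status).
#'
#' @param bed path to the .bed file, or a fileset prefix if \code{bim} and
#'   \code{fam} are omitted.
#' @param bim,fam paths to the .bim and .fam files.
#' @return a \linkS4class{GenotypeDataset}
#' @export
readPlink <- function(bed, bim = NULL, fam = NULL) {
    if (is.null(bim) && is.null(fam)) {
        prefix <- sub("\\.bed$", "", bed)
        bed <- paste0(prefix, ".bed")
        bim <- paste0(prefix, ".bim")
        fam <- paste0(prefix, ".fam")
    }
    for (f in c(bed, bim, fam))
        if (!file.exists(f)) stop("file not found: ", f)
    bimTab <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chromosome", "snp_id", "cm",
                                       "position", "a1", "a2"))
    famTab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("fid", "sample_id", "pat", "mat",
                                       "sex", "phenotype"))
    raw <- readBin(bed, "raw", n = file.size(bed))
    if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("not a PLINK bed file (bad magic number)")
    if (raw[3] != as.raw(0x01))
        stop("only SNP-major bed files are supported")
    n <- nrow(famTab); m <- nrow(bimTab)
    bytesPerSnp <- ceiling(n / 4)
    if (length(raw) - 3L != bytesPerSnp * m)
        stop("bed payload size does not match bim/fam dimensions")
    body <- as.integer(raw[-(1:3)])
    # decode all bytes to 4 dosages each, then trim padding per SNP
    dec <- .bedDecodeTable()[body + 1L, , drop = FALSE]
    full <- matrix(t(dec), nrow = 4L * bytesPerSnp, ncol = m)
    dosages <- t(full[seq_len(n), , drop = FALSE])  # m x n
    snps <- DataFrame(snp_id = bimTab$snp_id, chromosome = bimTab$chromosome,
                      position = bimTab$position,
                      allele_minor = bimTab$a1, allele_major = bimTab$a2)
    status <- factor(c("control", "case")[match(famTab$phenotype, c(1, 2))],
                     levels = c("control", "case"))
    samples <- DataFrame(sample_id = famTab$sample_id, status = status,
                         sex = as.character(famTab$sex))
    GenotypeDataset(dosages, snps, samples)
}

#' Write a binary PLINK fileset
#'
#' Inverse of \code{\link{readPlink}}: writes \code{prefix.bed} (SNP-major),
#' \code{prefix.bim} and \code{prefix.fam}. Dosages are written as counts of
#' the bim A1 allele (the minor allele).
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @param prefix output fileset prefix
#' @return the prefix, invisibly
#' @export
writePlink <- function(x, prefix) {
    d <- dosages(x); si <- snpInfo(x); sa <- sampleInfo(x)
    n <- ncol(d); m <- nrow(d)
    bim <- data.frame(si$chromosome, si$snp_id, 0L, si$position,
                      si$allele_minor, si$allele_major)
    write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    pheno <- rep(-9L, n)
    if (!is.null(sa$status))
        pheno <- ifelse(is.na(sa$status), -9L,
                        ifelse(sa$status == "case", 2L, 1L))
    sex <- if (is.null(sa$sex)) rep(0L, n) else sa$sex
    fam <- data.frame(sa$sample_id, sa$sample_id, 0L, 0L, sex, pheno)
    write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    bytesPerSnp <- ceiling(n / 4)
    pad <- bytesPerSnp * 4L - n
    bytes <- apply(d, 1L, function(row) {
        r <- c(row, rep(0, pad))
        vapply(seq_len(bytesPerSnp),
               function(i) .doseEncodeByte(r[(4L * i - 3L):(4L * i)]), 0)
    })
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(bytes)), con)
    invisible(prefix)
}

#' Read/write the plain-text genotype dialect
#'
#' A human-readable alternative to binary PLINK for small fixtures: a
#' tab-separated samples x SNPs table (first column \code{sample_id}, one
#' column per SNP with values 0/1/2/NA) accompanied by a SNP metadata table
#' (\code{snp_id}, \code{chromosome}, \code{position}, \code{allele_minor},
#' \code{allele_major}). Orientation to the minor allele is applied on read
#' exactly as for binary PLINK.
#'
#' @param genoPath path to the dosage table
#' @param snpPath path to the SNP metadata table
#' @return a \linkS4class{GenotypeDataset}
#' @export
readGenotypeTable <- function(genoPath, snpPath) {
    g <- read.table(genoPath, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
    s <- read.table(snpPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    need <- c("snp_id", "chromosome", "position",
              "allele_minor", "allele_major")
    if (!all(need %in% colnames(s)))
        stop("SNP table must have columns: ", paste(need, collapse = ", "))
    ids <- g[[1]]
    d <- t(as.matrix(g[, -1, drop = FALSE]))
    if (!identical(rownames(d), as.character(s$snp_id)))
        d <- d[match(s$snp_id, rownames(d)), , drop = FALSE]
    if (anyNA(rownames(d)))
        stop("genotype table columns do not match the SNP table")
    GenotypeDataset(d, s, DataFrame(sample_id = ids))
}

#' @rdname readGenotypeTable
#' @param x a \linkS4class{GenotypeDataset}
#' @export
writeGenotypeTable <- function(x, genoPath, snpPath) {
    d <- t(dosages(x))
    g <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    write.table(g, genoPath, sep = "\t", quote = FALSE, row.names = FALSE)
    si <- as.data.frame(snpInfo(x))
    write.table(si[, c("snp_id", "chromosome", "position",
                       "allele_minor", "allele_major")],
                snpPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(genoPath)
}

#' Read a sample covariate table
#'
#' Tab-separated with a header; requires \code{sample_id} and \code{status}.
#' Status accepts the PLINK numeric convention (1 = control, 2 = case) or
#' the literal strings \code{control}/\code{case}. Optional columns
#' \code{study}, \code{sex}, \code{age_stratum} are kept as factors; any
#' further numeric columns are carried along as extra covariates.
#'
#' @param path covariate table path
#' @return a \code{DataFrame}, one row per sample
#' @export
readCovariates <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(tab))
        stop("covariate table must contain a sample_id column")
    if (!"status" %in% colnames(tab))
        stop("covariate table must contain a status column")
    if (anyDuplicated(tab$sample_id))
        stop("duplicated sample_id in covariate table: ",
             paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                   collapse = ", "))
    st <- tab$status
    status <- rep(NA_character_, length(st))
    status[st %in% c("1", 1)] <- "control"
    status[st %in% c("2", 2)] <- "case"
    status[st %in% c("control", "case")] <- st[st %in% c("control", "case")]
    if (anyNA(status))
        stop("status must be 1/2 (PLINK convention) or control/case")
    out <- DataFrame(sample_id = as.character(tab$sample_id),
                     status = factor(status, levels = c("control", "case")))
    for (col in c("study", "sex", "age_stratum"))
        if (col %in% colnames(tab)) out[[col]] <- factor(tab[[col]])
    extra <- setdiff(colnames(tab), c("sample_id", "status", "study",
                                      "sex", "age_stratum"))
    for (col in extra) out[[col]] <- tab[[col]]
    out
}

#' Attach covariates to a genotype dataset
#'
#' Matches covariate rows to samples by \code{sample_id}. Samples without a
#' covariate record are dropped from the returned dataset and listed (with a
#' warning); covariate rows without a genotyped sample are likewise
#' reported.
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @param covariates a \code{DataFrame} from \code{\link{readCovariates}}
#' @return a \linkS4class{GenotypeDataset} with populated \code{colData};
#'   unmatched ids are recorded in
#'   \code{metadata(x)$unmatched}
#' @export
attachCovariates <- function(x, covariates) {
    ids <- colnames(x)
    idx <- match(ids, covariates$sample_id)
    dropped <- ids[is.na(idx)]
    extraCov <- setdiff(covariates$sample_id, ids)
    if (length(dropped))
        warning(length(dropped),
                " genotyped sample(s) lack covariates and were dropped: ",
                paste(dropped, collapse = ", "))
    keep <- !is.na(idx)
    out <- x[, keep]
    cd <- covariates[idx[keep], , drop = FALSE]
    rownames(cd) <- cd$sample_id
    colData(out) <- cd
    metadata(out)$unmatched <- list(genotyped_without_covariates = dropped,
                                    covariates_without_genotypes = extraCov)
    out
}

#' Read a gene definition table
#'
#' Tab-separated with header columns \code{gene_name}, \code{chromosome},
#' \code{strand} (+/-), \code{start}, \code{end}; coordinates 1-based
#' inclusive.
#'
#' @param path gene table path
#' @return a \code{GRanges} with names set to gene names
#' @export
readGeneTable <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("gene_name", "chromosome", "strand", "start", "end")
    if (!all(need %in% colnames(tab)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    if (any(tab$start > tab$end))
        stop("gene table has start > end for: ",
             paste(tab$gene_name[tab$start > tab$end], collapse = ", "))
    gr <- GRanges(seqnames = tab$chromosome,
                  ranges = IRanges(tab$start, tab$end),
                  strand = tab$strand)
    names(gr) <- tab$gene_name
    gr
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one tab-separated line per pathway — name, description,
#' then gene names. An empty gene set is an error; duplicate genes within a
#' set are collapsed with a warning.
#'
#' @param path GMT file path
#' @param genes optional \code{GRanges} from \code{\link{readGeneTable}};
#'   when given, pathway genes missing from the table are reported with a
#'   warning and kept in the \code{missing} attribute.
#' @return named list of character vectors (one per pathway)
#' @export
readGmt <- function(path, genes = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("GMT line with no genes: ", parts[1])
        gset <- parts[-(1:2)]
        gset <- gset[nzchar(gset)]
        if (!length(gset)) stop("empty gene set: ", parts[1])
        if (anyDuplicated(gset)) {
            warning("duplicate genes collapsed in pathway ", parts[1])
            gset <- unique(gset)
        }
        out[[parts[1]]] <- gset
    }
    if (!is.null(genes)) {
        missing <- lapply(out, function(g) setdiff(g, names(genes)))
        bad <- vapply(missing, length, 0L) > 0
        if (any(bad))
            warning("pathway gene(s) absent from the gene table: ",
                    paste(unlist(missing[bad]), collapse = ", "))
        attr(out, "missing") <- missing
    }
    out
}
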