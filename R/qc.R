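#' Quality-control thresholds
#'
#' All four filters are strict inequalities: a SNP is removed when its call
#' rate is below \code{snpCallRateMin}, its minor allele frequency (cases
#' and controls combined) is below \code{mafMin}, or its exact
#' Hardy-Weinberg p-value in controls is below \code{hwePMin}; a sample is
#' removed when its completion rate is below \code{sampleCompletionMin}.
#' Values sitting exactly on a threshold are retained.
#'
#' @param snpCallRateMin minimum SNP call rate (default 0.90)
#' @param mafMin minimum minor allele frequency (default 0.05)
#' @param hwePMin minimum HWE exact p in controls (default 1e-4)
#' @param sampleCompletionMin minimum per-sample completion rate
#'   (default 0.94)
#' @return a named list of thresholds
#' @export
qcThresholds <- function(snpCallRateMin = 0.90, mafMin = 0.05,
                         hwePMin = 1e-4, sampleCompletionMin = 0.94) {
    th <- list(snpCallRateMin = snpCallRateMin, mafMin = mafMin,
               hwePMin = hwePMin, sampleCompletionMin = sampleCompletionMin)
    bad <- vapply(th, function(v)
        !is.null(v) && (!is.numeric(v) || v < 0 || v > 1), TRUE)
    if (any(bad))
        stop("thresholds must be proportions in [0, 1] (or NULL to disable)")
    th
}

#' Per-SNP call rate
#'
#' @param dosage numeric vector of dosages for one SNP (NA = missing call)
#' @return proportion of non-missing calls
#' @export
snpCallRate <- function(dosage) {
    if (!length(dosage)) stop("empty dosage vector")
    mean(!is.na(dosage))
}

#' Minor allele frequency
#'
#' Computed over all non-missing calls (cases and controls combined) as
#' min(f, 1 - f) with f = sum(dosage) / (2 * n called). With dosages already
#' oriented to the minor allele this equals f itself, but the fold is kept
#' so the statistic is orientation-proof.
#'
#' @param dosage numeric vector of dosages for one SNP
#' @return the minor allele frequency
#' @export
minorAlleleFrequency <- function(dosage) {
    called <- dosage[!is.na(dosage)]
    if (!length(called))
        stop("minor allele frequency undefined: all calls missing")
    f <- sum(called) / (2 * length(called))
    min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the conditional probabilities of every heterozygote count
#' that is no more probable than the observed one. The conditional
#' distribution of the heterozygote count h given n genotypes and nA copies
#' of the minor allele is P(h) = n! nA! nB! 2^h / ( (2n)! nAA! h! nBB! ),
#' evaluated in log space.
#'
#' @param nHomMajor,nHet,nHomMinor genotype counts (computed among controls
#'   in the QC context)
#' @return two-sided exact p-value
#' @export
hweExactTest <- function(nHomMajor, nHet, nHomMinor) {
    if (any(c(nHomMajor, nHet, nHomMinor) < 0))
        stop("genotype counts must be non-negative")
    n <- nHomMajor + nHet + nHomMinor
    if (n == 0) stop("HWE test undefined: zero genotyped individuals")
    nA <- 2 * nHomMinor + nHet   # minor allele copies
    nB <- 2 * nHomMajor + nHet
    hs <- seq(nA %% 2, min(nA, nB), by = 2)
    logp <- lfactorial(n) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n) +
        hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
        lfactorial((nB - hs) / 2)
    probs <- exp(logp - max(logp))
    probs <- probs / sum(probs)
    pObs <- probs[match(nHet, hs)]
    # tolerance guards ties against floating-point noise
    min(1, sum(probs[probs <= pObs * (1 + 1e-9)]))
}

.genotypeCounts <- function(dosage) {
    c(nHomMajor = sum(dosage == 0, na.rm = TRUE),
      nHet = sum(dosage == 1, na.rm = TRUE),
      nHomMinor = sum(dosage == 2, na.rm = TRUE))
}

#' Apply quality-control filters
#'
#' Filters are applied in a fixed order: (1) sample completion rate; then,
#' on the retained samples only, per-SNP (2) call rate, (3) minor allele
#' frequency over cases and controls combined, (4) exact Hardy-Weinberg
#' p-value among controls. Each removed item records the first filter it
#' failed as its primary reason. Samples on a precomputed exclusion list
#' (e.g. gender-discordant subjects or unexpected duplicates identified
#' upstream) are removed before anything is computed.
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @param thresholds from \code{\link{qcThresholds}}; set an entry to
#'   \code{NULL} to disable that filter
#' @param excludeSamples character vector of sample_ids to drop up front
#' @return list with elements \code{dataset} (the filtered
#'   \linkS4class{GenotypeDataset}) and \code{report} (a
#'   \linkS4class{QcReport})
#' @export
applyQc <- function(x, thresholds = qcThresholds(),
                    excludeSamples = character()) {
    nSamples0 <- ncol(x); nSnps0 <- nrow(x)
    pre <- x[, !(colnames(x) %in% excludeSamples)]

    d <- dosages(pre)
    completion <- colMeans(!is.na(d))
    th <- thresholds
    sampleFail <- if (is.null(th$sampleCompletionMin)) rep(FALSE, ncol(pre))
                  else completion < th$sampleCompletionMin
    sampleStats <- DataFrame(sample_id = colnames(pre),
                             completion = completion,
                             pass = !sampleFail,
                             reason = ifelse(sampleFail, "completion", ""))
    kept <- pre[, !sampleFail]
    d <- dosages(kept)
    if (ncol(kept) == 0) {
        report <- .qcReport(sampleStats, .emptySnpStats(rownames(x)),
                            nSamples0, nSnps0,
                            length(intersect(excludeSamples, colnames(x))),
                            sum(sampleFail), 0L, 0L, 0L, th)
        return(list(dataset = kept, report = report))
    }

    callRate <- rowMeans(!is.na(d))
    maf <- apply(d, 1L, function(v)
        if (all(is.na(v))) NA_real_ else minorAlleleFrequency(v))
    status <- sampleInfo(kept)$status
    isControl <- !is.null(status) & status == "control"
    if (!any(isControl, na.rm = TRUE) && !is.null(th$hwePMin))
        stop("HWE filtering requires at least one control sample")
    hweP <- rep(NA_real_, nrow(kept))
    if (!is.null(th$hwePMin)) {
        dc <- d[, which(isControl), drop = FALSE]
        hweP <- apply(dc, 1L, function(v) {
            cnt <- .genotypeCounts(v)
            if (sum(cnt) == 0) NA_real_
            else hweExactTest(cnt[1], cnt[2], cnt[3])
        })
    }

    failCall <- if (is.null(th$snpCallRateMin)) rep(FALSE, nrow(kept))
                else callRate < th$snpCallRateMin
    failMaf <- if (is.null(th$mafMin)) rep(FALSE, nrow(kept))
               else is.na(maf) | maf < th$mafMin
    failHwe <- if (is.null(th$hwePMin)) rep(FALSE, nrow(kept))
               else !is.na(hweP) & hweP < th$hwePMin
    reason <- rep("", nrow(kept))
    reason[failHwe] <- "hwe"
    reason[failMaf] <- "maf"          # earlier filters take precedence
    reason[failCall] <- "call_rate"
    pass <- reason == ""
    snpStats <- DataFrame(snp_id = rownames(kept), call_rate = callRate,
                          maf = maf, hwe_p = hweP, pass = pass,
                          reason = reason)

    out <- kept[pass, ]
    if (nrow(out) == 0)
        message("QC removed every SNP; returning an empty dataset")
    report <- .qcReport(sampleStats, snpStats, nSamples0, nSnps0,
                        length(intersect(excludeSamples, colnames(x))),
                        sum(sampleFail),
                        sum(failCall), sum(failMaf & !failCall),
                        sum(failHwe & !failMaf & !failCall), th)
    list(dataset = out, report = report)
}

.emptySnpStats <- function(ids) {
    DataFrame(snp_id = ids, call_rate = NA_real_, maf = NA_real_,
              hwe_p = NA_real_, pass = FALSE, reason = "no_samples")
}

.qcReport <- function(sampleStats, snpStats, nSamples0, nSnps0,
                      nExcluded, nCompletion, nCall, nMaf, nHwe, th) {
    counts <- list(
        sample_exclusion_list = c(retained = nSamples0 - nExcluded,
                                  removed = nExcluded),
        sample_completion = c(retained = nSamples0 - nExcluded - nCompletion,
                              removed = nCompletion),
        snp_call_rate = c(retained = nSnps0 - nCall, removed = nCall),
        snp_maf = c(retained = nSnps0 - nCall - nMaf, removed = nMaf),
        snp_hwe = c(retained = nSnps0 - nCall - nMaf - nHwe, removed = nHwe))
    new("QcReport", snpStats = snpStats, sampleStats = sampleStats,
        counts = counts, thresholds = th)
}

#' Write a QC report
#'
#' Emits the per-SNP and per-sample statistics as tab-separated tables and
#' the step counts plus thresholds as a JSON summary.
#'
#' @param report a \linkS4class{QcReport}
#' @param dir output directory (created if needed)
#' @return paths of the written files, invisibly
#' @export
writeQcReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    snpPath <- file.path(dir, "qc_snps.tsv")
    samplePath <- file.path(dir, "qc_samples.tsv")
    jsonPath <- file.path(dir, "qc_summary.json")
    write.table(as.data.frame(report@snpStats), snpPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report@sampleStats), samplePath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counts = report@counts,
                              thresholds = report@thresholds),
                         jsonPath, auto_unbox = TRUE, null = "null",
                         digits = NA)
    invisible(c(snpPath, samplePath, jsonPath))
}
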