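#' @importFrom stats glm.fit binomial pchisq pnorm model.matrix as.formula
#'   complete.cases setNames cor
NULL

.Z95 <- 1.959964  # normal quantile for the 95% Wald interval

#' Principal components of standardized genotypes
#'
#' Computes the top-k principal components of the samples in genotype
#' space for use as stratification covariates. Each SNP g is standardized
#' as (g - 2f) / sqrt(2f(1 - f)) with f its allele frequency; missing
#' dosages are mean-imputed before standardization. The returned columns
#' are the unit-norm eigenvectors of the sample-by-sample covariance of the
#' standardized genotypes, ordered by decreasing eigenvalue. Monomorphic
#' SNPs (f = 0) are skipped. Iterative outlier removal and LD pruning, as
#' some stratification pipelines add, are not performed.
#'
#' @param x a \linkS4class{GenotypeDataset} (QC-passed)
#' @param k number of components; \code{k = 0} yields a zero-column matrix
#' @return numeric matrix, n_samples x k, rownames = sample ids
#' @export
computePCs <- function(x, k) {
    n <- ncol(x)
    if (k < 0 || k != round(k)) stop("k must be a non-negative integer")
    if (k >= n) stop("k must be smaller than the number of samples")
    if (k == 0)
        return(matrix(0, nrow = n, ncol = 0,
                      dimnames = list(colnames(x), NULL)))
    d <- dosages(x)
    f <- rowMeans(d, na.rm = TRUE) / 2
    keep <- !is.na(f) & f > 0 & f < 1
    d <- d[keep, , drop = FALSE]; f <- f[keep]
    imp <- d
    na <- is.na(imp)
    if (any(na)) imp[na] <- (2 * f[row(imp)])[na]
    z <- (imp - 2 * f) / sqrt(2 * f * (1 - f))
    sv <- svd(t(z), nu = k, nv = 0)
    pcs <- sv$u[, seq_len(k), drop = FALSE]
    rownames(pcs) <- colnames(x)
    colnames(pcs) <- paste0("PC", seq_len(k))
    pcs
}

#' Build a covariate design matrix
#'
#' Assembles the intercept + covariate design used by the per-SNP logistic
#' fits and by the permutation score test. Categorical covariates (study,
#' sex, age stratum) get reference-level indicator encoding; numeric
#' columns (e.g. principal components) enter as-is. The result must be of
#' full column rank, otherwise an error is raised.
#'
#' @param x a \linkS4class{GenotypeDataset} with populated \code{colData}
#' @param covariates character vector of \code{colData} column names
#' @param pcs optional matrix from \code{\link{computePCs}} (rows matched
#'   to samples by name)
#' @return list with \code{matrix} (n x p design, first column intercept)
#'   and \code{status} (0/1 outcome, 1 = case)
#' @export
buildDesign <- function(x, covariates = character(), pcs = NULL) {
    cd <- as.data.frame(sampleInfo(x))
    miss <- setdiff(covariates, colnames(cd))
    if (length(miss))
        stop("covariate(s) not in sample metadata: ",
             paste(miss, collapse = ", "))
    if (is.null(cd$status) || !all(levels(factor(cd$status)) %in%
                                   c("control", "case")))
        stop("sample metadata must carry a control/case status column")
    y <- as.integer(cd$status == "case")
    if (length(covariates)) {
        form <- as.formula(paste("~", paste(covariates, collapse = " + ")))
        X <- model.matrix(form, data = cd)
    } else {
        X <- matrix(1, nrow = nrow(cd), ncol = 1,
                    dimnames = list(NULL, "(Intercept)"))
    }
    if (!is.null(pcs) && ncol(pcs) > 0) {
        idx <- match(colnames(x), rownames(pcs))
        if (anyNA(idx)) stop("pcs rows do not cover all samples")
        X <- cbind(X, pcs[idx, , drop = FALSE])
    }
    if (qr(X)$rank < ncol(X))
        stop("design matrix is rank deficient after encoding")
    rownames(X) <- colnames(x)
    list(matrix = X, status = y)
}

#' Per-SNP additive logistic regression
#'
#' Unconditional logistic regression of case/control status on the
#' minor-allele dosage (additive coding 0/1/2) plus covariates, on complete
#' cases. Reports the per-minor-allele log-odds (beta), its standard error,
#' the odds ratio with 95% Wald confidence interval (z = 1.959964), the
#' two-sided Wald p-value and the complete-case count. Degenerate inputs do
#' not raise: a constant dosage yields status \code{"monomorphic"}, an
#' outcome class absent from the complete cases yields
#' \code{"one_class"}, and non-convergence or separation yields
#' \code{"unstable"}, each with NA estimates where undefined.
#'
#' @param dosage numeric dosage vector for one SNP
#' @param design from \code{\link{buildDesign}}
#' @param snpId identifier carried into the result
#' @return one-row \code{data.frame}: snp_id, beta, se, or_, ci_low,
#'   ci_high, p, n_used, status
#' @export
fitSnpLogistic <- function(dosage, design, snpId = "snp") {
    X <- design$matrix; y <- design$status
    cc <- !is.na(dosage) & complete.cases(X)
    g <- dosage[cc]; Xc <- cbind(X[cc, , drop = FALSE], dosage = g)
    yc <- y[cc]
    bad <- function(status) data.frame(
        snp_id = snpId, beta = NA_real_, se = NA_real_, or_ = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        n_used = sum(cc), status = status, stringsAsFactors = FALSE)
    if (length(unique(g)) < 2) return(bad("monomorphic"))
    if (length(unique(yc)) < 2) return(bad("one_class"))
    fit <- suppressWarnings(
        glm.fit(Xc, yc, family = binomial(),
                control = list(epsilon = 1e-10, maxit = 25)))
    beta <- fit$coefficients["dosage"]
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    cov <- tryCatch(solve(crossprod(Xc, Xc * w)),
                    error = function(e) NULL)
    if (is.null(cov)) return(bad("unstable"))
    se <- sqrt(cov[ncol(Xc), ncol(Xc)])
    if (!fit$converged || is.na(beta) || !is.finite(se) || se > 100 ||
        abs(beta) > 15)
        return(bad("unstable"))
    p <- 2 * pnorm(-abs(beta / se))
    data.frame(snp_id = snpId, beta = unname(beta), se = se,
               or_ = exp(unname(beta)),
               ci_low = exp(unname(beta) - .Z95 * se),
               ci_high = exp(unname(beta) + .Z95 * se),
               p = max(p, .Machine$double.xmin), n_used = sum(cc),
               status = "ok", stringsAsFactors = FALSE)
}

#' Association scan over all SNPs
#'
#' Runs \code{\link{fitSnpLogistic}} for every SNP in the dataset.
#'
#' @param x a \linkS4class{GenotypeDataset}
#' @inheritParams fitSnpLogistic
#' @return \code{data.frame}, one row per SNP, with chromosome and position
#'   merged in
#' @export
snpAssociation <- function(x, design) {
    d <- dosages(x)
    rows <- lapply(seq_len(nrow(d)), function(i)
        fitSnpLogistic(d[i, ], design, snpId = rownames(d)[i]))
    out <- do.call(rbind, rows)
    si <- as.data.frame(snpInfo(x))
    cbind(out[, "snp_id", drop = FALSE],
          si[match(out$snp_id, si$snp_id), c("chromosome", "position")],
          out[, setdiff(colnames(out), "snp_id")],
          row.names = NULL)
}

# Mean-impute missing dosages, SNP-wise (rows).
.imputeDosages <- function(d) {
    na <- is.na(d)
    if (any(na)) {
        mu <- rowMeans(d, na.rm = TRUE)
        d[na] <- mu[row(d)][na]
    }
    d
}

#' Rao score test p-values for many SNPs at once
#'
#' The fast path used inside the permutation ensemble: the covariate-only
#' null logistic model is fitted once for a given outcome vector, then each
#' SNP's score statistic U^2/V is formed with U = g~' (y - mu) and V the
#' efficient score variance, where g~ is the dosage residualized against
#' the covariates under the null weights mu(1 - mu). Missing dosages are
#' mean-imputed. P-values come from the chi-square distribution with 1 df;
#' a SNP orthogonal to the residuals scores 0 and reports p = 1. Agreement
#' with the Wald fit is asymptotic and is what makes a shared permutation
#' ensemble affordable.
#'
#' @param G numeric matrix n_samples x n_snps of dosages (may contain NA)
#' @param y 0/1 outcome vector
#' @param X covariate design matrix (with intercept)
#' @return named vector of p-values in (0, 1]
#' @export
scoreTestPvalues <- function(G, y, X) {
    G <- t(.imputeDosages(t(G)))   # impute per SNP (columns of G)
    if (ncol(X) == 1L && all(X == X[1L])) {
        # intercept-only null: the MLE fitted value is the case fraction
        mu <- rep(mean(y), length(y))
    } else {
        fit <- suppressWarnings(
            glm.fit(X, y, family = binomial(),
                    control = list(epsilon = 1e-10, maxit = 25)))
        if (!fit$converged)
            stop("null model did not converge; cannot compute score tests")
        mu <- fit$fitted.values
    }
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    H <- solve(XtWX, crossprod(X, G * w))        # p x m
    Gt <- G - X %*% H                            # residualized dosages
    U <- as.vector(crossprod(Gt, y - mu))
    V <- colSums(Gt * Gt * w)
    stat <- ifelse(V > 1e-12, U^2 / V, 0)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    setNames(pmin(pmax(p, .Machine$double.xmin), 1), colnames(G))
}
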