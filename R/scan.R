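#' Residualize a trait on age and sex
#'
#' Optionally log-transforms the raw values, then returns the residuals of
#' an ordinary least-squares fit on intercept + age + sex. The residuals
#' are the trait `y` used by both regression scans.
#'
#' @param values raw trait values (strictly positive when `logTransform`).
#' @param age,sex covariate vectors of the same length.
#' @param logTransform log-transform before residualizing (default TRUE,
#'   as appropriate for blood-pressure measurements).
#' @return Residual vector (mean zero).
#' @export
residualizeTrait <- function(values, age, sex, logTransform = TRUE) {
  if (length(values) != length(age) || length(values) != length(sex))
    stop("values, age and sex must have equal length")
  if (logTransform) {
    if (any(values <= 0)) stop("log transform requires positive values")
    values <- log(values)
  }
  as.numeric(residuals(lm(values ~ age + sex)))
}

.SCAN_TOL <- 1e-10

#' Admixture-mapping scan: trait on local-ancestry deviation
#'
#' For each SNP j fits, by ordinary least squares,
#' `y_i = b0 + b1 * Sbar_i + b2 * (S_ij - Sbar_i) + e_i`,
#' where `S_ij` is the dosage of the chosen ancestry at SNP j and `Sbar_i`
#' its unweighted mean across all scanned SNPs, and tests `b2 = 0` with a
#' t-statistic on n - 3 degrees of freedom. SNPs whose deviation regressor
#' is (numerically) constant are flagged and assigned p = 1.
#' Benjamini-Hochberg FDR q-values and the scan's genomic-control lambda
#' are attached.
#'
#' @param y residual trait vector (see [residualizeTrait()]).
#' @param callset a [LocalAncestryCallset-class] covering the same
#'   individuals.
#' @param ancestry population label (or index) whose dosage is tested.
#' @return A [ScanResult-class] with model tag `"admixmap"`.
#' @export
admixtureScan <- function(y, callset, ancestry = "EUR") {
  n <- length(y)
  if (n < 4L) stop("need at least 4 individuals")
  if (nIndividuals(callset) != n)
    stop("call set must cover the same individuals as y")
  popIdx <- resolvePop(ancestry, callset@popLabels)
  S <- callset@dosage[, , popIdx, drop = FALSE]
  dim(S) <- dim(callset@dosage)[1:2]      # m x n
  m <- nrow(S)
  Sbar <- colMeans(S)
  Z <- cbind(1, Sbar)
  qz <- qr(Z)
  ytil <- qr.resid(qz, y)
  X <- t(S) - matrix(Sbar, n, m)          # deviation regressors, n x m
  Xtil <- qr.resid(qz, X)
  xx <- colSums(Xtil^2)
  xy <- as.numeric(crossprod(Xtil, ytil))
  flagged <- xx < .SCAN_TOL
  beta <- ifelse(flagged, NA_real_, xy / xx)
  df <- n - 3
  rss <- sum(ytil^2) - ifelse(flagged, 0, beta^2 * xx)
  sigma2 <- rss / df
  se <- ifelse(flagged, NA_real_, sqrt(sigma2 / xx))
  tstat <- ifelse(flagged, NA_real_, beta / se)
  p <- ifelse(flagged, 1, 2 * pt(-abs(tstat), df))
  p <- pmax(p, .Machine$double.xmin)      # keep p in (0, 1]
  makeScanResult(callset@map@snpId, beta, se, tstat, p, flagged,
                 model = "admixmap", n = n, df = df)
}

#' Ancestry-adjusted genotype association scan
#'
#' For each SNP j fits, by ordinary least squares,
#' `y_i = b * G_ij + sum_k b_k * alpha_ijk * q_jk + e_i`,
#' where `G_ij` is half the nonreference allele count, `alpha_ijk` the local
#' ancestry dosage and `q_jk` the ancestral nonreference allele frequency,
#' and tests `b = 0` with a t-statistic on `n - (K + 1)` degrees of freedom
#' (`n - K - 2` with an intercept). The model has no intercept by default,
#' exactly as specified; note the K ancestry regressors span a constant
#' column whenever all `q_jk` are nonzero and distinct, and `intercept =
#' TRUE` adds one explicitly. Collinear designs (e.g. G perfectly explained
#' by the ancestry regressors) are flagged and assigned p = 1.
#'
#' @param y residual trait vector.
#' @param geno SNP x individual genotype dosage matrix in \{0, 0.5, 1\}.
#' @param callset a [LocalAncestryCallset-class] on the same SNPs and
#'   individuals.
#' @param panelFreqs SNP x population matrix of ancestral allele
#'   frequencies (or an [AncestralPanel-class]).
#' @param intercept add an explicit intercept column (default FALSE).
#' @return A [ScanResult-class] with model tag `"assoc"`.
#' @export
ancestryAdjustedScan <- function(y, geno, callset, panelFreqs,
                                 intercept = FALSE) {
  if (is(panelFreqs, "AncestralPanel")) panelFreqs <- panelFreqs@freqs
  n <- length(y)
  m <- nrow(geno)
  K <- length(callset@popLabels)
  if (n < K + 2L) stop("too few individuals for the adjusted model")
  if (nIndividuals(callset) != n || ncol(geno) != n)
    stop("geno and call set must cover the same individuals as y")
  if (nSnps(callset) != m || nrow(panelFreqs) != m)
    stop("geno, call set and panel frequencies must cover the same SNPs")
  beta <- se <- tstat <- rep(NA_real_, m)
  p <- rep(1, m)
  flagged <- logical(m)
  ncolX <- K + 1L + intercept
  df <- n - ncolX
  for (j in seq_len(m)) {
    X <- cbind(geno[j, ], callset@dosage[j, , ] *
                 matrix(panelFreqs[j, ], n, K, byrow = TRUE))
    if (intercept) X <- cbind(X, 1)
    # the tested genotype column must be identifiable: if adding G to the
    # adjustment columns does not raise the rank, G lies in their span and
    # the SNP is flagged; redundant *adjustment* columns (e.g. ancestry
    # regressors spanning the intercept) are silently dropped instead
    qa <- qr(X[, -1L, drop = FALSE])
    qx <- qr(X)
    if (qx$rank == qa$rank) { flagged[j] <- TRUE; next }
    r <- qa$rank + 1L
    gpos <- 1L
    if (r < ncol(X)) {
      keepAdj <- 1L + sort(qa$pivot[seq_len(qa$rank)])
      qx <- qr(X[, c(1L, keepAdj), drop = FALSE])
    }
    dfj <- n - r
    cf <- qr.coef(qx, y)
    res <- qr.resid(qx, y)
    sigma2 <- sum(res^2) / dfj
    Ri <- backsolve(qr.R(qx), diag(r))
    V <- tcrossprod(Ri)[order(qx$pivot), order(qx$pivot)]
    beta[j] <- cf[gpos]
    se[j] <- sqrt(sigma2 * V[gpos, gpos])
    tstat[j] <- beta[j] / se[j]
    p[j] <- max(2 * pt(-abs(tstat[j]), dfj), .Machine$double.xmin)
  }
  makeScanResult(callset@map@snpId, beta, se, tstat, p, flagged,
                 model = "assoc", n = n, df = df)
}

makeScanResult <- function(snpId, beta, se, tstat, p, flagged, model, n, df) {
  q <- bhFdr(p)
  tab <- data.frame(snp_id = snpId, beta = beta, se = se, t = tstat,
                    p = p, q = q, flag = flagged, stringsAsFactors = FALSE)
  lambda <- if (length(p) >= 10L) gcLambdaFromP(p, warn = FALSE) else NA_real_
  new("ScanResult", table = tab, model = model, lambda = lambda,
      n = as.numeric(n), df = as.numeric(df))
}

#' @rdname scanTable
#' @export
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @rdname gcLambda
#' @export
setMethod("gcLambda", "ScanResult", function(x) x@lambda)

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult [", object@model, "]: ", nrow(object@table), " SNPs, n = ",
      object@n, ", df = ", object@df, "\n", sep = "")
  cat(sprintf("  lambda = %.3f, #q < 0.05: %d, min p = %.3g\n",
              object@lambda, sum(object@table$q < 0.05, na.rm = TRUE),
              min(object@table$p)))
})

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), delegated to
#' [stats::p.adjust()] after validating the input.
#'
#' @param pvals p-values in (0, 1\].
#' @return q-values of the same length.
#' @export
bhFdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Genomic-control inflation factor
#'
#' Converts each two-sided p-value to a 1-df chi-square quantile and
#' returns the ratio of their median to the 1-df chi-square median
#' (0.4549...). Computing lambda from p-values (rather than squared
#' t-statistics) respects the t reference distribution at small n.
#'
#' @param x a [ScanResult-class] or a vector of at least 10 p-values.
#' @return lambda (1 under a calibrated null; 0, with a warning, when all
#'   p = 1).
#' @export
genomicControl <- function(x) {
  p <- if (is(x, "ScanResult")) x@table$p else x
  if (length(p) < 10L) stop("need at least 10 SNPs for genomic control")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  gcLambdaFromP(p, warn = TRUE)
}

gcLambdaFromP <- function(p, warn = TRUE) {
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lam <- median(chi) / qchisq(0.5, df = 1)
  if (lam == 0 && warn) warning("degenerate scan (all p = 1): lambda = 0")
  lam
}

#' Permutation test for an excess of large t-statistics
#'
#' The observed statistic is the number of SNPs whose t-statistic exceeds
#' `threshold` (`|t| > t*` by default; `signed = TRUE` counts `t > t*`,
#' matching a one-directional reading). The trait residuals are permuted
#' uniformly `B` times, the scan is rerun on each permuted trait, and the
#' add-one empirical p-value `(1 + #\{count_b >= observed\}) / (B + 1)` is
#' returned, so p is never zero.
#'
#' @param y residual trait vector.
#' @param scanFun function taking a trait vector and returning either a
#'   [ScanResult-class] or a numeric vector of t-statistics.
#' @param threshold t-statistic threshold t* (default 3).
#' @param B number of permutations (default 3000).
#' @param seed optional integer seed.
#' @param signed count signed exceedances t > t* instead of |t| > t*.
#' @return A [PermutationResult-class].
#' @export
permutationExcessTest <- function(y, scanFun, threshold = 3, B = 3000,
                                  seed = NULL, signed = FALSE) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  count1 <- function(t) {
    t <- t[!is.na(t)]
    if (signed) sum(t > threshold) else sum(abs(t) > threshold)
  }
  tvec <- function(yy) {
    r <- scanFun(yy)
    if (is(r, "ScanResult")) r@table$t else r
  }
  observed <- count1(tvec(y))
  counts <- vapply(seq_len(B),
                   function(b) count1(tvec(sample(y))), numeric(1))
  p <- (1 + sum(counts >= observed)) / (B + 1)
  new("PermutationResult", threshold = threshold, observed = observed,
      counts = counts, p = p, signed = signed)
}

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed", object@observed, "SNPs with",
      if (object@signed) "t >" else "|t| >", object@threshold, "\n")
  cat(sprintf("  B = %d permutations, empirical p = %.4g\n",
              length(object@counts), object@p))
})
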