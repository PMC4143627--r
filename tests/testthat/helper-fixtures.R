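# shared fixtures and independent oracles, built in code at test time

`%null%` <- function(a, b) if (is.null(a)) b else a

# brute-force OLS through the normal equations (independent of the scans'
# QR/Frisch-Waugh implementation)
olsOracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- unname(drop(solve(XtX, t(X) %*% y)))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * s2))
  list(beta = beta, se = se, t = beta / se, df = df)
}

# hand step-up BH implementation (oracle for bhFdr)
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

gridMap <- function(cm, bp = NULL, chrom = "chr3") {
  GeneticMap(paste0("s", seq_along(cm)), bp %null% (seq_along(cm) * 1000),
             cm, chrom)
}

hapPath <- function(breaks, labels, K = 3) {
  new("HaplotypePath", breakpointsCm = as.numeric(breaks),
      labels = as.integer(labels), K = as.integer(K))
}

# hard-called callset from two haploid label matrices (SNP x individual)
callsetFromLabels <- function(l1, l2, map, K = 3,
                              pops = c("EUR", "AFR", "NAM")[seq_len(K)]) {
  m <- nrow(l1); n <- ncol(l1)
  d <- array(0, c(m, n, K))
  for (k in seq_len(K)) d[, , k] <- (l1 == k) * 0.5 + (l2 == k) * 0.5
  LocalAncestryCallset(d, map, pops)
}

randCallset <- function(m, n, K = 3, seed = 1, map = NULL) {
  set.seed(seed)
  map <- map %null% gridMap(seq_len(m))
  l1 <- matrix(sample.int(K, m * n, TRUE), m, n)
  l2 <- matrix(sample.int(K, m * n, TRUE), m, n)
  callsetFromLabels(l1, l2, map, K)
}

# interior (uncensored) lengths in morgans of target-ancestry segments of
# one haplotype path, after binarizing to the target label
binarySegLengths <- function(path, target, mapStartCm, mapEndCm) {
  bounds <- c(mapStartCm, path@breakpointsCm, mapEndCm)
  lab <- as.integer(path@labels == target)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segStart <- bounds[starts]
  segEnd <- bounds[ends + 1L]
  keep <- r$values == 1L & starts > 1L & ends < length(lab)
  (segEnd[keep] - segStart[keep]) / 100
}
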