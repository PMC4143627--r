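test_that("trait residualization matches closed-form least squares", {
  # exact linear dependence on age: residuals vanish
  age <- c(30, 40, 50, 60, 70); sex <- c(0, 1, 0, 1, 0)
  r <- residualizeTrait(2 + 0.5 * age, age, sex, logTransform = FALSE)
  expect_lt(max(abs(r)), 1e-10)

  # 5-point toy against the normal equations
  v <- c(118, 135, 122, 140, 128)
  X <- cbind(1, age, sex)
  oracle <- log(v) - X %*% solve(t(X) %*% X, t(X) %*% log(v))
  expect_equal(residualizeTrait(v, age, sex), as.numeric(oracle),
               tolerance = 1e-10)
  expect_lt(abs(mean(residualizeTrait(v, age, sex))), 1e-10)

  expect_error(residualizeTrait(c(-1, v[-1]), age, sex), "positive")
  expect_error(residualizeTrait(v, age[-1], sex[-1]), "equal length")
})

test_that("admixture scan equals brute-force normal equations and honors its contracts", {
  # 6-individual, 2-SNP toy with a hand-computable design
  map <- gridMap(c(0, 1))
  l1 <- rbind(c(1L, 1L, 2L, 2L, 1L, 2L), c(1L, 2L, 1L, 2L, 2L, 1L))
  l2 <- rbind(c(1L, 2L, 2L, 1L, 1L, 2L), c(2L, 2L, 1L, 1L, 2L, 1L))
  cs <- callsetFromLabels(l1, l2, map, K = 2, pops = c("EUR", "AFR"))
  y <- c(0.3, -1.2, 0.8, 0.1, -0.5, 0.6)
  scan <- admixtureScan(y, cs, ancestry = "EUR")
  S <- ancestryDosage(cs)[, , 1]
  Sbar <- colMeans(S)
  for (j in 1:2) {
    o <- olsOracle(cbind(1, Sbar, S[j, ] - Sbar), y)
    expect_equal(scanTable(scan)$beta[j], o$beta[3], tolerance = 1e-8)
    expect_equal(scanTable(scan)$se[j], o$se[3], tolerance = 1e-8)
    expect_equal(scanTable(scan)$t[j], o$t[3], tolerance = 1e-8)
  }
  expect_equal(scan@df, 3)

  # perfect noiseless signal at one SNP dominates the scan
  cs2 <- randCallset(20, 50, seed = 51)
  S2 <- ancestryDosage(cs2)[, , 1]
  dev1 <- S2[1, ] - colMeans(S2)
  scan2 <- admixtureScan(2 * dev1, cs2, ancestry = "EUR")
  expect_lt(scanTable(scan2)$p[1], 1e-12)
  expect_equal(which.min(scanTable(scan2)$q), 1L)

  # a SNP with constant dosage is flagged with p = 1
  d <- ancestryDosage(cs2)
  d[2, , ] <- rep(c(1, 0, 0), each = 50)
  csc <- LocalAncestryCallset(d, cs2@map, popLabels(cs2))
  scan3 <- admixtureScan(rnorm(50), csc, ancestry = "EUR")
  expect_true(scanTable(scan3)$flag[2])
  expect_equal(scanTable(scan3)$p[2], 1)

  # permuting individuals in y and predictors together leaves t unchanged
  set.seed(5)
  pi <- sample(50)
  csPerm <- LocalAncestryCallset(ancestryDosage(cs2)[, pi, ], cs2@map,
                                 popLabels(cs2))
  y2 <- rnorm(50)
  expect_equal(scanTable(admixtureScan(y2[pi], csPerm))$t,
               scanTable(admixtureScan(y2, cs2))$t, tolerance = 1e-10)

  expect_error(admixtureScan(y[1:3], cs), "at least 4")
})

test_that("ancestry-adjusted scan equals brute-force least squares, handles degeneracies", {
  # 5-individual single-SNP toy, K = 2
  map <- gridMap(0)
  cs <- callsetFromLabels(matrix(c(1L, 1L, 2L, 2L, 1L), 1),
                          matrix(c(1L, 2L, 2L, 1L, 1L), 1),
                          map, K = 2, pops = c("EUR", "AFR"))
  geno <- matrix(c(0.5, 0, 1, 0.5, 0), 1)
  q <- matrix(c(0.8, 0.2), 1)
  y <- c(0.5, -0.3, 1.1, 0.2, -0.8)
  scan <- ancestryAdjustedScan(y, geno, cs, q)
  alpha <- ancestryDosage(cs)[1, , ]
  X <- cbind(geno[1, ], alpha[, 1] * q[1], alpha[, 2] * q[2])
  o <- olsOracle(X, y)
  expect_equal(scanTable(scan)$beta[1], o$beta[1], tolerance = 1e-8)
  expect_equal(scanTable(scan)$se[1], o$se[1], tolerance = 1e-8)
  expect_equal(scan@df, 2)

  # equal q across populations: the ancestry regressors span a constant
  # column, so an explicit intercept is redundant rather than fatal: the
  # intercept model drops the aliased column and reproduces the
  # no-intercept fit (and the brute-force oracle on the K + 1 columns)
  set.seed(6)
  n <- 40
  csr <- randCallset(1, n, K = 3, seed = 61, map = map)
  g1 <- matrix(sample(c(0, 0.5, 1), n, TRUE), 1)
  qeq <- matrix(0.4, 1, 3)
  y2 <- rnorm(n)
  scanI <- ancestryAdjustedScan(y2, g1, csr, qeq, intercept = TRUE)
  scanNI <- ancestryAdjustedScan(y2, g1, csr, qeq, intercept = FALSE)
  alphaR <- ancestryDosage(csr)[1, , ]
  oI <- olsOracle(cbind(g1[1, ], alphaR * 0.4), y2)
  expect_false(scanTable(scanI)$flag[1])
  expect_equal(scanTable(scanI)$beta[1], scanTable(scanNI)$beta[1],
               tolerance = 1e-10)
  expect_equal(scanTable(scanI)$beta[1], oI$beta[1], tolerance = 1e-8)
  expect_equal(scanTable(scanI)$se[1], oI$se[1], tolerance = 1e-8)

  # genotype perfectly explained by the ancestry regressors: flagged, p = 1
  alpha3 <- ancestryDosage(csr)[1, , ]
  gdep <- matrix(alpha3[, 1] * 0.4, 1)
  scanC <- ancestryAdjustedScan(y2, gdep, csr, qeq)
  expect_true(scanTable(scanC)$flag[1])
  expect_equal(scanTable(scanC)$p[1], 1)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(50)
    q <- bhFdr(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
  expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("genomic control is calibrated under the null and scales with inflation", {
  set.seed(8)
  p <- runif(10000)
  expect_equal(genomicControl(p), 1, tolerance = 0.05)

  # doubling every statistic quadruples the median chi-square
  z <- rnorm(20000)
  lam1 <- genomicControl(2 * pnorm(-abs(z)))
  lam2 <- genomicControl(2 * pnorm(-abs(2 * z)))
  expect_equal(lam2 / lam1, 4, tolerance = 0.05)

  expect_error(genomicControl(runif(5)), "at least 10")
  expect_warning(lam0 <- genomicControl(rep(1, 20)), "lambda = 0")
  expect_equal(lam0, 0)
})

test_that("permutation excess test: boundaries and power against a planted signal", {
  # observed count 0: every permutation count is >= 0, so p = 1
  y <- rnorm(30)
  res <- permutationExcessTest(y, function(yy) rep(0.1, 50), B = 19, seed = 1)
  expect_equal(res@observed, 0)
  expect_equal(res@p, 1)
  expect_error(permutationExcessTest(y, function(yy) yy, B = 0), "B must")

  # planted ancestry signal at 50 of 500 SNPs, n = 200
  cs <- randCallset(500, 200, seed = 71)
  S <- ancestryDosage(cs)[, , 1]
  dev <- sweep(S, 2, colMeans(S))  # SNP x individual deviations
  set.seed(72)
  ysig <- colSums(dev[1:50, , drop = FALSE] * 0.4) + rnorm(200, 0, 0.5)
  res2 <- permutationExcessTest(
    ysig, function(yy) admixtureScan(yy, cs, ancestry = "EUR"),
    threshold = 3, B = 199, seed = 73)
  expect_lte(res2@p, 0.01)
  expect_gt(res2@observed, 0)
})

test_that("admixture scan type-I error is nominal at small n", {
  pan <- drawAncestralFreqs(300, seed = 81)
  rej <- numeric(30)
  for (r in 1:30) {
    coh <- simulateCohort(pan, n = 50, seed = 810 + r,
                          trait = traitSpec(ageEffect = 0, sexEffect = 0,
                                            noiseSd = 1))
    ph <- phenotypes(coh)
    y <- residualizeTrait(ph$sbp, ph$age, ph$sex)
    rej[r] <- mean(scanTable(admixtureScan(y, trueAncestry(coh)))$p <= 0.05)
  }
  expect_equal(mean(rej), 0.05, tolerance = 0.02 / 0.05)
})
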