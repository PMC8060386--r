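test_that("Spearman correlation handles monotone, antitone and tied data", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearmanRho(1:3, c(10, 20, 30))$p, 0)
  expect_equal(spearmanRho(1:3, c(3, 2, 1))$rho, -1)
  r <- spearmanRho(1:4, c(2, 1, 4, 3))
  expect_equal(r$rho, oracleSpearmanNoTies(1:4, c(2, 1, 4, 3)))
  # t-approximation p agrees with its closed form
  tt <- r$rho * sqrt(2 / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), df = 2))
  # and with cor.test's rho estimate (ties averaged)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 6)
  expect_equal(spearmanRho(x, y)$rho,
               unname(suppressWarnings(
                 cor.test(x, y, method = "spearman")$estimate)))
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("bin-width selection maximizes |rho| with smallest-width ties", {
  ages <- c(61, 55, 70, 64, 75, 58)
  one <- list(`8` = rnorm(6))
  expect_equal(selectBinWidth(one, ages)$width, 8)
  # a width tracking the ages exactly wins with rho 1
  set.seed(2)
  vals <- list(`1` = rnorm(6), `16` = ages + 0, `64` = rnorm(6))
  pick <- selectBinWidth(vals, ages)
  expect_equal(pick$width, 16)
  expect_equal(pick$rho, 1)
  # all-constant features: zero correlation, smallest width returned
  cons <- list(`8` = rep(1, 6), `2` = rep(2, 6), `64` = rep(3, 6))
  pick2 <- selectBinWidth(cons, ages)
  expect_equal(pick2$width, 2)
  expect_equal(pick2$rho, 0)
})

test_that("rank statistics are invariant to monotone age transforms", {
  set.seed(8)
  ages <- runif(20, 55, 75)
  vals <- list(`1` = rnorm(20), `8` = rnorm(20) + 0.1 * ages,
               `64` = rnorm(20))
  a <- selectBinWidth(vals, ages)
  b <- selectBinWidth(vals, exp(ages / 10))
  expect_identical(a, b)
})

test_that("region PCA obeys the 90% rule and reconstructs its input", {
  # rank-1 structure: two perfectly correlated features
  subjects <- sprintf("s%02d", 1:10)
  ages <- setNames(seq(55, 75, length.out = 10), subjects)
  base <- rnorm(10)
  tbl <- rbind(
    data.frame(subject_id = subjects, region = 1L, feature_id = 1L,
               feature_name = "A", family = "TEST", bin_width = 1L,
               value = base),
    data.frame(subject_id = subjects, region = 1L, feature_id = 2L,
               feature_name = "B", family = "TEST", bin_width = 1L,
               value = 3 * base + 2))
  pca <- regionPca(tbl, 1L, ages)
  expect_identical(nIndependent(pca), 1L)
  expect_equal(explainedVariance(pca)[1], 1)

  # random features: full decomposition reproduces the z-scored matrix
  set.seed(19)
  nf <- 6
  tbl2 <- do.call(rbind, lapply(seq_len(nf), function(f)
    data.frame(subject_id = subjects, region = 2L, feature_id = f,
               feature_name = paste0("F", f), family = "TEST",
               bin_width = 1L, value = rnorm(10))))
  pca2 <- regionPca(tbl2, 2L, ages)
  z <- pcaScores(pca2) %*% t(pcaLoadings(pca2))
  x <- matrix(tbl2$value, nrow = 10)
  mu <- colMeans(x); s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zref <- sweep(sweep(x, 2, mu), 2, s, "/")
  dimnames(z) <- NULL
  expect_equal(z, zref, tolerance = 1e-8)
  ev <- explainedVariance(pca2)
  k <- nIndependent(pca2)
  expect_gte(sum(ev[1:k]), 0.90)
  if (k > 1) expect_lt(sum(ev[1:(k - 1)]), 0.90)
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(pcaLoadings(pca2)))) {
    cj <- pcaLoadings(pca2)[, j]
    expect_gt(cj[which.max(abs(cj))], 0)
  }
})

test_that("independent features need about 90% of the components", {
  subjects <- sprintf("s%03d", 1:400)
  ages <- setNames(runif(400, 55, 75), subjects)
  set.seed(33)
  nf <- 30
  tbl <- do.call(rbind, lapply(seq_len(nf), function(f)
    data.frame(subject_id = subjects, region = 1L, feature_id = f,
               feature_name = paste0("F", f), family = "TEST",
               bin_width = 1L, value = rnorm(400))))
  pca <- regionPca(tbl, 1L, ages)
  expect_gte(nIndependent(pca), 24)   # ~0.9 * 30 at large n
  expect_lte(nIndependent(pca), 29)
})

test_that("PCA results are invariant to feature order up to the sign rule", {
  subjects <- sprintf("s%02d", 1:12)
  ages <- setNames(runif(12, 55, 75), subjects)
  set.seed(44)
  tbl <- do.call(rbind, lapply(1:5, function(f)
    data.frame(subject_id = subjects, region = 1L, feature_id = f,
               feature_name = paste0("F", f), family = "TEST",
               bin_width = 1L, value = rnorm(12))))
  pca <- regionPca(tbl, 1L, ages)
  tblR <- tbl[rev(seq_len(nrow(tbl))), ]
  pcaR <- regionPca(tblR, 1L, ages)
  expect_equal(explainedVariance(pca), explainedVariance(pcaR))
  expect_equal(abs(unname(pcaScores(pca))), abs(unname(pcaScores(pcaR))),
               tolerance = 1e-8)
})

test_that("zero-variance features are dropped, not imputed", {
  subjects <- sprintf("s%02d", 1:8)
  ages <- setNames(runif(8, 55, 75), subjects)
  set.seed(55)
  tbl <- rbind(
    data.frame(subject_id = subjects, region = 1L, feature_id = 1L,
               feature_name = "Flat", family = "TEST", bin_width = 1L,
               value = 1.0),
    data.frame(subject_id = subjects, region = 1L, feature_id = 2L,
               feature_name = "Var", family = "TEST", bin_width = 1L,
               value = rnorm(8)))
  pca <- regionPca(tbl, 1L, ages)
  expect_identical(pca@dropped, "TEST_Flat")
  expect_identical(nrow(pcaLoadings(pca)), 1L)
})

test_that("component screening requires both the rho and p conditions", {
  subjects <- sprintf("s%02d", 1:10)
  ages <- setNames(seq(55, 75, length.out = 10), subjects)
  base <- as.numeric(scale(seq_len(10)))
  tbl <- rbind(
    data.frame(subject_id = subjects, region = 1L, feature_id = 1L,
               feature_name = "A", family = "TEST", bin_width = 1L,
               value = base),
    data.frame(subject_id = subjects, region = 1L, feature_id = 2L,
               feature_name = "B", family = "TEST", bin_width = 1L,
               value = -2 * base))
  pca <- regionPca(tbl, 1L, ages)
  sc <- screenComponents(pca, unname(ages))
  expect_identical(nrow(sc), 1L)
  expect_equal(abs(sc$rho), 1)
  expect_true(sc$significant)
  expect_identical(sc$component, 0L)

  # rho above threshold but p too large at tiny n: not significant
  pca5 <- pca
  pca5@scores <- pca@scores[1:5, , drop = FALSE]
  sc5 <- screenComponents(pca5, c(60, 57, 74, 66, 71))
  expect_true(abs(sc5$rho) > 0.5 || !sc5$significant)
  r <- spearmanRho(pca5@scores[, 1], c(60, 57, 74, 66, 71))
  if (abs(r$rho) > 0.5 && r$p >= 0.05) expect_false(sc5$significant)
})

test_that("null component scores are flagged at about the Bonferroni rate", {
  set.seed(77)
  n <- 43
  nInd <- 5
  hits <- 0L
  nsim <- 2000
  ages <- runif(n, 55, 75)
  for (i in seq_len(nsim)) {
    sc <- rnorm(n)
    sp <- spearmanRho(sc, ages)
    if (abs(sp$rho) > 0.5 && sp$p < 0.05 / nInd) hits <- hits + 1L
  }
  # detection requires |rho| > 0.5, far out in the null tail at n = 43:
  # the empirical rate must sit well below the nominal 0.05 / nInd
  expect_lt(hits / nsim, 0.05 / nInd)
})

test_that("the pooled t-test matches its closed form and degenerates safely", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r <- pooledTTest(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tref <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(r$t, tref)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(tref), 4))
  expect_equal(r$p, t.test(a, b, var.equal = TRUE)$p.value)

  same <- pooledTTest(c(1, 2), c(1, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  sep <- pooledTTest(c(0, 0, 0), c(1, 1, 1))
  expect_equal(sep$p, 0)
  expect_true(is.infinite(sep$t))
  expect_error(pooledTTest(1, c(1, 2)), "at least 2")

  w <- pooledTTest(a, c(2, 3, 9), welch = TRUE)
  expect_equal(w$p, t.test(a, c(2, 3, 9))$p.value)
})

test_that("the threshold-age scan finds a planted step and skips tiny groups", {
  set.seed(88)
  ages <- c(56:64, 66:75)           # no subject under 56
  scores <- ifelse(ages < 65, 2, 0) + rnorm(length(ages), 0, 0.2)
  scan <- thresholdAgeScan(scores, ages, nInd = 6)
  expect_identical(scan$A, 55:75)
  expect_true(is.na(scan$p[scan$A == 55]))       # empty early group
  expect_true(is.na(scan$p[scan$A == 56]))       # early group of size 1
  expect_true(scan$significant[scan$A == 65])
  expect_true(all(scan$p[!is.na(scan$p)] > 0 &
                  scan$p[!is.na(scan$p)] <= 1))

  # age-independent scores: usually nothing significant
  emptyRate <- mean(vapply(1:40, function(i) {
    sc <- rnorm(length(ages))
    any(thresholdAgeScan(sc, ages, nInd = 6)$significant)
  }, logical(1)))
  expect_lt(emptyRate, 0.4)
})
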