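# The compiled matrix builders against the plain-R brute-force oracles,
# plus the analytic conservation identities every family must satisfy.

test_that("all five matrix families match brute-force enumeration", {
  set.seed(101)
  for (i in 1:40) {
    arr <- randomLevelArray(maxDim = 5, nlev = 6)
    q <- qvoiFromArray(arr, binWidth = 32L)
    nl <- nLevels(q)
    expect_equal(matrixCounts(buildGlcm(q)), oracleGlcm(arr, nl))
    expect_equal(matrixCounts(buildGldm(q)), oracleGldm(arr, nl))
    glr <- matrixCounts(buildGlrlm(q))
    ref <- oracleGlrlm(arr, nl)
    expect_equal(glr, ref[, seq_len(ncol(glr)), drop = FALSE])
    expect_true(all(ref[, -seq_len(ncol(glr))] == 0))
    glsz <- matrixCounts(buildGlszm(q))
    expect_equal(glsz, oracleGlszm(arr, nl))
    ng <- buildNgtdm(q)
    ref <- oracleNgtdm(arr, nl)
    expect_equal(as.vector(matrixCounts(ng)), unname(ref[, 2]))
    expect_equal(ng@aux$n, unname(ref[, 1]))
  }
})

test_that("GLDM alpha widens the dependence criterion", {
  arr <- array(c(0L, 1L, 2L, 3L), dim = c(4, 1, 1))
  q <- qvoiFromArray(arr, binWidth = 64L)
  m0 <- matrixCounts(buildGldm(q, alpha = 0))
  m1 <- matrixCounts(buildGldm(q, alpha = 1))
  expect_equal(m0, oracleGldm(arr, 4, alpha = 0))
  expect_equal(m1, oracleGldm(arr, 4, alpha = 1))
  expect_gt(sum(m1[, -1]), sum(m0[, -1]))
})

test_that("conservation identities hold on random fixtures", {
  set.seed(202)
  for (i in 1:25) {
    arr <- randomLevelArray(maxDim = 6, nlev = 5)
    q <- qvoiFromArray(arr, binWidth = 32L)
    n <- nVoxels(q)
    glcm <- matrixCounts(buildGlcm(q))
    expect_identical(glcm, t(glcm))
    if (sum(glcm) > 0)
      expect_equal(sum(glcm / sum(glcm)), 1, tolerance = 1e-12)
    gldm <- matrixCounts(buildGldm(q))
    expect_equal(sum(gldm), n)
    glsz <- matrixCounts(buildGlszm(q))
    expect_equal(sum(sweep(glsz, 2, seq_len(ncol(glsz)), "*")), n)
    glr <- buildGlrlm(q)
    cnt <- matrixCounts(glr)
    expect_equal(sum(sweep(cnt, 2, seq_len(ncol(cnt)), "*")),
                 n * glr@aux$nDirections)
  }
})

test_that("zone connectivity is 26-connected (corner touch is one zone)", {
  arr <- array(NA_integer_, dim = c(4, 4, 4))
  # two 2x1x1 blobs of level 1 touching only at a voxel corner
  arr[2, 2, 2] <- 1L
  arr[1, 2, 2] <- 1L
  arr[3, 3, 3] <- 1L
  arr[4, 3, 3] <- 1L
  q <- qvoiFromArray(arr, binWidth = 64L)
  z <- matrixCounts(buildGlszm(q))
  expect_equal(sum(z[2, ]), 1)        # a single zone of size 4
  expect_equal(z[2, 4], 1)

  # separate the blobs with a different level: two zones of size 2
  arr[2, 2, 2] <- 1L; arr[3, 3, 3] <- 0L; arr[4, 3, 3] <- 1L
  arr2 <- arr
  q2 <- qvoiFromArray(arr2, binWidth = 64L)
  z2 <- matrixCounts(buildGlszm(q2))
  expect_equal(z2[2, 2], 1)           # (1,2,2)-(2,2,2)
  expect_equal(z2[2, 1], 1)           # (4,3,3) alone
})

test_that("runs partition collinear voxels as enumerated by hand", {
  arr <- array(NA_integer_, dim = c(4, 3, 3))
  arr[, 2, 2] <- c(1L, 1L, 1L, 2L)
  q <- qvoiFromArray(arr, binWidth = 64L)
  cnt <- matrixCounts(buildGlrlm(q))
  # x-axis: one run of level 1 length 3, one of level 2 length 1;
  # the 12 other directions see four singleton runs
  expect_equal(cnt[2, 3], 1)
  expect_equal(cnt[2, 1], 12 * 3)
  expect_equal(cnt[3, 1], 13 * 1)

  arrN <- array(5L, dim = c(6, 1, 1))
  qN <- qvoiFromArray(arrN, binWidth = 32L)
  cntN <- matrixCounts(buildGlrlm(qN))
  expect_equal(cntN[6, 6], 1)         # one maximal run of length 6
})

test_that("features are invariant to VOI translation within the grid", {
  set.seed(7)
  arr <- randomLevelArray(maxDim = 4, nlev = 4, pOut = 0.2)
  big <- array(NA_integer_, dim = dim(arr) + c(5, 3, 2))
  big[3:(2 + dim(arr)[1]), 2:(1 + dim(arr)[2]), 3:(2 + dim(arr)[3])] <- arr
  q1 <- qvoiFromArray(arr, binWidth = 64L)
  q2 <- qvoiFromArray(big, binWidth = 64L)
  for (build in list(buildGlcm, buildGldm, buildGlrlm, buildNgtdm))
    expect_equal(matrixCounts(build(q1)), matrixCounts(build(q2)))
  expect_equal(matrixCounts(buildGlszm(q1)), matrixCounts(buildGlszm(q2)))
})

test_that("degenerate VOIs follow the documented conventions", {
  # constant 2x2x2 block at one level
  arr <- array(2L, dim = c(2, 2, 2))
  q <- qvoiFromArray(arr, binWidth = 64L)
  f <- glcmFeatures(buildGlcm(q))
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Correlation"]), 0)   # zero marginal variance
  ng <- ngtdmFeatures(buildNgtdm(q))
  expect_equal(unname(ng["Coarseness"]), 1e6)
  expect_equal(unname(ng["Contrast"]), 0)
  # single isolated voxel: dependence count 0, empty GLCM
  arr1 <- array(3L, dim = c(1, 1, 1))
  q1 <- qvoiFromArray(arr1, binWidth = 64L)
  gld <- matrixCounts(buildGldm(q1))
  expect_equal(gld[4, 1], 1)
  expect_equal(sum(gld), 1)
  expect_true(all(glcmFeatures(buildGlcm(q1)) == 0))
  # 3x3x3 constant block: center voxel has full 26-neighborhood
  arr3 <- array(1L, dim = c(3, 3, 3))
  q3 <- qvoiFromArray(arr3, binWidth = 64L)
  gld3 <- matrixCounts(buildGldm(q3))
  expect_equal(gld3[2, 27], 1)
})

test_that("constant region yields one zone and ZonePercentage 1/n", {
  arr <- array(1L, dim = c(3, 2, 2))
  q <- qvoiFromArray(arr, binWidth = 64L)
  f <- glszmFeatures(buildGlszm(q))
  expect_equal(unname(f["ZonePercentage"]), 1 / 12)
})
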