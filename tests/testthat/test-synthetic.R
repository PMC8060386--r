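test_that("the atlas partitions an ellipsoid into sized, contiguous regions", {
  cfg <- toyConfig(seed = 4, nRegions = 8L)
  atlas <- makeAtlas(cfg)
  labs <- regionLabels(atlas)
  expect_identical(labs, 1:8)
  sizes <- tabulate(imgData(atlas)[imgData(atlas) > 0], nbins = 8)
  expect_true(all(sizes >= 64))
  # determinism
  atlas2 <- makeAtlas(cfg)
  expect_identical(imgData(atlas), imgData(atlas2))
  # every in-mask voxel carries exactly one nonzero label by construction;
  # check the mask is a single filled ellipsoid component along an axis ray
  mid <- imgData(atlas)[, 16, 16]
  inm <- which(mid > 0)
  expect_identical(inm, seq(min(inm), max(inm)))
})

test_that("a single region covers the whole mask", {
  cfg <- synthConfig(gridShape = c(12L, 12L, 12L), nRegions = 1L,
                     nAd = 0L, nControl = 0L, signalRegions = integer(0),
                     seed = 1)
  atlas <- makeAtlas(cfg)
  expect_identical(regionLabels(atlas), 1L)
})

test_that("too-small grids raise a sizing error", {
  cfg <- synthConfig(gridShape = c(8L, 8L, 8L), nRegions = 20L,
                     nAd = 0L, nControl = 0L, signalRegions = integer(0),
                     seed = 1)
  expect_error(makeAtlas(cfg), "grid too small")
})

test_that("the default atlas reproduces the 83-region Hammers layout", {
  cfg <- synthConfig(gridShape = c(48L, 56L, 48L), nAd = 0L, nControl = 0L,
                     seed = 2)
  atlas <- makeAtlas(cfg)
  expect_identical(regionLabels(atlas), 1:83)
  nm <- regionNames(atlas)
  expect_identical(length(nm), 83L)
  expect_match(nm[["3"]], "amygdala", ignore.case = TRUE)
})

test_that("control volumes carry background only; amplitude is 0 at onset 65", {
  cfg <- toyConfig(seed = 7, signalRegions = c(1L, 2L), slope = 0.05,
                   intercept = 0)
  atlas <- makeAtlas(cfg)
  ctl <- data.frame(subject_id = "CN001", group = "CONTROL", age = 70)
  adRef <- data.frame(subject_id = "AD_ref", group = "AD", age = 65)
  volC <- simulateSubjectVolume(atlas, ctl, cfg)
  volA <- simulateSubjectVolume(atlas, adRef, cfg)
  lab <- imgData(atlas)
  for (vol in list(volC, volA)) {
    x <- imgData(vol)[lab == 1L]
    expect_equal(mean(x), cfg$baseSuv, tolerance = 0.02)
    expect_equal(sd(x), cfg$noiseSd, tolerance = 0.05)
  }
  expect_true(all(imgData(volC)[lab == 0L] == 0))
  # determinism under (seed, subject id)
  volC2 <- simulateSubjectVolume(atlas, ctl, cfg)
  expect_identical(imgData(volC), imgData(volC2))
  expect_error(simulateSubjectVolume(
    atlas, data.frame(subject_id = "x", group = "WHAT", age = 60), cfg),
    "unknown subject group")
})

test_that("the planted perturbation is mean-free and grows with earlier onset", {
  cfg <- toyConfig(seed = 3, signalRegions = 1L, slope = 0.05,
                   intercept = 0.2)
  atlas <- makeAtlas(cfg)
  lab <- imgData(atlas)
  v55 <- v75 <- numeric(50)
  m55 <- numeric(50)
  for (s in 1:50) {
    cfgS <- toyConfig(seed = 100 + s, signalRegions = 1L, slope = 0.05,
                      intercept = 0.2)
    early <- simulateSubjectVolume(atlas,
      data.frame(subject_id = "E", group = "AD", age = 55), cfgS)
    late <- simulateSubjectVolume(atlas,
      data.frame(subject_id = "L", group = "AD", age = 75), cfgS)
    v55[s] <- var(imgData(early)[lab == 1L])
    v75[s] <- var(imgData(late)[lab == 1L])
    m55[s] <- mean(imgData(early)[lab == 1L])
  }
  expect_gt(mean(v55), mean(v75))                    # heterogeneity signal
  expect_gt(mean(v55) / mean(v75), 2)                # and clearly so
  expect_equal(mean(m55), cfg$baseSuv, tolerance = 5e-3)  # but mean-free
})

test_that("region mean SUV carries no onset-age signal", {
  cfg <- toyConfig(seed = 11, nAd = 20L, nControl = 0L,
                   signalRegions = c(1L, 3L), slope = 0.08, intercept = 0.3)
  atlas <- makeAtlas(cfg)
  lab <- imgData(atlas)
  rhos <- vapply(1:8, function(rep) {
    cfgS <- toyConfig(seed = 500 + rep, nAd = 20L, nControl = 0L,
                      signalRegions = c(1L, 3L), slope = 0.08,
                      intercept = 0.3)
    ages <- seq(55, 75, length.out = 20)
    means <- vapply(seq_along(ages), function(k) {
      vol <- simulateSubjectVolume(atlas,
        data.frame(subject_id = sprintf("AD%02d", k), group = "AD",
                   age = ages[k]), cfgS)
      mean(imgData(vol)[lab == 1L])
    }, numeric(1))
    spearmanRho(means, ages)$rho
  }, numeric(1))
  # an |rho| this small is inconsistent with any planted first-order signal
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("simulateCohort writes a complete, reproducible study", {
  cfg <- synthConfig(gridShape = c(16L, 16L, 16L), nRegions = 2L,
                     nAd = 0L, nControl = 3L, signalRegions = integer(0),
                     seed = 5)
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  co1 <- simulateCohort(cfg, d1)
  co2 <- simulateCohort(cfg, d2)
  expect_identical(nrow(co1), 3L)
  expect_true(all(co1$group == "CONTROL"))
  expect_true(all(file.exists(co1$volume_path)))
  expect_true(file.exists(file.path(d1, "atlas.nii")))
  # byte-identical reruns
  expect_identical(readBin(file.path(d1, "cohort.tsv"), "raw", 1e5),
                   readBin(file.path(d2, "cohort.tsv"), "raw", 1e5))
  expect_identical(readBin(co1$volume_path[1], "raw", 1e7),
                   readBin(co2$volume_path[1], "raw", 1e7))
  back <- readCohort(file.path(d1, "cohort.tsv"))
  expect_identical(back$subject_id, co1$subject_id)
  expect_true(!is.null(back$volume_path))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort composition follows the requested group sizes", {
  cfg <- synthConfig(gridShape = c(16L, 16L, 16L), nRegions = 2L,
                     nAd = 4L, nControl = 2L, signalRegions = integer(0),
                     seed = 6)
  d <- file.path(tempdir(), "cohortC")
  co <- simulateCohort(cfg, d)
  expect_identical(sum(co$group == "AD"), 4L)
  expect_identical(sum(co$group == "CONTROL"), 2L)
  expect_true(all(co$age[co$group == "AD"] >= 55 &
                  co$age[co$group == "AD"] <= 75))
  expect_true(all(co$mmse[co$group == "AD"] >= 0 &
                  co$mmse[co$group == "AD"] <= 30))
  unlink(d, recursive = TRUE)
})
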