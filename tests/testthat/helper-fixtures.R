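# Fixture builders shared across test files. All fixtures are generated in
# code under fixed seeds; nothing is read from disk except what a test
# itself writes to tempdir().

# QuantizedVoi directly from a 3D level array (NA = outside the VOI).
# binWidth controls the nominal level count: 32 -> 8 levels, 64 -> 4,
# 128 -> 2. Intensities are set to the levels so first-order code stays
# runnable on the same fixture.
qvoiFromArray <- function(arr, binWidth = 32L) {
  idx <- which(!is.na(arr))
  stopifnot(length(idx) >= 1)
  d <- dim(arr)
  i0 <- idx - 1L
  co <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  storage.mode(co) <- "integer"
  voi <- new("Voi", regionLabel = 1L, coords = co,
             intensities = as.numeric(arr[idx]), subject = "fix")
  new("QuantizedVoi", voi, levels = as.integer(arr[idx]),
      nLevels = as.integer(ceiling(256 / binWidth)),
      binWidth = as.integer(binWidth))
}

# random level array: dims up to maxDim, levels 0..(nlev-1), a fraction of
# voxels knocked out of the VOI
randomLevelArray <- function(maxDim = 5, nlev = 6, pOut = 0.25) {
  d <- sample(2:maxDim, 3, replace = TRUE)
  arr <- array(sample(0:(nlev - 1), prod(d), replace = TRUE), dim = d)
  out <- runif(prod(d)) < pOut
  if (all(out)) out[1] <- FALSE
  arr[out] <- NA
  arr
}

voiFromIntensities <- function(x, voxelSizeMm = c(1, 1, 1)) {
  n <- length(x)
  co <- cbind(seq_len(n) - 1L, 0L, 0L)
  storage.mode(co) <- "integer"
  new("Voi", regionLabel = 1L, coords = co, intensities = as.numeric(x),
      subject = "fix", voxelSizeMm = voxelSizeMm)
}

# small synthetic study used by pipeline tests: 8 regions on a 32^3 grid
toyConfig <- function(seed = 1L, nAd = 14L, nControl = 5L,
                      slope = 0.05, intercept = 0,
                      signalRegions = integer(0), nRegions = 8L) {
  synthConfig(gridShape = c(32L, 32L, 32L), voxelSizeMm = c(2, 2, 2),
              nRegions = nRegions, nAd = nAd, nControl = nControl,
              signalRegions = signalRegions,
              heterogeneitySlope = slope,
              heterogeneityIntercept = intercept, seed = seed)
}
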