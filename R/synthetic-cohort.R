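#' Configuration for the synthetic phantom cohort
#'
#' Bundles the parameters of the synthetic testbed: a Hammers-like 83-region
#' parcellation of an ellipsoidal "brain" on the standard 91 x 109 x 91 grid
#' of 2 mm voxels, and a cohort of AD and control subjects whose phantom PET
#' volumes carry textural heterogeneity -- but no mean-uptake signal --
#' growing with earlier disease onset.
#'
#' The defaults mirror the reference study design: 43 AD subjects and 27
#' controls, onset ages spanning 55-75 years, and heterogeneity planted in
#' the four regions reported as significant (Hammers labels 8, 55, 71, 82:
#' left lateral anterior temporal lobe, right anterior orbital gyrus, right
#' lateral orbital gyrus, left anterior superior temporal gyrus). The
#' perturbation amplitude for an AD subject with onset age `a` is
#' `max(0, heterogeneityIntercept + heterogeneitySlope * (65 - a))` SUV:
#' with the default intercept of 0, only subjects with onset before 65 carry
#' planted texture, a ramp effect anchored at the early/late-onset boundary.
#' `baseSuv` and `noiseSd` are calibration knobs of the phantom, not
#' literature values; the slope default is calibrated so that the leading
#' planted principal component correlates with onset age at roughly
#' |rho| 0.6 under the default cohort (see the methods vignette).
#'
#' @param gridShape integer(3), voxel grid dimensions.
#' @param voxelSizeMm numeric(3), voxel size in mm.
#' @param nRegions number of atlas regions (default 83).
#' @param nAd,nControl cohort sizes.
#' @param onsetAgeRange numeric(2), uniform range of AD onset ages (years);
#'   controls draw their age at scan from the same range.
#' @param signalRegions integer labels of regions carrying planted texture.
#' @param baseSuv mean background uptake (SUV).
#' @param noiseSd voxelwise Gaussian noise SD (SUV).
#' @param heterogeneitySlope texture amplitude per year of earlier onset
#'   (SUV/year).
#' @param heterogeneityIntercept amplitude at onset age 65 (SUV).
#' @param seed integer seed governing atlas, cohort and volumes.
#' @return A validated list of class `SynthConfig`.
#' @export
synthConfig <- function(gridShape = c(91L, 109L, 91L),
                        voxelSizeMm = c(2, 2, 2),
                        nRegions = 83L,
                        nAd = 43L,
                        nControl = 27L,
                        onsetAgeRange = c(55, 75),
                        signalRegions = c(8L, 55L, 71L, 82L),
                        baseSuv = 1.4,
                        noiseSd = 0.1,
                        heterogeneitySlope = 0.007,
                        heterogeneityIntercept = 0,
                        seed = 1L) {
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1),
            length(voxelSizeMm) == 3L, all(voxelSizeMm > 0),
            nRegions >= 1L, nAd >= 0L, nControl >= 0L,
            length(onsetAgeRange) == 2L,
            onsetAgeRange[1] < onsetAgeRange[2],
            baseSuv > 0, noiseSd > 0, heterogeneityIntercept >= 0)
  signalRegions <- as.integer(signalRegions)
  if (length(signalRegions) &&
      (min(signalRegions) < 1L || max(signalRegions) > nRegions))
    stopf("signalRegions must lie in 1..%d", nRegions)
  cfg <- list(gridShape = as.integer(gridShape),
              voxelSizeMm = as.numeric(voxelSizeMm),
              nRegions = as.integer(nRegions),
              nAd = as.integer(nAd), nControl = as.integer(nControl),
              onsetAgeRange = as.numeric(onsetAgeRange),
              signalRegions = signalRegions,
              baseSuv = baseSuv, noiseSd = noiseSd,
              heterogeneitySlope = heterogeneitySlope,
              heterogeneityIntercept = heterogeneityIntercept,
              seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  cfg
}

synthAffine <- function(config) {
  aff <- diag(4)
  diag(aff)[1:3] <- config$voxelSizeMm
  aff
}

#' Generate the synthetic label atlas
#'
#' Partitions an ellipsoidal brain mask (semi-axes 90% of the half-grid)
#' into `nRegions` contiguous regions by nearest-seed growth: seed points
#' are drawn inside the mask, relaxed by a few Lloyd (k-means) iterations to
#' even out region sizes, and every mask voxel takes the label of its
#' nearest seed. Voronoi cells of point seeds are convex, so each region is
#' connected. Label 0 is background. Deterministic given `config$seed`.
#' The real Hammers N30R83 geometry is not emulated; only the label count
#' and the region-name map are shared.
#'
#' @param config a [synthConfig()].
#' @return A [LabelAtlas-class] with Hammers region names attached when
#'   `nRegions` is 83.
#' @export
makeAtlas <- function(config) {
  d <- config$gridShape
  ctr <- (d - 1) / 2
  semi <- pmax((d - 1) / 2 * 0.9, 0.5)
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                             y = seq_len(d[2]) - 1L,
                             z = seq_len(d[3]) - 1L))
  inMask <- ((g[, 1] - ctr[1]) / semi[1])^2 +
            ((g[, 2] - ctr[2]) / semi[2])^2 +
            ((g[, 3] - ctr[3]) / semi[3])^2 <= 1
  nm <- sum(inMask)
  if (nm < 64 * config$nRegions)
    stopf("grid too small: mask has %d voxels, need >= %d for %d regions",
          nm, 64 * config$nRegions, config$nRegions)
  coords <- sweep(g[inMask, , drop = FALSE], 2, config$voxelSizeMm, "*")
  lab <- integer(nrow(g))
  set.seed(config$seed)
  if (config$nRegions == 1L) {
    lab[inMask] <- 1L
  } else {
    cl <- NULL
    for (try in 1:5) {
      init <- coords[sample.int(nm, config$nRegions), , drop = FALSE]
      km <- suppressWarnings(
        stats::kmeans(coords, centers = init, iter.max = 25,
                      algorithm = "Lloyd"))
      sizes <- tabulate(km$cluster, nbins = config$nRegions)
      if (min(sizes) >= 64L) { cl <- km$cluster; break }
    }
    if (is.null(cl))
      stopf("grid too small for %d regions of >= 64 voxels (smallest region %d had %d voxels)",
            config$nRegions, which.min(sizes), min(sizes))
    lab[inMask] <- cl
  }
  nms <- if (config$nRegions == 83L) hammersRegionNames() else character(0)
  new("LabelAtlas", labels = array(lab, dim = d),
      affine = synthAffine(config), regionNames = nms)
}

# deterministic per-subject stream: decouples a subject's volume from the
# cohort composition
subjectSeed <- function(seed, subjectId) {
  as.integer((abs(seed) * 7919 + strHash(subjectId)) %% 2147483647)
}

#' Simulate one subject's phantom PET volume
#'
#' Every in-mask voxel receives `baseSuv` plus Gaussian noise. For AD
#' subjects, each signal region additionally receives a spatially clustered,
#' exactly mean-free perturbation: a sum of compact Gaussian blobs of
#' alternating sign centered at random voxels of the region, rescaled to a
#' standard deviation of `max(0, intercept + slope * (65 - onset age))` SUV
#' and recentered to zero mean over the region. The recentering keeps every
#' region's mean uptake free of any onset-age signal -- only the texture
#' carries it -- while the voxel noise leaves region means non-degenerate.
#' Voxels outside the brain mask are 0. Deterministic given
#' (`config$seed`, `subjectId`).
#'
#' @param atlas a [LabelAtlas-class] from [makeAtlas()].
#' @param subject one-row data.frame with columns `subject_id`, `group`
#'   (`"AD"` or `"CONTROL"`) and `age` (onset age for AD, age at scan for
#'   controls).
#' @param config the [synthConfig()] used for the atlas.
#' @return An [ImageVolume-class].
#' @export
simulateSubjectVolume <- function(atlas, subject, config) {
  grp <- as.character(subject$group)
  if (!grp %in% c("AD", "CONTROL"))
    stopf("unknown subject group '%s'", grp)
  set.seed(subjectSeed(config$seed, as.character(subject$subject_id)))
  lab <- atlas@labels
  vol <- array(0, dim = dim(lab))
  inMask <- which(lab > 0L)
  vol[inMask] <- config$baseSuv + rnorm(length(inMask), 0, config$noiseSd)
  amp <- 0
  if (grp == "AD")
    amp <- max(0, config$heterogeneityIntercept +
                 config$heterogeneitySlope * (65 - subject$age))
  if (amp > 0 && length(config$signalRegions)) {
    d <- dim(lab)
    for (r in config$signalRegions) {
      idx <- which(lab == r)
      if (!length(idx)) next
      i0 <- idx - 1L
      co <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
      f <- blobField(co, nBlobs = max(4L, length(idx) %/% 120L))
      f <- f - mean(f)
      sdf <- sqrt(mean(f^2))
      if (sdf > 0) vol[idx] <- vol[idx] + f / sdf * amp
    }
  }
  newVolume(vol, synthAffine(config))
}

# sum of compact Gaussian blobs with alternating sign at random in-region
# centers; widths of 1.5-3 voxels give zones spanning several voxels after
# quantization
blobField <- function(co, nBlobs) {
  f <- numeric(nrow(co))
  ctrIdx <- sample.int(nrow(co), nBlobs, replace = TRUE)
  sigma <- runif(nBlobs, 1.5, 3)
  sgn <- rep(c(1, -1), length.out = nBlobs)[sample.int(nBlobs)]
  for (b in seq_len(nBlobs)) {
    d2 <- (co[, 1] - co[ctrIdx[b], 1])^2 +
          (co[, 2] - co[ctrIdx[b], 2])^2 +
          (co[, 3] - co[ctrIdx[b], 3])^2
    f <- f + sgn[b] * exp(-d2 / (2 * sigma[b]^2))
  }
  f
}

#' Simulate and write a full phantom cohort
#'
#' Draws the cohort table (AD onset ages uniform over `onsetAgeRange`,
#' control ages at scan from the same range), generates the atlas and one
#' PET volume per subject, and writes everything under `outDir`: the atlas
#' as `atlas.nii`, volumes as `<subject_id>.nii`, and the cohort table as
#' `cohort.tsv` with columns `subject_id group age sex mmse`. Two runs with
#' the same configuration produce byte-identical files.
#'
#' @param config a [synthConfig()].
#' @param outDir output directory, created if missing.
#' @param atlas optionally, a pre-built atlas to reuse.
#' @param verbose emit progress messages.
#' @return The cohort data.frame, invisibly carrying the atlas path in
#'   `attr(, "atlasPath")` and a `volume_path` column.
#' @export
simulateCohort <- function(config, outDir, atlas = NULL, verbose = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(atlas)) atlas <- makeAtlas(config)
  set.seed(config$seed)
  n <- config$nAd + config$nControl
  ids <- c(sprintf("AD%03d", seq_len(config$nAd)),
           sprintf("CN%03d", seq_len(config$nControl)))
  grp <- rep(c("AD", "CONTROL"), c(config$nAd, config$nControl))
  age <- round(runif(n, config$onsetAgeRange[1], config$onsetAgeRange[2]), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  mmse <- ifelse(grp == "AD",
                 round(pmin(30, pmax(0, rnorm(n, 17, 6)))), NA_real_)
  cohort <- data.frame(subject_id = ids, group = grp, age = age, sex = sex,
                       mmse = mmse, stringsAsFactors = FALSE)
  atlasPath <- file.path(outDir, "atlas.nii")
  writeAtlas(atlas, atlasPath)
  paths <- character(n)
  for (k in seq_len(n)) {
    vol <- simulateSubjectVolume(atlas, cohort[k, ], config)
    paths[k] <- file.path(outDir, paste0(ids[k], ".nii"))
    writeVolume(vol, paths[k])
    petLog("simulate", "wrote %s (%s, age %.1f)", paths[k], grp[k], age[k],
           verbose = verbose)
  }
  cohort$volume_path <- paths
  write.table(cohort[, c("subject_id", "group", "age", "sex", "mmse")],
              file.path(outDir, "cohort.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  attr(cohort, "atlasPath") <- atlasPath
  invisible(cohort)
}

#' Read a cohort table
#'
#' @param path TSV with header `subject_id group age sex mmse`; a
#'   `volume_path` column is added when volumes sit next to the table.
#' @return The cohort data.frame.
#' @export
readCohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age")
  if (!all(need %in% names(df)))
    stopf("cohort table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stopf("duplicate subject ids in %s", path)
  if (is.null(df$volume_path)) {
    cand <- file.path(dirname(path), paste0(df$subject_id, ".nii"))
    if (all(file.exists(cand))) df$volume_path <- cand
  }
  df
}

# Hammers N30R83 label -> region-name map (odd labels right, even left for
# paired structures), shipped as a plain-text default for 83-region atlases.
hammersRegionNames <- function() {
  path <- system.file("extdata", "hammers_region_names.tsv",
                      package = "PETtex")
  if (!nzchar(path)) return(character(0))
  readRegionNames(path)
}
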