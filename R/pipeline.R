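#' Extract features and mean uptake for a whole cohort
#'
#' Reads each subject's volume, extracts every nonzero atlas region as a
#' VOI, and computes the 93-feature battery at each bin width plus the
#' region mean SUV.
#'
#' @param cohort cohort data.frame with columns `subject_id`, `group`,
#'   `age` and `volume_path` (see [readCohort()], [simulateCohort()]).
#' @param atlas a [LabelAtlas-class] on the volumes' grid.
#' @param widths bin widths, subset of `c(1, 2, 8, 16, 32, 64, 128)`.
#' @param duplicateEntropy see [featureRegistry()].
#' @param verbose emit one progress line per subject.
#' @return List with `features` (long data.frame) and `suv` (data.frame
#'   `subject_id`, `region`, `mean_suv`).
#' @export
extractCohortFeatures <- function(cohort, atlas,
                                  widths = ALLOWED_BIN_WIDTHS,
                                  duplicateEntropy = FALSE,
                                  verbose = FALSE) {
  missing <- cohort$volume_path[!file.exists(cohort$volume_path)]
  if (length(missing))
    stopf("missing volumes for subjects: %s",
          paste(cohort$subject_id[!file.exists(cohort$volume_path)],
                collapse = ", "))
  labs <- regionLabels(atlas)
  featParts <- vector("list", nrow(cohort))
  suvParts <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    vol <- readVolume(cohort$volume_path[k])
    sid <- cohort$subject_id[k]
    fk <- vector("list", length(labs))
    mk <- numeric(length(labs))
    for (li in seq_along(labs)) {
      voi <- extractVoi(vol, atlas, labs[li], subject = sid)
      fk[[li]] <- extractFeatures(voi, widths = widths,
                                  duplicateEntropy = duplicateEntropy)
      mk[li] <- meanSuv(voi)
    }
    featParts[[k]] <- do.call(rbind, fk)
    suvParts[[k]] <- data.frame(subject_id = sid, region = labs,
                                mean_suv = mk, stringsAsFactors = FALSE)
    petLog("extract", "subject %s: %d regions x %d widths", sid,
           length(labs), length(widths), verbose = verbose)
  }
  list(features = do.call(rbind, featParts),
       suv = do.call(rbind, suvParts))
}

pickReferenceRegion <- function(atlas, referenceRegion) {
  if (!is.null(referenceRegion)) return(as.integer(referenceRegion))
  nm <- regionNames(atlas)
  hit <- grep("amygdala", nm, ignore.case = TRUE, value = FALSE)
  if (length(hit)) {
    labs <- sort(as.integer(names(nm)[hit]))
    return(labs[1])
  }
  regionLabels(atlas)[1]
}

#' Run the complete texture-heterogeneity analysis
#'
#' End-to-end pipeline on a cohort of spatially normalized PET volumes and a
#' label atlas: per-region feature extraction at every bin width, per-feature
#' bin-width selection against the AD onset ages, per-region PCA under the
#' 90% explained-variance rule, Bonferroni-screened Spearman correlation of
#' retained components with onset age, and a threshold-age group-difference
#' scan for the significant components. Alongside, region mean SUV and SUVR
#' (against an amygdala-named or caller-chosen reference region) are tested
#' for onset-age correlation -- the expected null result -- and control
#' subjects are pushed through the same feature extraction and projected
#' onto the AD components as a background reference.
#'
#' @param cohort cohort data.frame (see [readCohort()]); AD rows drive the
#'   analysis, CONTROL rows form the background.
#' @param atlas a [LabelAtlas-class] or path to an atlas NIfTI.
#' @param widths bin widths to extract.
#' @param varianceThreshold PCA cumulative explained-variance rule
#'   (default 0.90).
#' @param rhoThreshold Spearman screening threshold (default 0.5).
#' @param alpha family-wise level before the per-region Bonferroni division
#'   (default 0.05).
#' @param ageRange threshold-age scan bounds (default 55..75).
#' @param referenceRegion SUVR reference label; default: first region whose
#'   name contains "amygdala", else the first region.
#' @param candleAge threshold age of the per-group candle summary
#'   (default 65).
#' @param widthSelection `"cohort"` (default) selects one bin width per
#'   feature shared across regions via [selectCohortWidths()]; `"region"`
#'   re-selects per (feature, region) with [selectBinWidth()]. The cohort
#'   rule keeps the component screen calibrated under the null; see the
#'   methods vignette.
#' @param duplicateEntropy,welch battery and t-test variants, see
#'   [featureRegistry()] and [pooledTTest()].
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param precomputed optional list with elements `features` and `suv` as
#'   returned by [extractCohortFeatures()]; when given, volumes are not
#'   re-read and extraction is skipped.
#' @param verbose progress messages.
#' @return A [TextureAnalysis-class].
#' @export
runPipeline <- function(cohort, atlas, widths = ALLOWED_BIN_WIDTHS,
                        varianceThreshold = 0.90, rhoThreshold = 0.5,
                        alpha = 0.05, ageRange = c(55L, 75L),
                        referenceRegion = NULL, candleAge = 65,
                        widthSelection = c("cohort", "region"),
                        duplicateEntropy = FALSE, welch = FALSE,
                        seed = NA_integer_, precomputed = NULL,
                        verbose = FALSE) {
  widthSelection <- match.arg(widthSelection)
  if (is.character(atlas)) atlas <- readAtlas(atlas)
  if (is.null(cohort$volume_path) && is.null(precomputed))
    stopf("cohort has no volume_path column")
  opts <- list(widths = sort(as.integer(widths)),
               varianceThreshold = varianceThreshold,
               rhoThreshold = rhoThreshold, alpha = alpha,
               ageRange = as.integer(ageRange),
               candleAge = candleAge, widthSelection = widthSelection,
               duplicateEntropy = duplicateEntropy, welch = welch)
  ad <- cohort[cohort$group == "AD", , drop = FALSE]
  ctl <- cohort[cohort$group == "CONTROL", , drop = FALSE]
  if (nrow(ad) < 3L) stopf("need at least 3 AD subjects")
  ex <- if (is.null(precomputed))
    extractCohortFeatures(cohort, atlas, widths = widths,
                          duplicateEntropy = duplicateEntropy,
                          verbose = verbose)
  else precomputed
  ages <- setNames(ad$age, ad$subject_id)
  labs <- regionLabels(atlas)
  adFeatures <- ex$features[ex$features$subject_id %in% ad$subject_id, ,
                            drop = FALSE]

  widthMap <- NULL
  if (widthSelection == "cohort") {
    cw <- selectCohortWidths(adFeatures, ages)
    widthMap <- setNames(as.integer(cw$binWidth), cw$feature)
    petLog("analyze", "cohort-level bin widths selected for %d features",
           length(widthMap), verbose = verbose)
  }

  pcas <- list()
  comps <- list()
  scans <- list()
  for (r in labs) {
    pca <- regionPca(adFeatures, r, ages,
                     varianceThreshold = varianceThreshold,
                     widthMap = widthMap)
    pcas[[as.character(r)]] <- pca
    sc <- screenComponents(pca, unname(ages), rhoThreshold = rhoThreshold,
                           alpha = alpha)
    comps[[as.character(r)]] <- sc
    for (k in which(sc$significant)) {
      scan <- thresholdAgeScan(pca@scores[, k], unname(ages), pca@nInd,
                               ageRange = ageRange, alpha = alpha,
                               welch = welch)
      scan$region <- r
      scan$component <- k - 1L
      scans[[length(scans) + 1L]] <- scan
    }
    petLog("analyze", "region %d: nInd=%d, significant=%d", r, pca@nInd,
           sum(sc$significant), verbose = verbose)
  }
  components <- do.call(rbind, comps)
  rownames(components) <- NULL
  scans <- if (length(scans)) do.call(rbind, scans) else
    data.frame(A = integer(0), n_early = integer(0), n_late = integer(0),
               p = numeric(0), significant = logical(0),
               region = integer(0), component = integer(0))

  suvStats <- suvNullCheck(ex$suv, ad, atlas, referenceRegion, alpha)
  controlComponents <- controlBackground(ex$features, pcas, ctl,
                                         rhoThreshold, alpha)
  candle <- candleSummary(pcas, components, ad, ctl, ex$features, candleAge)

  manifest <- list(seed = seed, configHash = configHash(opts),
                   nAd = nrow(ad), nControl = nrow(ctl),
                   nRegions = length(labs),
                   widths = opts$widths,
                   package = as.character(packageVersion("PETtex")))
  new("TextureAnalysis", featureTable = ex$features, regionPcas = pcas,
      components = components, scans = scans, suvStats = suvStats,
      controlComponents = controlComponents, candle = candle,
      manifest = manifest)
}

# Per-region Spearman test of mean SUV (and SUVR against the reference
# region) versus onset age in the AD group. The Bonferroni flag divides
# alpha by the number of regions tested.
suvNullCheck <- function(suvTable, ad, atlas, referenceRegion, alpha) {
  adSuv <- suvTable[suvTable$subject_id %in% ad$subject_id, , drop = FALSE]
  labs <- sort(unique(adSuv$region))
  ref <- pickReferenceRegion(atlas, referenceRegion)
  refVals <- adSuv[adSuv$region == ref, , drop = FALSE]
  thr <- alpha / length(labs)
  rows <- lapply(labs, function(r) {
    rw <- adSuv[adSuv$region == r, , drop = FALSE]
    v <- setNames(rw$mean_suv, rw$subject_id)[ad$subject_id]
    sp <- spearmanRho(v, ad$age)
    ratio <- v / setNames(refVals$mean_suv, refVals$subject_id)[ad$subject_id]
    spr <- if (r == ref) list(rho = NA_real_, p = NA_real_) else
      spearmanRho(ratio, ad$age)
    data.frame(region = r, suv_rho = sp$rho, suv_p = sp$p,
               suvr_rho = spr$rho, suvr_p = spr$p,
               suv_significant = sp$p < thr,
               suvr_significant = !is.na(spr$p) & spr$p < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "referenceRegion") <- ref
  out
}

# Project control subjects onto the AD-derived components (same selected
# widths, same z-scoring) and screen their scores against age at scan.
controlBackground <- function(features, pcas, ctl, rhoThreshold, alpha) {
  empty <- data.frame(region = integer(0), component = integer(0),
                      rho = numeric(0), p = numeric(0),
                      significant = logical(0))
  if (nrow(ctl) < 3L) return(empty)
  ctlFeatures <- features[features$subject_id %in% ctl$subject_id, ,
                          drop = FALSE]
  rows <- list()
  for (rc in names(pcas)) {
    pca <- pcas[[rc]]
    z <- projectScores(pca, ctlFeatures, ctl$subject_id)
    thr <- alpha / pca@nInd
    for (k in seq_len(pca@nInd)) {
      sc <- z[, k]
      if (sd(sc) == 0 || sd(ctl$age) == 0) { rho <- 0; p <- 1 }
      else { sp <- spearmanRho(sc, ctl$age); rho <- sp$rho; p <- sp$p }
      rows[[length(rows) + 1L]] <-
        data.frame(region = pca@region, component = k - 1L, rho = rho,
                   p = p, significant = abs(rho) > rhoThreshold & p < thr)
    }
  }
  do.call(rbind, rows)
}

#' Project new subjects onto a region's components
#'
#' Applies the region's selected bin widths, z-scoring parameters and
#' loadings to feature values of subjects that did not enter the PCA.
#'
#' @param pca a [RegionPca-class].
#' @param features long feature data.frame covering the new subjects.
#' @param subjects subject ids to project.
#' @return subjects x components score matrix.
#' @export
projectScores <- function(pca, features, subjects) {
  sub <- features[features$region == pca@region &
                  features$subject_id %in% subjects, , drop = FALSE]
  key <- paste(sub$family, sub$feature_name, sep = "_")
  feats <- names(pca@center)
  x <- matrix(NA_real_, nrow = length(subjects), ncol = length(feats),
              dimnames = list(subjects, feats))
  sel <- pca@selectedWidths
  for (fi in seq_along(feats)) {
    w <- sel$binWidth[sel$feature == feats[fi]]
    rw <- sub[key == feats[fi] & sub$bin_width == w, , drop = FALSE]
    x[, fi] <- rw$value[match(subjects, rw$subject_id)]
  }
  if (anyNA(x)) stopf("incomplete features for projection in region %d",
                      pca@region)
  z <- sweep(sweep(x, 2, pca@center), 2, pca@scale, "/")
  z %*% pca@loadings
}

#' Candle-plot summary of significant components
#'
#' For every significant component: mean, SD and quartiles of the scores in
#' the early-onset (onset < `candleAge`), late-onset (onset >= `candleAge`)
#' and control groups, the numbers behind a box/candle figure.
#'
#' @param pcas list of [RegionPca-class] keyed by region.
#' @param components the component screen table.
#' @param ad,ctl AD and control cohort rows.
#' @param features long feature table (controls included).
#' @param candleAge the group-defining threshold age.
#' @return data.frame, three rows (EOAD, LOAD, CONTROL) per significant
#'   component; empty when nothing is significant.
#' @export
candleSummary <- function(pcas, components, ad, ctl, features, candleAge) {
  sig <- components[components$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(region = integer(0), component = integer(0),
                      group = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0), q25 = numeric(0),
                      median = numeric(0), q75 = numeric(0)))
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    pca <- pcas[[as.character(sig$region[i])]]
    k <- sig$component[i] + 1L
    adScores <- pca@scores[, k]
    groups <- list(EOAD = adScores[ad$age < candleAge],
                   LOAD = adScores[ad$age >= candleAge])
    if (nrow(ctl) >= 3L) {
      ctlScores <- projectScores(pca,
        features[features$subject_id %in% ctl$subject_id, , drop = FALSE],
        ctl$subject_id)[, k]
      groups$CONTROL <- ctlScores
    }
    for (g in names(groups)) {
      v <- groups[[g]]
      qs <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <-
        data.frame(region = sig$region[i], component = sig$component[i],
                   group = g, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   q25 = qs[1], median = qs[2], q75 = qs[3])
    }
  }
  do.call(rbind, rows)
}

#' Write analysis results to files
#'
#' Writes the Table 3/Table 4-style summaries as JSON
#' (`results.json`: per-region component counts, the component screen with
#' top features, SUV null checks, manifest), the scan curves as
#' `scans.tsv`, the candle summary as `candle.tsv` and the full feature
#' table as `features.tsv`.
#'
#' @param analysis a [TextureAnalysis-class].
#' @param dir output directory, created if missing.
#' @param writeFeatures also dump the (large) long feature table.
#' @return `dir`, invisibly.
#' @export
writeResults <- function(analysis, dir, writeFeatures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- data.frame(
    region = vapply(analysis@regionPcas, function(p) p@region, integer(1)),
    nInd = vapply(analysis@regionPcas, function(p) p@nInd, integer(1)))
  rownames(regions) <- NULL
  out <- list(manifest = analysis@manifest,
              regions = regions,
              components = analysis@components,
              suv = analysis@suvStats,
              controlComponents = analysis@controlComponents)
  jsonlite::write_json(out, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write.table(analysis@scans, file.path(dir, "scans.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(analysis@candle, file.path(dir, "candle.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (writeFeatures)
    write.table(analysis@featureTable, file.path(dir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
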