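#' @rdname ImageVolume-class
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname ImageVolume-class
setMethod("imgAffine", "ImageVolume", function(x) x@affine)

#' @rdname LabelAtlas-class
setMethod("imgAffine", "LabelAtlas", function(x) x@affine)

#' @rdname ImageVolume-class
setMethod("voxelSize", "ImageVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname LabelAtlas-class
setMethod("voxelSize", "LabelAtlas",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname LabelAtlas-class
setMethod("imgData", "LabelAtlas", function(x) x@labels)

#' @rdname LabelAtlas-class
setMethod("regionLabels", "LabelAtlas",
          function(x) sort(unique(as.integer(x@labels[x@labels > 0L]))))

#' @rdname LabelAtlas-class
setMethod("regionNames", "LabelAtlas", function(x) x@regionNames)

#' @rdname Voi-class
setMethod("nVoxels", "Voi", function(x) nrow(x@coords))

#' @rdname Voi-class
setMethod("voiCoords", "Voi", function(x) x@coords)

#' @rdname Voi-class
setMethod("voiIntensities", "Voi", function(x) x@intensities)

#' @rdname QuantizedVoi-class
setMethod("grayLevels", "QuantizedVoi", function(x) x@levels)

#' @rdname QuantizedVoi-class
setMethod("binWidth", "QuantizedVoi", function(x) x@binWidth)

#' @rdname QuantizedVoi-class
setMethod("nLevels", "QuantizedVoi", function(x) x@nLevels)

#' @rdname TextureMatrix-class
setMethod("matrixFamily", "TextureMatrix", function(x) x@family)

#' @rdname TextureMatrix-class
setMethod("matrixCounts", "TextureMatrix", function(x) x@counts)

#' @rdname TextureMatrix-class
setMethod("nVoxels", "TextureMatrix", function(x) x@nVoxels)

#' @rdname RegionPca-class
setMethod("pcaScores", "RegionPca", function(x) x@scores)

#' @rdname RegionPca-class
setMethod("pcaLoadings", "RegionPca", function(x) x@loadings)

#' @rdname RegionPca-class
setMethod("explainedVariance", "RegionPca", function(x) x@explainedVar)

#' @rdname RegionPca-class
setMethod("nIndependent", "RegionPca", function(x) x@nInd)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  vs <- voxelSize(object)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelAtlas", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelAtlas: %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(regionLabels(object))))
})

setMethod("show", "Voi", function(object) {
  cat(sprintf("Voi: region %d, %d voxels%s\n", object@regionLabel,
              nVoxels(object),
              if (is.na(object@subject)) ""
              else sprintf(", subject %s", object@subject)))
})

setMethod("show", "QuantizedVoi", function(object) {
  cat(sprintf(
    "QuantizedVoi: region %d, %d voxels, bin width %d (%d levels)\n",
    object@regionLabel, nVoxels(object), object@binWidth, object@nLevels))
})

setMethod("show", "TextureMatrix", function(object) {
  cat(sprintf("TextureMatrix (%s): %d x %d counts from %d voxels\n",
              object@family, nrow(object@counts), ncol(object@counts),
              object@nVoxels))
})

setMethod("show", "RegionPca", function(object) {
  cat(sprintf(
    "RegionPca: region %d, %d features, %d components to 90%% variance\n",
    object@region, nrow(object@loadings), object@nInd))
  if (length(object@dropped))
    cat(sprintf("  dropped %d zero-variance features\n",
                length(object@dropped)))
})

setMethod("show", "TextureAnalysis", function(object) {
  cat("TextureAnalysis\n")
  cat(sprintf("  feature table: %d rows\n", nrow(object@featureTable)))
  cat(sprintf("  regions analyzed: %d\n", length(object@regionPcas)))
  sig <- object@components$significant
  cat(sprintf("  components retained: %d, significant: %d\n",
              nrow(object@components), sum(sig)))
  cat(sprintf("  seed: %s, config hash: %s\n",
              object@manifest$seed, object@manifest$configHash))
})
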