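#' @rdname ImageVolume-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ImageVolume-class
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname LabelAtlas-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname LabelAtlas-class
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname Voi-class
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname Voi-class
#' @export
setGeneric("voiCoords", function(x) standardGeneric("voiCoords"))

#' @rdname Voi-class
#' @export
setGeneric("voiIntensities", function(x) standardGeneric("voiIntensities"))

#' @rdname QuantizedVoi-class
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))

#' @rdname QuantizedVoi-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname QuantizedVoi-class
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname TextureMatrix-class
#' @export
setGeneric("matrixFamily", function(x) standardGeneric("matrixFamily"))

#' @rdname TextureMatrix-class
#' @export
setGeneric("matrixCounts", function(x) standardGeneric("matrixCounts"))

#' @rdname RegionPca-class
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname RegionPca-class
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname RegionPca-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname RegionPca-class
#' @export
setGeneric("nIndependent", function(x) standardGeneric("nIndependent"))
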