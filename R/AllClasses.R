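#' @import methods
NULL

ALLOWED_BIN_WIDTHS <- c(1L, 2L, 8L, 16L, 32L, 64L, 128L)
N_GRAY_LEVELS <- 256L

#' 3D image volume on a voxel grid
#'
#' Container for a spatially normalized PET volume: a 3D array of voxel
#' intensities (SUV) together with the 4x4 voxel-to-world affine (mm).
#' Voxel indices are 0-based, following the NIfTI convention.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot affine 4x4 numeric voxel-to-world matrix in mm.
#' @export
setClass("ImageVolume",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, sprintf("data must be a 3D array, got %d dimensions",
                            length(dim(object@data))))
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    if (anyNA(object@data))
      msg <- c(msg, "volume contains NA/NaN voxels")
    if (is.null(msg)) TRUE else msg
  })

#' Integer label parcellation on a voxel grid
#'
#' A brain atlas: non-negative integer labels on a 3D grid, label 0 meaning
#' background, with an optional label-to-name map.
#'
#' @slot labels 3D integer array of region labels (0 = background).
#' @slot affine 4x4 numeric voxel-to-world matrix in mm.
#' @slot regionNames named character vector; names are label integers.
#' @export
setClass("LabelAtlas",
  representation(labels = "array", affine = "matrix",
                 regionNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    if (anyNA(object@labels) || any(object@labels < 0))
      msg <- c(msg, "labels must be non-negative integers without NA")
    if (is.null(msg)) TRUE else msg
  })

#' Volume of interest: one atlas region's voxels
#'
#' The voxels of a single atlas region, as extracted by [extractVoi()]:
#' 0-based voxel coordinates in lexicographic order and the matching SUV
#' intensities.
#'
#' @slot regionLabel integer atlas label.
#' @slot coords n x 3 integer matrix of 0-based voxel indices.
#' @slot intensities numeric vector, one value per coordinate row.
#' @slot subject subject identifier the VOI came from.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @export
setClass("Voi",
  representation(regionLabel = "integer", coords = "matrix",
                 intensities = "numeric", subject = "character",
                 voxelSizeMm = "numeric"),
  prototype(subject = NA_character_, voxelSizeMm = c(1, 1, 1)),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@coords) != 3L)
      msg <- c(msg, "coords must have 3 columns")
    if (nrow(object@coords) < 1L)
      msg <- c(msg, "VOI must contain at least one voxel")
    if (nrow(object@coords) != length(object@intensities))
      msg <- c(msg, "coords and intensities lengths differ")
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      msg <- c(msg, "voxelSizeMm must be 3 positive reals")
    if (is.null(msg)) TRUE else msg
  })

#' A VOI with quantized gray levels
#'
#' Adds to [Voi-class] the gray levels obtained by 256-level min-max
#' discretization ([discretize()]) and optional rebinning ([rebin()]).
#' Levels are 0-based; `nLevels = ceiling(256 / binWidth)`.
#'
#' @slot levels integer vector of 0-based gray levels, one per voxel.
#' @slot nLevels number of gray levels of the quantization.
#' @slot binWidth rebinning width, one of 1, 2, 8, 16, 32, 64, 128.
#' @export
setClass("QuantizedVoi",
  contains = "Voi",
  representation(levels = "integer", nLevels = "integer",
                 binWidth = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@levels) != length(object@intensities))
      msg <- c(msg, "levels and intensities lengths differ")
    if (!(object@binWidth %in% ALLOWED_BIN_WIDTHS))
      msg <- c(msg, sprintf("binWidth %d not in {%s}", object@binWidth,
                            paste(ALLOWED_BIN_WIDTHS, collapse = ",")))
    if (object@nLevels != as.integer(ceiling(N_GRAY_LEVELS / object@binWidth)))
      msg <- c(msg, "nLevels must equal ceiling(256 / binWidth)")
    if (length(object@levels) &&
        (min(object@levels) < 0L || max(object@levels) >= object@nLevels))
      msg <- c(msg, "levels out of range [0, nLevels)")
    if (is.null(msg)) TRUE else msg
  })

#' A texture matrix of one family
#'
#' Raw (unnormalized) counts of one of the five texture matrix families,
#' merged over the 13 unique 26-neighborhood directions. Rows index the gray
#' level (row g holds 0-based level g-1); the column meaning depends on the
#' family: co-occurring level (GLCM), dependence count + 1 (GLDM), run length
#' (GLRLM), zone size (GLSZM), or the two columns (occurrence count,
#' gray-tone difference sum) for NGTDM.
#'
#' @slot family one of "GLCM", "GLDM", "GLRLM", "GLSZM", "NGTDM".
#' @slot counts numeric count matrix.
#' @slot nVoxels number of voxels in the source VOI.
#' @slot aux list of family-specific extras (e.g. number of directions).
#' @export
setClass("TextureMatrix",
  representation(family = "character", counts = "matrix",
                 nVoxels = "integer", aux = "list"),
  prototype(aux = list()),
  validity = function(object) {
    ok <- object@family %in% c("GLCM", "GLDM", "GLRLM", "GLSZM", "NGTDM")
    if (!ok) return("unknown texture matrix family")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' Per-region principal components decomposition
#'
#' Result of [regionPca()]: the PCA of a region's bin-width-selected,
#' z-scored feature matrix, with the number of components retained under the
#' 90% cumulative explained-variance rule.
#'
#' @slot region atlas label of the region.
#' @slot selectedWidths data.frame (feature, binWidth, rho) from
#'   [selectBinWidth()].
#' @slot loadings features x components matrix of loadings.
#' @slot explainedVar explained variance ratio per component, non-increasing.
#' @slot nInd components retained to reach 90% cumulative variance.
#' @slot scores subjects x components score matrix.
#' @slot dropped names of zero-variance features dropped before the PCA.
#' @slot center,scale per-feature z-scoring parameters (population SD), kept
#'   so new subjects (e.g. controls) can be projected onto the components.
#' @export
setClass("RegionPca",
  representation(region = "integer", selectedWidths = "data.frame",
                 loadings = "matrix", explainedVar = "numeric",
                 nInd = "integer", scores = "matrix", dropped = "character",
                 center = "numeric", scale = "numeric"),
  validity = function(object) {
    msg <- NULL
    ev <- object@explainedVar
    if (any(diff(ev) > 1e-9))
      msg <- c(msg, "explained variance ratios must be non-increasing")
    if (sum(ev) > 1 + 1e-9)
      msg <- c(msg, "explained variance ratios sum above 1")
    k <- object@nInd
    if (k < 1L || k > length(ev)) {
      msg <- c(msg, "nInd out of range")
    } else {
      cs <- cumsum(ev)
      if (cs[k] < 0.90 - 1e-12)
        msg <- c(msg, "cumulative explained variance at nInd below 90%")
      if (k > 1L && cs[k - 1L] >= 0.90)
        msg <- c(msg, "nInd is not minimal for the 90% rule")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Full pipeline results
#'
#' Everything [runPipeline()] computes: the long feature table, per-region
#' PCA decompositions, the component screen against onset age, threshold-age
#' scans for significant components, per-region mean-SUV/SUVR null checks,
#' the control-group background screen, the candle-plot summary at the
#' reference threshold age, and a reproducibility manifest.
#'
#' @slot featureTable long data.frame of feature values.
#' @slot regionPcas list of [RegionPca-class], named by region label.
#' @slot components data.frame, one row per retained component.
#' @slot scans data.frame of threshold-age scan curves.
#' @slot suvStats data.frame of per-region SUV and SUVR correlations.
#' @slot controlComponents data.frame, background screen on controls.
#' @slot candle data.frame, per-group score summaries at the candle age.
#' @slot manifest list: seed, configuration hash, package version.
#' @export
setClass("TextureAnalysis",
  representation(featureTable = "data.frame", regionPcas = "list",
                 components = "data.frame", scans = "data.frame",
                 suvStats = "data.frame", controlComponents = "data.frame",
                 candle = "data.frame", manifest = "list"))
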