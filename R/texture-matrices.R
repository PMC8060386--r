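#' @useDynLib PETtex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Embed a quantized VOI into its bounding-box array: 0-based levels inside
# the VOI, NA outside. Translation of the VOI within the grid cancels here,
# which is what makes the texture features translation invariant.
voiLevelArray <- function(q) {
  co <- q@coords
  lo <- apply(co, 2, min)
  hi <- apply(co, 2, max)
  d <- hi - lo + 1L
  arr <- array(NA_integer_, dim = d)
  arr[cbind(co[, 1] - lo[1], co[, 2] - lo[2], co[, 3] - lo[3]) + 1L] <-
    q@levels
  arr
}

#' Build the gray-level co-occurrence matrix
#'
#' Counts of gray-level pairs at 26-connected neighbor voxels, restricted to
#' voxel pairs inside the VOI. Counts are summed over the 13 unique direction
#' offsets into a single merged matrix and symmetrized, so the matrix always
#' equals its transpose.
#'
#' @param q a [QuantizedVoi-class].
#' @return A [TextureMatrix-class] with family `"GLCM"`.
#' @seealso [glcmFeatures()]
#' @export
buildGlcm <- function(q) {
  m <- .cppGlcm(voiLevelArray(q), q@nLevels)
  new("TextureMatrix", family = "GLCM", counts = m,
      nVoxels = nVoxels(q), aux = list(nDirections = 13L))
}

#' Build the gray-level dependence matrix
#'
#' For every VOI voxel, the dependence count is the number of its in-VOI
#' 26-neighbors whose gray level differs by at most `alpha`. Entry (g, j)
#' counts voxels of level g-1 with dependence count j-1; entries sum to the
#' VOI voxel count.
#'
#' @param q a [QuantizedVoi-class].
#' @param alpha dependence tolerance on the level difference (default 0:
#'   equal levels only).
#' @return A [TextureMatrix-class] with family `"GLDM"`.
#' @seealso [gldmFeatures()]
#' @export
buildGldm <- function(q, alpha = 0L) {
  if (alpha < 0) stopf("alpha must be a non-negative integer")
  m <- .cppGldm(voiLevelArray(q), q@nLevels, as.integer(alpha))
  new("TextureMatrix", family = "GLDM", counts = m, nVoxels = nVoxels(q),
      aux = list(alpha = as.integer(alpha)))
}

#' Build the gray-level run-length matrix
#'
#' Maximal runs of constant gray level along each of the 13 unique
#' 26-neighborhood directions (each direction's two orientations describe the
#' same runs), restricted to in-VOI voxels; counts from all directions are
#' merged into one matrix. Entry (g, l) counts runs of level g-1 and length
#' l; per direction, run lengths weighted by counts partition the VOI, so the
#' merged matrix satisfies `sum(length * count) = 13 * nVoxels`.
#'
#' @param q a [QuantizedVoi-class].
#' @return A [TextureMatrix-class] with family `"GLRLM"`.
#' @seealso [glrlmFeatures()]
#' @export
buildGlrlm <- function(q) {
  m <- .cppGlrlm(voiLevelArray(q), q@nLevels)
  # trim trailing all-zero run-length columns beyond the longest run
  last <- max(c(1L, which(colSums(m) > 0)))
  new("TextureMatrix", family = "GLRLM",
      counts = m[, seq_len(last), drop = FALSE],
      nVoxels = nVoxels(q), aux = list(nDirections = 13L))
}

#' Build the gray-level size-zone matrix
#'
#' Zones are 26-connected components of constant gray level within the VOI
#' (two blobs touching only at a voxel corner are one zone). Entry (g, s)
#' counts zones of level g-1 and size s; `sum(size * count)` equals the VOI
#' voxel count.
#'
#' @param q a [QuantizedVoi-class].
#' @return A [TextureMatrix-class] with family `"GLSZM"`.
#' @seealso [glszmFeatures()]
#' @export
buildGlszm <- function(q) {
  m <- zonesToCounts(.cppGlszmZones(voiLevelArray(q)), q@nLevels)
  new("TextureMatrix", family = "GLSZM", counts = m, nVoxels = nVoxels(q))
}

# (level, size) zone list -> level x size count matrix
zonesToCounts <- function(z, nLevels) {
  smax <- max(z[, 2])
  m <- matrix(0, nrow = nLevels, ncol = smax)
  key <- z[, 1] + nLevels * (z[, 2] - 1L)
  tab <- rowsum(rep(1, nrow(z)), key)
  k <- as.integer(rownames(tab))
  m[cbind((k %% nLevels) + 1L, (k %/% nLevels) + 1L)] <- tab
  m
}

#' Build the neighborhood gray-tone difference matrix
#'
#' For each gray level i the matrix stores `s_i`, the sum over VOI voxels of
#' that level of the absolute difference between the voxel's level and the
#' mean level of its in-VOI 26-neighbors. Voxels with no in-VOI neighbor are
#' excluded both from `s_i` and from the occurrence counts kept alongside.
#'
#' @param q a [QuantizedVoi-class].
#' @return A [TextureMatrix-class] with family `"NGTDM"`; `counts` is the
#'   single column of `s_i`, with occurrence counts in `aux$n`.
#' @seealso [ngtdmFeatures()]
#' @export
buildNgtdm <- function(q) {
  m <- .cppNgtdm(voiLevelArray(q), q@nLevels)
  new("TextureMatrix", family = "NGTDM",
      counts = m[, 2, drop = FALSE], nVoxels = nVoxels(q),
      aux = list(n = m[, 1], nValid = sum(m[, 1])))
}
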