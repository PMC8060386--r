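#' Reslice a label atlas onto a target grid
#'
#' Nearest-neighbor resampling of the atlas through the two voxel-to-world
#' affines: each target voxel center is mapped to world space, then into
#' atlas voxel space, and receives the label of the nearest atlas voxel.
#' Labels are never interpolated; target voxels falling outside the atlas
#' field of view become background (0). Estimating a registration is out of
#' scope -- both images are assumed to already sit in a common world space.
#'
#' @param atlas a [LabelAtlas-class].
#' @param target an [ImageVolume-class] defining the output grid.
#' @return A [LabelAtlas-class] on the target grid.
#' @export
resliceAtlas <- function(atlas, target) {
  aAff <- atlas@affine
  tAff <- target@affine
  if (abs(det(aAff)) < 1e-12 || abs(det(tAff)) < 1e-12)
    stopf("singular affine: cannot reslice")
  td <- dim(target@data)
  # 0-based voxel index grid of the target
  g <- as.matrix(expand.grid(x = seq_len(td[1]) - 1L,
                             y = seq_len(td[2]) - 1L,
                             z = seq_len(td[3]) - 1L))
  m <- solve(aAff) %*% tAff          # target voxel -> atlas voxel
  src <- cbind(g, 1) %*% t(m)
  src <- round(src[, 1:3])
  ad <- dim(atlas@labels)
  ok <- src[, 1] >= 0 & src[, 1] < ad[1] &
        src[, 2] >= 0 & src[, 2] < ad[2] &
        src[, 3] >= 0 & src[, 3] < ad[3]
  out <- integer(nrow(src))
  out[ok] <- atlas@labels[1L + src[ok, , drop = FALSE]]
  new("LabelAtlas", labels = array(out, dim = td), affine = tAff,
      regionNames = atlas@regionNames)
}

checkSameGrid <- function(vol, atlas) {
  if (!all(dim(vol@data) == dim(atlas@labels)))
    stopf("volume and atlas grids differ (%s vs %s); reslice the atlas first",
          paste(dim(vol@data), collapse = "x"),
          paste(dim(atlas@labels), collapse = "x"))
  if (max(abs(vol@affine - atlas@affine)) > 1e-4)
    stopf("volume and atlas affines differ; reslice the atlas first")
}

#' Extract the volume of interest for one atlas label
#'
#' Masks the PET volume with one region of the atlas ("point multiplication"
#' of mask and image): the VOI holds exactly the voxels where the atlas
#' equals `label`, in lexicographic (column-major) order.
#'
#' @param vol an [ImageVolume-class].
#' @param atlas a [LabelAtlas-class] on the same grid and affine.
#' @param label integer region label present in the atlas.
#' @param subject optional subject id to record on the VOI.
#' @return A [Voi-class].
#' @export
extractVoi <- function(vol, atlas, label, subject = NA_character_) {
  checkSameGrid(vol, atlas)
  idx <- which(atlas@labels == label)
  if (!length(idx))
    stopf("label %d not present in atlas", label)
  d <- dim(vol@data)
  i0 <- idx - 1L
  coords <- cbind(i0 %% d[1],
                  (i0 %/% d[1]) %% d[2],
                  i0 %/% (d[1] * d[2]))
  storage.mode(coords) <- "integer"
  new("Voi", regionLabel = as.integer(label), coords = coords,
      intensities = as.numeric(vol@data[idx]), subject = subject,
      voxelSizeMm = voxelSize(vol))
}

#' Mean SUV of a VOI
#'
#' @param voi a [Voi-class].
#' @return Arithmetic mean of the VOI intensities.
#' @export
meanSuv <- function(voi) mean(voi@intensities)

#' SUV ratio against a reference region
#'
#' Mean uptake of `voi` normalized to the mean uptake of a reference VOI
#' (the amygdala in the standard analysis).
#'
#' @param voi a [Voi-class].
#' @param reference the reference [Voi-class].
#' @return `meanSuv(voi) / meanSuv(reference)`.
#' @export
suvr <- function(voi, reference) {
  m <- meanSuv(reference)
  if (abs(m) < .Machine$double.eps)
    stopf("reference region has zero mean uptake")
  meanSuv(voi) / m
}
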