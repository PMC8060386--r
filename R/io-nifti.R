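#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1 file into an [ImageVolume-class]. The input must be 3D and
#' free of NaN; both conditions are checked at read so downstream texture code
#' never sees undefined intensities.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [ImageVolume-class].
#' @seealso [writeVolume()], [readAtlas()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected a 3D volume, got %dD in %s", length(d), path)
  arr <- array(as.numeric(img), dim = d)
  if (anyNA(arr))
    stopf("volume contains NaN voxels: %s", path)
  aff <- unclass(RNifti::xform(img))
  newVolume(arr, aff)
}

#' Construct an ImageVolume from an array and affine
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix; default `diag(4)` (1 mm voxels).
#' @return An [ImageVolume-class].
#' @export
newVolume <- function(data, affine = diag(4)) {
  new("ImageVolume", data = data, affine = unname(affine))
}

#' Write a volume to NIfTI
#'
#' Float32 on disk; a write/read round trip preserves float32 voxel values
#' bit-exactly and the affine to 1e-6.
#'
#' @param vol an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a label atlas from NIfTI
#'
#' @param path path to an integer-valued NIfTI parcellation.
#' @param namesFile optional two-column TSV `label name` mapping labels to
#'   region names.
#' @return A [LabelAtlas-class].
#' @export
readAtlas <- function(path, namesFile = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected a 3D atlas, got %dD in %s", length(d), path)
  vals <- as.numeric(img)
  if (anyNA(vals)) stopf("atlas contains NaN voxels: %s", path)
  if (max(abs(vals - round(vals))) > 1e-6)
    stopf("atlas voxel values are not integers: %s", path)
  arr <- array(as.integer(round(vals)), dim = d)
  nm <- character(0)
  if (!is.null(namesFile)) nm <- readRegionNames(namesFile)
  new("LabelAtlas", labels = arr,
      affine = unname(unclass(RNifti::xform(img))), regionNames = nm)
}

#' Write a label atlas to NIfTI (int16 datatype)
#'
#' @param atlas a [LabelAtlas-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas@labels)
  RNifti::sform(img) <- structure(atlas@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a region-name map
#'
#' @param path two-column TSV with header `label name`.
#' @return Named character vector (names are label integers).
#' @export
readRegionNames <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(df)))
    stopf("region name file must have columns 'label' and 'name': %s", path)
  setNames(as.character(df$name), as.character(df$label))
}
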