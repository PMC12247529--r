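#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`) as an [fcd_volume],
#' applying the on-disk scale slope/intercept and preserving the affine and
#' voxel spacing.
#'
#' @param path Path to a readable NIfTI file.
#' @param axial_axis Which array axis holds axial slices (default 3, the
#'   usual convention for axially acquired FLAIR).
#' @return An [fcd_volume].
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 1))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(ph$volume, f)
#' v <- read_volume(f)
#' all.equal(v$data, ph$volume$data)
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, axial_axis = 3L) {
  if (!file.exists(path)) {
    stop_fcd(sprintf("NIfTI file not found: %s", path), "io")
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop_fcd(
      sprintf("failed to parse NIfTI file %s: %s", path, conditionMessage(e)),
      "format"
    )
  )
  nd <- length(dim(img))
  if (nd != 3L) {
    stop_fcd(sprintf("expected a 3D image, got rank %d (%s)", nd, path), "dim")
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop RNifti header attributes
  fcd_volume(arr, affine = affine, axial_axis = axial_axis)
}

#' Read a binary lesion mask aligned to a reference volume
#'
#' Reads a NIfTI mask, binarizes it at `threshold` (stored masks are expected
#' to be 0/1 already; thresholding guards against fractional labels from
#' earlier interpolation), and checks voxel alignment against `reference`.
#'
#' @param path Path to the mask file.
#' @param reference An [fcd_volume] the mask must be voxel-aligned with.
#' @param threshold Binarization threshold in (0,1), default 0.5.
#' @return An [fcd_mask] with the reference geometry.
#' @export
read_mask <- function(path, reference, threshold = 0.5) {
  stopifnot(inherits(reference, "fcd_volume"))
  raw <- read_volume(path, axial_axis = reference$axial_axis)
  if (!same_shape(raw$data, reference$data)) {
    stop_fcd(
      sprintf(
        "mask shape (%s) does not match reference shape (%s)",
        paste(dim(raw$data), collapse = "x"),
        paste(dim(reference$data), collapse = "x")
      ),
      "geometry"
    )
  }
  m <- binarize_mask(raw$data, threshold = threshold)
  fcd_mask(m$data, reference = reference)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit for exact binary round-trips; images
#' keep a floating-point representation. The affine is stored in both the
#' sform and qform so geometry survives round-trips.
#'
#' @param v An [fcd_volume] or [fcd_mask].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory is created if needed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "fcd_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_fcd(sprintf("cannot create directory %s", dir), "io")
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  datatype <- if (inherits(v, "fcd_mask")) "uint8" else "double"
  res <- tryCatch(
    RNifti::writeNifti(img, path, datatype = datatype),
    error = function(e) stop_fcd(
      sprintf("cannot write NIfTI to %s: %s", path, conditionMessage(e)), "io"
    )
  )
  invisible(path)
}
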