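#' 3D volume and lesion-mask containers
#'
#' An `fcd_volume` holds a 3D intensity array together with its geometry: a
#' 4x4 voxel-to-world affine (mm) and per-axis voxel spacing (mm). An
#' `fcd_mask` is the voxel-aligned binary counterpart used for lesion
#' annotations and predictions. The third array axis is treated as the axial
#' (inferior-superior) slice axis by default; slice indices are 1-based.
#'
#' @param data 3D numeric array of intensities (arbitrary scanner units), or
#'   for masks an array whose values are 0/1.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, strictly
#'   positive. Ignored when `affine` is supplied (it is then derived from the
#'   affine's column norms).
#' @param affine 4x4 voxel-to-world transform. Defaults to a diagonal affine
#'   built from `spacing` with the world origin at the volume centre.
#' @param axial_axis Integer, which array axis indexes axial slices
#'   (default 3).
#' @return An object of class `fcd_volume` (or `fcd_mask`): a list with
#'   elements `data`, `affine`, `spacing`, `axial_axis`.
#' @examples
#' v <- fcd_volume(array(rnorm(8 * 8 * 4, 100), c(8, 8, 4)), spacing = c(1, 1, 3))
#' dim(v)
#' v$spacing
#' @export
fcd_volume <- function(data, spacing = c(1, 1, 1), affine = NULL, axial_axis = 3L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_fcd(
      sprintf(
        "volume data must be a 3D array, got rank %d",
        if (is.array(data)) length(dim(data)) else NA_integer_
      ),
      "dim"
    )
  }
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop_fcd("spacing must be 3 strictly positive finite values", "value")
    }
    affine <- default_affine(dim(data), spacing)
  } else {
    affine <- unclass(affine)
    if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
      stop_fcd("affine must be a 4x4 matrix", "value")
    }
    spacing <- spacing_from_affine(affine)
  }
  out <- structure(
    list(
      data = data, affine = affine, spacing = spacing,
      axial_axis = as.integer(axial_axis)
    ),
    class = "fcd_volume"
  )
  validate_volume(out)
  out
}

#' @rdname fcd_volume
#' @param reference Optional `fcd_volume` the mask must be aligned with; its
#'   geometry is adopted and the shapes must agree.
#' @examples
#' m <- fcd_mask(array(0L, c(8, 8, 4)), reference = v)
#' sum(m$data)
#' @export
fcd_mask <- function(data, spacing = c(1, 1, 1), affine = NULL, axial_axis = 3L,
                     reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "fcd_volume"))
    if (!identical(dim(data), dim(reference$data))) {
      stop_fcd(
        sprintf(
          "mask shape (%s) does not match reference shape (%s)",
          paste(dim(data), collapse = "x"),
          paste(dim(reference$data), collapse = "x")
        ),
        "geometry"
      )
    }
    affine <- reference$affine
    axial_axis <- reference$axial_axis
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stop_fcd("mask voxels must all be exactly 0 or 1", "value")
  }
  storage.mode(data) <- "integer"
  v <- fcd_volume(data, spacing = spacing, affine = affine, axial_axis = axial_axis)
  class(v) <- c("fcd_mask", "fcd_volume")
  v
}

# diagonal affine with world origin at the array centre
default_affine <- function(shape, spacing) {
  a <- diag(4)
  diag(a)[1:3] <- spacing
  a[1:3, 4] <- -(shape - 1) * spacing / 2
  a
}

spacing_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

validate_volume <- function(v) {
  d <- dim(v$data)
  if (any(d < 1L)) stop_fcd("every volume axis must have size >= 1", "dim")
  implied <- spacing_from_affine(v$affine)
  if (any(abs(implied - v$spacing) > 1e-3)) {
    stop_fcd(
      sprintf(
        "spacing (%s) inconsistent with affine column norms (%s)",
        paste(signif(v$spacing, 6), collapse = ", "),
        paste(signif(implied, 6), collapse = ", ")
      ),
      "geometry"
    )
  }
  if (!v$axial_axis %in% 1:3) stop_fcd("axial_axis must be 1, 2 or 3", "value")
  invisible(v)
}

#' @export
dim.fcd_volume <- function(x) dim(x$data)

#' @export
print.fcd_volume <- function(x, ...) {
  kind <- if (inherits(x, "fcd_mask")) "lesion mask" else "volume"
  cat(sprintf(
    "<fcd_%s> %s voxels, spacing %s mm, axial axis %d\n",
    if (inherits(x, "fcd_mask")) "mask" else "volume",
    paste(dim(x$data), collapse = " x "),
    paste(signif(x$spacing, 4), collapse = " x "),
    x$axial_axis
  ))
  if (inherits(x, "fcd_mask")) {
    cat(sprintf("  %d lesion voxels (%s of volume)\n", sum(x$data),
                sprintf("%.3f%%", 100 * mean(x$data))))
  } else {
    cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

n_axial_slices <- function(v) dim(v$data)[v$axial_axis]

# extract slice z along the axial axis as a 2D matrix
axial_slice <- function(arr, axis, z) {
  switch(axis,
    arr[z, , , drop = TRUE],
    arr[, z, , drop = TRUE],
    arr[, , z, drop = TRUE]
  )
}

# subset an array to the given indices along `axis`
take_axial <- function(arr, axis, idx) {
  switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE]
  )
}

same_shape <- function(a, b) identical(dim(a), dim(b))

as_mask_array <- function(m) {
  if (inherits(m, "fcd_volume")) m$data else m
}
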