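#' Preprocessing configuration
#'
#' Bundles the settings for the four-stage preprocessing pipeline applied to
#' each FLAIR volume/mask pair before slice selection and model training:
#' spatial resampling to a standard voxel spacing, skull stripping, intensity
#' normalization, and mask binarization.
#'
#' @param target_spacing Per-axis target voxel size in mm (default 1 mm
#'   isotropic).
#' @param image_interp_order Spline order for image interpolation: 0
#'   (nearest), 1 (linear), 2 or 3 (cubic spline).
#' @param mask_interp Mask interpolation scheme; only `"nearest"` is
#'   supported, so labels are never blended.
#' @param normalization `"zscore_brain"` (standardize within the brain mask;
#'   default), `"zscore_global"` (whole volume) or `"none"`.
#' @param skullstrip_method `"otsu_cc"` (Otsu threshold, morphological
#'   closing, largest connected component, hole filling) or `"none"`.
#' @param binarize_threshold Threshold in (0,1) for mask binarization
#'   (default 0.5).
#' @return A list of class `fcd_preprocess_config`.
#' @examples
#' cfg <- preprocess_config(target_spacing = c(1, 1, 1))
#' cfg$normalization
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 1),
                              image_interp_order = 3L,
                              mask_interp = "nearest",
                              normalization = c("zscore_brain", "zscore_global", "none"),
                              skullstrip_method = c("otsu_cc", "none"),
                              binarize_threshold = 0.5) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop_fcd("target_spacing must be 3 strictly positive values", "value")
  }
  if (!image_interp_order %in% 0:3) {
    stop_fcd("image_interp_order must be one of 0, 1, 2, 3", "value")
  }
  mask_interp <- match.arg(mask_interp, "nearest")
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop_fcd("binarize_threshold must lie in (0, 1)", "value")
  }
  structure(
    list(
      target_spacing = target_spacing,
      image_interp_order = as.integer(image_interp_order),
      mask_interp = mask_interp,
      normalization = match.arg(normalization),
      skullstrip_method = match.arg(skullstrip_method),
      binarize_threshold = binarize_threshold
    ),
    class = "fcd_preprocess_config"
  )
}

#' Read or write a preprocessing configuration as a YAML file
#'
#' @param path File path.
#' @return `read_preprocess_config()` returns an `fcd_preprocess_config`;
#'   `write_preprocess_config()` returns `path` invisibly.
#' @export
read_preprocess_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(preprocess_config, vals)
}

#' @rdname read_preprocess_config
#' @param cfg An `fcd_preprocess_config`.
#' @export
write_preprocess_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# 1D interpolation of each column of a matrix at positions `pos` (0-based
# index coordinates of the source grid)
interp_columns <- function(mat, pos, order) {
  n <- nrow(mat)
  x <- seq_len(n) - 1
  if (order == 0L) {
    idx <- pmin(pmax(round(pos), 0), n - 1) + 1
    return(mat[idx, , drop = FALSE])
  }
  pos <- pmin(pmax(pos, 0), n - 1)
  if (order == 1L || n < 4L) {
    out <- apply(mat, 2L, function(col) {
      stats::approx(x, col, xout = pos, rule = 2)$y
    })
  } else {
    out <- apply(mat, 2L, function(col) {
      stats::splinefun(x, col, method = "natural")(pos)
    })
  }
  matrix(out, nrow = length(pos))
}

# separable interpolation of a 3D array along one axis
interp_axis3d <- function(arr, axis, pos, order) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- interp_columns(m, pos, order)
  res <- array(out, c(length(pos), d[2], d[3]))
  aperm(res, order(perm))
}

#' Resample a volume to a target voxel spacing
#'
#' Spatial interpolation standardizes voxel spacing across scans. The new
#' shape per axis is `round(old_shape * old_spacing / new_spacing)` (minimum
#' 1); the affine's direction columns are rescaled so the world extent is
#' preserved to within one voxel. Interpolation is separable per axis:
#' nearest (order 0), linear (order 1) or natural cubic spline (orders 2-3).
#'
#' @param v An [fcd_volume] or [fcd_mask]. Masks are always resampled with
#'   nearest-neighbour so the label set \{0,1\} is preserved.
#' @param target_spacing Per-axis target spacing in mm.
#' @param order Interpolation order in 0..3 (ignored for masks).
#' @return A resampled object of the same class.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 7))
#' half <- resample_volume(ph$volume, c(2, 2, 2))
#' dim(half)
#' @export
resample_volume <- function(v, target_spacing, order = 3L) {
  stopifnot(inherits(v, "fcd_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0)) {
    stop_fcd("target spacing must be 3 strictly positive values", "value")
  }
  is_mask <- inherits(v, "fcd_mask")
  if (is_mask) order <- 0L
  if (!order %in% 0:3) stop_fcd("order must be in 0..3", "value")

  old_shape <- dim(v$data)
  new_shape <- pmax(1L, as.integer(round(old_shape * v$spacing / target_spacing)))
  scale <- target_spacing / v$spacing

  arr <- v$data
  for (ax in 1:3) {
    if (new_shape[ax] == old_shape[ax] && abs(scale[ax] - 1) < 1e-12) next
    pos <- (seq_len(new_shape[ax]) - 1) * scale[ax]
    arr <- interp_axis3d(arr, ax, pos, order)
  }

  affine <- v$affine
  for (ax in 1:3) affine[1:3, ax] <- affine[1:3, ax] * scale[ax]

  if (is_mask) {
    fcd_mask(round(arr), affine = affine, axial_axis = v$axial_axis)
  } else {
    fcd_volume(arr, affine = affine, axial_axis = v$axial_axis)
  }
}

#' Skull stripping by thresholding and connected components
#'
#' Removes non-brain voxels so downstream stages operate on cerebral tissue
#' only: Otsu threshold on the intensity histogram, morphological closing
#' (radius 1 voxel, face connectivity), largest connected component, and
#' interior hole filling.
#'
#' @param v An [fcd_volume] with non-constant intensities.
#' @return A list with `volume` (input with non-brain voxels set to 0) and
#'   `brain_mask` (an [fcd_mask] of the retained region).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 3))
#' ss <- skull_strip(ph$volume)
#' sum(ss$brain_mask$data) > 0
#' @export
skull_strip <- function(v) {
  stopifnot(inherits(v, "fcd_volume"))
  x <- v$data
  rng <- range(x)
  if (diff(rng) == 0) {
    stop_fcd("cannot skull-strip a constant-intensity volume", "degenerate")
  }
  scaled <- (x - rng[1]) / diff(rng)
  # single global histogram threshold: reshape the volume to one 2D frame
  thr <- EBImage::otsu(matrix(scaled, nrow = dim(x)[1]), range = c(0, 1))
  fg <- scaled > thr
  if (!any(fg)) stop_fcd("Otsu threshold removed every voxel", "degenerate")
  fg <- closing6(fg)
  fg <- largest_component(fg)
  fg <- fill_holes(fg)
  stripped <- x
  stripped[!fg] <- 0
  out_v <- fcd_volume(stripped, affine = v$affine, axial_axis = v$axial_axis)
  brain <- fcd_mask(array(as.integer(fg), dim(x)), affine = v$affine,
                    axial_axis = v$axial_axis)
  list(volume = out_v, brain_mask = brain)
}

#' Z-score intensity normalization within a brain mask
#'
#' Standardizes voxel intensities so each scan has mean 0 and standard
#' deviation 1 inside the brain mask; voxels outside the mask are set to 0.
#' The operation is idempotent and invariant under positive affine intensity
#' transforms.
#'
#' @param v An [fcd_volume].
#' @param brain_mask An [fcd_mask] (or logical/0-1 array) of the same shape;
#'   must be non-empty with positive in-mask variance.
#' @return A normalized [fcd_volume].
#' @export
normalize_intensity <- function(v, brain_mask) {
  stopifnot(inherits(v, "fcd_volume"))
  bm <- as_mask_array(brain_mask) > 0
  if (!same_shape(v$data, bm)) {
    stop_fcd("brain mask shape does not match volume shape", "geometry")
  }
  if (!any(bm)) stop_fcd("brain mask is empty", "degenerate")
  vals <- v$data[bm]
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    stop_fcd("zero intensity variance within the brain mask", "degenerate")
  }
  out <- array(0, dim(v$data))
  out[bm] <- (vals - mean(vals)) / s
  fcd_volume(out, affine = v$affine, axial_axis = v$axial_axis)
}

#' Binarize a soft mask
#'
#' Voxels strictly greater than `threshold` become 1, all others 0.
#'
#' @param raw A 3D numeric array (or [fcd_volume]/[fcd_mask]) of finite
#'   values.
#' @param threshold Scalar threshold (default 0.5).
#' @param geometry Optional [fcd_volume] providing affine/spacing for the
#'   result; defaults to `raw`'s geometry when `raw` is an `fcd_volume`.
#' @return An [fcd_mask].
#' @export
binarize_mask <- function(raw, threshold = 0.5, geometry = NULL) {
  if (inherits(raw, "fcd_volume") && is.null(geometry)) geometry <- raw
  arr <- as_mask_array(raw)
  if (any(!is.finite(arr))) {
    stop_fcd("mask values must be finite to binarize", "value")
  }
  bin <- array(as.integer(arr > threshold), dim(arr))
  if (is.null(geometry)) {
    fcd_mask(bin)
  } else {
    fcd_mask(bin, affine = geometry$affine, axial_axis = geometry$axial_axis)
  }
}

#' Run the full preprocessing pipeline on one case
#'
#' Applies, in order: resampling to `cfg$target_spacing` (image with
#' `cfg$image_interp_order`, mask with nearest-neighbour), skull stripping,
#' intensity normalization, and mask binarization. Errors raised by a stage
#' are annotated with the stage name.
#'
#' @param v An [fcd_volume].
#' @param m The voxel-aligned [fcd_mask].
#' @param cfg An [preprocess_config()].
#' @return A list with `volume`, `mask` and `brain_mask` (NULL when skull
#'   stripping is disabled), all voxel-aligned.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 5))
#' pp <- preprocess_case(ph$volume, ph$mask, preprocess_config())
#' range(pp$mask$data)
#' @export
preprocess_case <- function(v, m, cfg = preprocess_config()) {
  stopifnot(inherits(v, "fcd_volume"), inherits(m, "fcd_mask"))
  if (!same_shape(v$data, m$data)) {
    stop_fcd("volume and mask are not voxel-aligned", "geometry")
  }
  stage <- function(name, expr) {
    tryCatch(expr, fcdseg_error = function(e) {
      rlang::abort(
        sprintf("[stage %s] %s", name, conditionMessage(e)),
        class = class(e)[1], parent = e
      )
    })
  }
  v <- stage("resample", resample_volume(v, cfg$target_spacing, cfg$image_interp_order))
  m <- stage("resample", resample_volume(m, cfg$target_spacing))

  brain <- NULL
  if (cfg$skullstrip_method == "otsu_cc") {
    ss <- stage("skull_strip", skull_strip(v))
    v <- ss$volume
    brain <- ss$brain_mask
  }

  if (cfg$normalization == "zscore_brain") {
    bm <- if (is.null(brain)) {
      fcd_mask(array(1L, dim(v$data)), affine = v$affine, axial_axis = v$axial_axis)
    } else {
      brain
    }
    v <- stage("normalize", normalize_intensity(v, bm))
  } else if (cfg$normalization == "zscore_global") {
    all_mask <- fcd_mask(array(1L, dim(v$data)), affine = v$affine,
                         axial_axis = v$axial_axis)
    v <- stage("normalize", normalize_intensity(v, all_mask))
  }

  m <- stage("binarize", binarize_mask(m$data, cfg$binarize_threshold, geometry = v))
  list(volume = v, mask = m, brain_mask = brain)
}
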