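#' Specification for a FLAIR-like brain phantom
#'
#' Describes a synthetic 3D "brain": a noisy bright ellipsoid of cerebral
#' tissue surrounded by near-zero background, carrying zero or more
#' hyperintense cortical lesion blobs with voxel-aligned ground-truth masks.
#' The phantom reproduces the statistical structure the pipeline assumes —
#' FLAIR hyperintensity of dysplastic tissue, lesions confined to a few
#' axial slices, a frontal (anterior) predilection — without anatomical
#' realism, which is a non-goal.
#'
#' @param shape Voxel extents, length 3 (default `c(48, 48, 32)`).
#' @param spacing Voxel size in mm (default 1 mm isotropic).
#' @param brain_axes Ellipsoid semi-axes in voxels (default `0.42 * shape`).
#' @param tissue_mean,tissue_sd Brain-tissue intensity model (arbitrary
#'   units; defaults 100 and 5 — normalization removes scale, so units are
#'   immaterial).
#' @param lesion_count Number of lesions (default 1; 0 gives a lesion-free
#'   phantom).
#' @param lesion_radius_range In-plane lesion radius bounds in voxels
#'   (default 3 to 5).
#' @param lesion_contrast Multiplicative hyperintensity factor, > 1
#'   (default 1.8).
#' @param lesion_slab_extent Number of axial slices each lesion spans
#'   (default 5).
#' @param frontal_bias Probability that a lesion centre falls in the
#'   anterior half of the first in-plane axis (default 0.624, the reported
#'   frontal-lobe frequency in the FCD II cohort this emulates).
#' @param noise_sd Additive Gaussian noise scale (default 5).
#' @param seed Integer RNG seed; phantoms are bitwise reproducible from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 32),
                         spacing = c(1, 1, 1),
                         brain_axes = NULL,
                         tissue_mean = 100, tissue_sd = 5,
                         lesion_count = 1L,
                         lesion_radius_range = c(3, 5),
                         lesion_contrast = 1.8,
                         lesion_slab_extent = 5L,
                         frontal_bias = 0.624,
                         noise_sd = 5,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop_fcd("phantom shape must be 3 extents of at least 8 voxels", "value")
  }
  brain_axes <- brain_axes %||% (0.42 * shape)
  if (lesion_contrast <= 1) {
    stop_fcd("lesion_contrast must exceed 1 (FLAIR hyperintensity)", "value")
  }
  if (frontal_bias < 0 || frontal_bias > 1) {
    stop_fcd("frontal_bias must lie in [0, 1]", "value")
  }
  if (lesion_count > 0 &&
      max(lesion_radius_range) >= min(brain_axes[1:2]) / 2) {
    stop_fcd("lesion radius too large to fit inside the brain ellipsoid", "value")
  }
  structure(
    list(
      shape = shape, spacing = as.numeric(spacing), brain_axes = brain_axes,
      tissue_mean = tissue_mean, tissue_sd = tissue_sd,
      lesion_count = as.integer(lesion_count),
      lesion_radius_range = lesion_radius_range,
      lesion_contrast = lesion_contrast,
      lesion_slab_extent = as.integer(lesion_slab_extent),
      frontal_bias = frontal_bias, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# squared normalized ellipsoid coordinate for every voxel
ellipsoid_rho2 <- function(shape, centre, axes) {
  gx <- (seq_len(shape[1]) - centre[1]) / axes[1]
  gy <- (seq_len(shape[2]) - centre[2]) / axes[2]
  gz <- (seq_len(shape[3]) - centre[3]) / axes[3]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

#' Generate one brain phantom with ground-truth lesion masks
#'
#' Builds the brain ellipsoid, draws tissue texture
#' `N(tissue_mean, tissue_sd)` inside it, places each lesion as an
#' ellipsoidal blob at a cortical radius (55-80% of the way to the brain
#' surface) whose base intensity is multiplied by `lesion_contrast`, then
#' adds `N(0, noise_sd)` noise everywhere. Lesion centres fall in the
#' anterior half of the first in-plane axis with probability
#' `frontal_bias`. Fully reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([fcd_volume]), `mask` ([fcd_mask]) and
#'   `meta` (a tibble: lesion centres, radii, anterior flags, voxel counts).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 11))
#' sum(ph$mask$data) > 0
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  shape <- spec$shape
  centre <- (shape + 1) / 2
  rho2 <- ellipsoid_rho2(shape, centre, spec$brain_axes)
  brain <- rho2 <= 1

  mask <- array(0L, shape)
  meta <- vector("list", spec$lesion_count)
  for (j in seq_len(spec$lesion_count)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      semi_z <- (spec$lesion_slab_extent - 1) / 2 + 0.49
      anterior <- runif(1) < spec$frontal_bias
      # cortical placement: radial fraction 0.55-0.80 of the brain ellipsoid
      rho <- runif(1, 0.55, 0.80)
      theta <- runif(1, 0, 2 * pi)
      phi <- acos(runif(1, -0.6, 0.6)) # stay away from the axial poles
      ux <- sin(phi) * cos(theta)
      uy <- sin(phi) * sin(theta)
      uz <- cos(phi)
      # anterior = lower half of the first in-plane axis
      cx <- centre[1] + rho * spec$brain_axes[1] * (if (anterior) -abs(ux) else abs(ux))
      cy <- centre[2] + rho * spec$brain_axes[2] * uy
      cz <- centre[3] + rho * spec$brain_axes[3] * uz
      lesion_centre <- c(cx, cy, cz)
      les_rho2 <- ellipsoid_rho2(shape, lesion_centre, c(r, r, semi_z))
      blob <- les_rho2 <= 1
      if (any(blob) && all(brain[blob])) {
        mask[blob] <- 1L
        meta[[j]] <- tibble(
          lesion = j,
          centre_x = cx, centre_y = cy, centre_z = cz,
          radius = r, anterior = anterior, voxels = sum(blob)
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_fcd("could not place a lesion inside the brain after 100 attempts",
               "placement")
    }
  }

  base <- array(0, shape)
  base[brain] <- rnorm(sum(brain), spec$tissue_mean, spec$tissue_sd)
  lesion_idx <- mask == 1L
  base[lesion_idx] <- base[lesion_idx] * spec$lesion_contrast
  vol <- base + rnorm(length(base), 0, spec$noise_sd)
  dim(vol) <- shape

  v <- fcd_volume(vol, spacing = spec$spacing)
  m <- fcd_mask(mask, affine = v$affine)
  list(
    volume = v, mask = m,
    meta = if (spec$lesion_count > 0) bind_rows(meta) else tibble(),
    brain = brain
  )
}

#' Generate a reproducible cohort of phantoms
#'
#' Draws `n` per-case phantom specifications from the given ranges —
#' emulating a cohort whose scans vary in matrix size and in-plane voxel
#' spacing — and generates each phantom from its own derived seed. Cases are
#' optionally written to disk as NIfTI pairs with a delimited-text manifest.
#'
#' @param n Number of cases.
#' @param dir Output directory for NIfTI pairs and `manifest.csv`; when
#'   `NULL` the cohort is kept in memory only.
#' @param seed Integer seed driving every random draw.
#' @param shape_range 2x3 matrix-like: row 1 minimum, row 2 maximum voxel
#'   extents (default in-plane 40-56, axial 28-36).
#' @param inplane_spacing_range In-plane spacing bounds in mm (default
#'   0.8-1.2).
#' @param axial_spacing Axial spacing in mm (default 1.0).
#' @param ... Further arguments passed to [phantom_spec()] (tissue model,
#'   lesion geometry, `frontal_bias`, ...).
#' @return A tibble of class `case_collection` with columns `case_id`,
#'   `image`, `mask` (paths, or `NA` for in-memory cohorts), `lesion_voxels`,
#'   `anterior`; in-memory cohorts carry the generated objects in a
#'   list-column `case`. The `provenance` attribute is `"synthetic"`.
#' @examples
#' coh <- generate_cohort(3, seed = 42)
#' coh$lesion_voxels
#' @export
generate_cohort <- function(n, dir = NULL, seed = 1L,
                            shape_range = rbind(c(40, 40, 28), c(56, 56, 36)),
                            inplane_spacing_range = c(0.8, 1.2),
                            axial_spacing = 1.0,
                            ...) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_fcd("n must be >= 1", "value")
  draws <- withr::with_seed(seed, {
    list(
      shapes = vapply(
        1:3,
        function(ax) {
          lo <- shape_range[1, ax]
          hi <- shape_range[2, ax]
          # avoid sample()'s scalar-expansion pitfall when lo == hi
          as.integer(lo) + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L
        },
        integer(n)
      ),
      inplane = runif(n, inplane_spacing_range[1], inplane_spacing_range[2]),
      seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  shapes <- matrix(draws$shapes, nrow = n)

  cases <- map(seq_len(n), function(i) {
    spec <- phantom_spec(
      shape = shapes[i, ],
      spacing = c(draws$inplane[i], draws$inplane[i], axial_spacing),
      seed = draws$seeds[i],
      ...
    )
    generate_phantom(spec)
  })

  ids <- sprintf("case_%03d", seq_len(n))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    img_paths <- file.path(dir, paste0(ids, "_flair.nii.gz"))
    mask_paths <- file.path(dir, paste0(ids, "_mask.nii.gz"))
    for (i in seq_len(n)) {
      write_volume(cases[[i]]$volume, img_paths[i])
      write_volume(cases[[i]]$mask, mask_paths[i])
    }
  } else {
    img_paths <- rep(NA_character_, n)
    mask_paths <- rep(NA_character_, n)
  }

  manifest <- tibble(
    case_id = ids,
    image = img_paths,
    mask = mask_paths,
    lesion_voxels = map_dbl(cases, ~ sum(.x$mask$data)),
    anterior = map_dbl(cases, ~ mean(.x$meta$anterior))
  )
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  } else {
    manifest$case <- cases
  }
  structure(manifest, provenance = "synthetic",
            class = c("case_collection", class(manifest)))
}
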