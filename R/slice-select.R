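#' Score axial slices for lesion-focused selection
#'
#' Because only a subset of axial slices carries visible lesion signal, the
#' pipeline ranks slices and keeps the most informative ones. Two criteria
#' are provided: `"lesion_area"` scores each slice by its lesion-voxel count
#' (the default when a ground-truth mask is available, e.g. for training
#' data), `"peak_intensity"` by the maximum FLAIR intensity in the slice
#' (mask-free, usable at inference), and `"lesion_intensity"` by the sum of
#' image intensity under the mask.
#'
#' @param v An [fcd_volume].
#' @param m An [fcd_mask] voxel-aligned with `v`; required for the mask-based
#'   criteria.
#' @param criterion One of `"lesion_area"`, `"peak_intensity"`,
#'   `"lesion_intensity"`.
#' @return A `slice_ranking` object (scores per slice, in slice order;
#'   selection unset until [select_top_k()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 2))
#' rk <- score_slices(ph$volume, ph$mask, "lesion_area")
#' tidy(rk)
#' @export
score_slices <- function(v, m = NULL,
                         criterion = c("lesion_area", "peak_intensity",
                                       "lesion_intensity")) {
  stopifnot(inherits(v, "fcd_volume"))
  criterion <- match.arg(criterion)
  axis <- v$axial_axis
  nz <- n_axial_slices(v)
  if (criterion != "peak_intensity") {
    if (is.null(m)) {
      stop_fcd(
        sprintf("criterion '%s' requires a lesion mask", criterion), "config"
      )
    }
    stopifnot(inherits(m, "fcd_mask"))
    if (!same_shape(v$data, m$data)) {
      stop_fcd("volume and mask are not voxel-aligned", "geometry")
    }
  }
  scores <- switch(criterion,
    peak_intensity = vapply(
      seq_len(nz), function(z) max(axial_slice(v$data, axis, z)), numeric(1)
    ),
    lesion_area = vapply(
      seq_len(nz), function(z) sum(axial_slice(m$data, axis, z)), numeric(1)
    ),
    lesion_intensity = vapply(
      seq_len(nz),
      function(z) sum(axial_slice(v$data, axis, z) * axial_slice(m$data, axis, z)),
      numeric(1)
    )
  )
  structure(
    list(scores = scores, criterion = criterion, selected = integer(0),
         k = NA_integer_, axial_axis = axis),
    class = "slice_ranking"
  )
}

#' Select the top-k ranked slices
#'
#' Keeps the `k` slices with the largest scores; ties are broken toward the
#' lower slice index and the selection is returned in ascending (anatomical)
#' order. When `k` is at least the slice count, every slice is selected.
#' Slice indices are 1-based.
#'
#' @param ranking A `slice_ranking` from [score_slices()].
#' @param k Number of slices to keep (default 5).
#' @return The ranking with `selected` and `k` filled in.
#' @examples
#' rk <- structure(
#'   list(scores = c(5, 1, 9, 3, 7), criterion = "peak_intensity",
#'        selected = integer(0), k = NA_integer_, axial_axis = 3L),
#'   class = "slice_ranking"
#' )
#' select_top_k(rk, 3)$selected  # 1, 3, 5
#' @export
select_top_k <- function(ranking, k = 5L) {
  stopifnot(inherits(ranking, "slice_ranking"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_fcd("k must be a positive integer", "value")
  n <- length(ranking$scores)
  ord <- order(-ranking$scores, seq_len(n))
  ranking$selected <- sort(ord[seq_len(min(k, n))])
  ranking$k <- k
  ranking
}

#' Compile selected axial slices into a slab
#'
#' Extracts the selected slices from the image and mask and stacks them, in
#' ascending slice order, into a new smaller 3D volume pair ("slab"). The
#' in-plane geometry is unchanged; the axial translation of the affine is
#' moved to the first selected slice's world position and the nominal axial
#' spacing is retained even when the selected slices are non-adjacent (the
#' true inter-slice gaps are recorded in the `slice_gaps` attribute).
#'
#' @param v An [fcd_volume].
#' @param m The aligned [fcd_mask].
#' @param selected Ascending 1-based slice indices, within bounds.
#' @return A list with `volume` and `mask` slabs.
#' @export
extract_slab <- function(v, m, selected) {
  stopifnot(inherits(v, "fcd_volume"), inherits(m, "fcd_mask"))
  selected <- as.integer(selected)
  nz <- n_axial_slices(v)
  if (length(selected) == 0L) stop_fcd("no slices selected", "value")
  if (is.unsorted(selected, strictly = TRUE)) {
    stop_fcd("selected slice indices must be strictly ascending", "value")
  }
  if (any(selected < 1L) || any(selected > nz)) {
    stop_fcd(
      sprintf("selected slice index out of bounds 1..%d", nz), "index"
    )
  }
  axis <- v$axial_axis
  affine <- v$affine
  step <- numeric(3)
  step[axis] <- selected[1] - 1
  affine[, 4] <- affine %*% c(step, 1)
  slab_v <- fcd_volume(take_axial(v$data, axis, selected), affine = affine,
                       axial_axis = axis)
  slab_m <- fcd_mask(take_axial(m$data, axis, selected), affine = affine,
                     axial_axis = axis)
  attr(slab_v, "slice_gaps") <- diff(selected)
  attr(slab_v, "source_slices") <- selected
  list(volume = slab_v, mask = slab_m)
}

#' Score, rank and extract the top-k axial slices for one case
#'
#' Composition of [score_slices()], [select_top_k()] and [extract_slab()]:
#' the standard lesion-focused slab compilation applied to every training
#' case (default: the five highest-ranked slices).
#'
#' @inheritParams score_slices
#' @param k Number of slices to keep (default 5).
#' @return A list with `volume`, `mask` (the slabs) and `ranking`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 20), seed = 4))
#' sel <- select_case(ph$volume, ph$mask)
#' dim(sel$volume)
#' @export
select_case <- function(v, m, criterion = "lesion_area", k = 5L) {
  ranking <- score_slices(v, m, criterion)
  ranking <- select_top_k(ranking, k)
  slab <- extract_slab(v, m, ranking$selected)
  list(volume = slab$volume, mask = slab$mask, ranking = ranking)
}

#' @export
print.slice_ranking <- function(x, ...) {
  cat(sprintf(
    "<slice_ranking> criterion '%s', %d slices%s\n",
    x$criterion, length(x$scores),
    if (length(x$selected)) {
      sprintf(", selected: %s", paste(x$selected, collapse = ", "))
    } else {
      " (no selection yet)"
    }
  ))
  invisible(x)
}

#' Tidy a slice ranking into a tibble
#'
#' @param x A `slice_ranking`.
#' @param ... Unused.
#' @return A tibble with columns `slice`, `score`, `selected`.
#' @export
tidy.slice_ranking <- function(x, ...) {
  tibble(
    slice = seq_along(x$scores),
    score = x$scores,
    selected = seq_along(x$scores) %in% x$selected
  )
}

#' Plot per-slice scores with the selected slices highlighted
#'
#' @param object A `slice_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slice_ranking <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$slice, y = .data$score, fill = .data$selected)) +
    geom_col() +
    scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    labs(
      x = "axial slice", y = paste0("score (", object$criterion, ")"),
      fill = "selected"
    ) +
    theme_minimal()
}
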