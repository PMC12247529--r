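#' Metric configuration for the pseudo-Dice family
#'
#' @param epsilon Small positive smoothing constant added to stabilize the
#'   Dice ratio for tiny or empty lesions (default 1e-5, small relative to
#'   any plausible lesion volume in voxels).
#' @param pds_variant Placement of the smoothing constant. `"as_printed"`
#'   (default) computes `2 * (|A∩B| + eps) / (|A| + |B| + eps)`; note this
#'   form can exceed 1 (it is bounded by 2, and equals 2 when both masks are
#'   empty). `"standard_smooth"` computes the conventional smoothed Dice
#'   `(2 * |A∩B| + eps) / (|A| + |B| + eps)`, which stays in `[0, 1]`.
#' @param window Window size `w` for the moving-average pseudo-Dice
#'   (default 10 epochs).
#' @return A list of class `fcd_metric_config`.
#' @export
metric_config <- function(epsilon = 1e-5,
                          pds_variant = c("as_printed", "standard_smooth"),
                          window = 10L) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop_fcd("epsilon must be > 0", "value")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_fcd("window must be >= 1", "value")
  structure(
    list(epsilon = epsilon, pds_variant = match.arg(pds_variant),
         window = window),
    class = "fcd_metric_config"
  )
}

mask_counts <- function(A, B) {
  a <- as_mask_array(A)
  b <- as_mask_array(B)
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop_fcd("masks must have identical shapes", "geometry")
  }
  list(a = sum(a == 1), b = sum(b == 1), ab = sum(a == 1 & b == 1))
}

#' Dice similarity coefficient
#'
#' Overlap between a predicted segmentation `A` and the ground truth `B`:
#' `DSC = 2 |A∩B| / (|A| + |B|)`, where `|.|` counts 1-voxels. 1 means
#' perfect overlap, 0 means none. Undefined (an error) when both masks are
#' empty; use [pseudo_dice()] for a total function.
#'
#' @param A,B [fcd_mask] objects (or 0/1 arrays) of identical shape.
#' @return A scalar in `[0, 1]`.
#' @examples
#' a <- array(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), c(10, 1, 1))
#' b <- array(c(0, 1, 1, 1, 1, 1, 1, 0, 0, 0), c(10, 1, 1))
#' dice(a, b) # 2*3 / (4+6) = 0.6
#' @export
dice <- function(A, B) {
  cnt <- mask_counts(A, B)
  if (cnt$a + cnt$b == 0) {
    stop_fcd("Dice is undefined for two empty masks (division by zero)", "metric")
  }
  2 * cnt$ab / (cnt$a + cnt$b)
}

#' Pseudo-Dice score
#'
#' The smoothing-stabilized Dice variant used to score small or empty lesion
#' volumes, where the plain Dice ratio is undefined or unstable. See
#' [metric_config()] for the two placements of the smoothing constant and
#' their ranges.
#'
#' @inheritParams dice
#' @param cfg A [metric_config()].
#' @return A scalar; in `[0, 1]` for `"standard_smooth"`, in `[0, 2]` for
#'   `"as_printed"`.
#' @examples
#' e <- array(0, c(4, 4, 4))
#' pseudo_dice(e, e)                                        # 2 (as printed)
#' pseudo_dice(e, e, metric_config(pds_variant = "standard_smooth")) # 1
#' @export
pseudo_dice <- function(A, B, cfg = metric_config()) {
  cnt <- mask_counts(A, B)
  eps <- cfg$epsilon
  switch(cfg$pds_variant,
    as_printed = 2 * (cnt$ab + eps) / (cnt$a + cnt$b + eps),
    standard_smooth = (2 * cnt$ab + eps) / (cnt$a + cnt$b + eps)
  )
}

#' Ordered trace of pseudo-Dice scores
#'
#' Holds the sequence `PDS_i` indexed by epoch/iteration (or by test case),
#' as produced during cross-validation.
#'
#' @param values Finite numeric vector, length >= 1.
#' @return A numeric vector of class `score_trace`.
#' @export
score_trace <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_fcd("a score trace cannot be empty", "value")
  if (any(!is.finite(values))) stop_fcd("score trace values must be finite", "value")
  structure(values, class = "score_trace")
}

#' Mean pseudo-Dice of a trace
#'
#' Arithmetic mean of the `PDS_i` values, summarizing performance across all
#' samples (or epochs) in one number.
#'
#' @param trace A [score_trace()] or numeric vector.
#' @return A scalar.
#' @export
mean_pds <- function(trace) {
  vals <- unclass(trace)
  if (length(vals) == 0L) stop_fcd("cannot average an empty trace", "value")
  if (any(!is.finite(vals))) stop_fcd("trace values must be finite", "value")
  mean(vals)
}

#' Moving-average pseudo-Dice
#'
#' Windowed mean of the trace used to monitor training stability: the mean
#' of the `w` most recent values ending at position `t` (1-based, inclusive:
#' positions `t - w + 1 .. t`).
#'
#' @param trace A [score_trace()] or numeric vector.
#' @param w Window size, `1 <= w <= t`.
#' @param t Current epoch/iteration, `t <= length(trace)`.
#' @return A scalar.
#' @examples
#' moving_average_pds(c(0.1, 0.2, 0.3, 0.4), w = 2, t = 4) # 0.35
#' @export
moving_average_pds <- function(trace, w, t) {
  vals <- unclass(trace)
  w <- as.integer(w)
  t <- as.integer(t)
  if (is.na(t) || t < 1L || t > length(vals)) {
    stop_fcd(sprintf("t must lie in 1..%d", length(vals)), "index")
  }
  if (is.na(w) || w < 1L || w > t) {
    stop_fcd("window w must satisfy 1 <= w <= t", "value")
  }
  mean(vals[(t - w + 1L):t])
}

#' Full moving-average trace
#'
#' Convenience wrapper returning the moving average at every epoch, using a
#' truncated window for the first `w - 1` epochs.
#'
#' @inheritParams moving_average_pds
#' @return Numeric vector, same length as `trace`.
#' @export
moving_average_trace <- function(trace, w = 10L) {
  vals <- unclass(trace)
  vapply(
    seq_along(vals),
    function(t) moving_average_pds(vals, min(w, t), t),
    numeric(1)
  )
}

# half-up rounding at `digits` decimals, the convention used in report tables
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.score_trace <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf(
    "<score_trace> %d values, mean %.3f, final %.3f\n",
    length(v), mean(v), v[length(v)]
  ))
  invisible(x)
}

#' Per-case metric report
#'
#' Evaluates Dice and pseudo-Dice for a set of prediction/truth mask pairs
#' and returns one row per case.
#'
#' @param predictions,truths Lists of [fcd_mask] objects (or 0/1 arrays),
#'   matched by position.
#' @param cfg A [metric_config()].
#' @param case_ids Optional character vector of identifiers.
#' @return A tibble with columns `case_id`, `dice`, `pseudo_dice`.
#' @export
metric_report <- function(predictions, truths, cfg = metric_config(),
                          case_ids = NULL) {
  stopifnot(length(predictions) == length(truths))
  case_ids <- case_ids %||% sprintf("case_%03d", seq_along(predictions))
  tibble(
    case_id = case_ids,
    dice = map_dbl(seq_along(predictions), function(i) {
      cnt <- mask_counts(predictions[[i]], truths[[i]])
      if (cnt$a + cnt$b == 0) NA_real_ else 2 * cnt$ab / (cnt$a + cnt$b)
    }),
    pseudo_dice = map_dbl(
      seq_along(predictions),
      function(i) pseudo_dice(predictions[[i]], truths[[i]], cfg)
    )
  )
}
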