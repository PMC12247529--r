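#' Pluggable segmenters for the cross-validation harness
#'
#' The harness treats the segmentation model as an interchangeable component
#' behind a single fitting interface, so the pipeline and its evaluation can
#' be exercised without the full deep-learning framework the study model
#' belongs to. Three bindings are provided:
#'
#' * `segmenter_threshold()` — a deterministic intensity-threshold segmenter:
#'   on (normalized) training slabs it grid-searches the threshold that
#'   maximizes mean training Dice, and predicts lesion = voxels above it.
#'   Because FLAIR lesions are the brightest structure, this recovers
#'   hyperintense blobs well. A linear annealing schedule from threshold 0
#'   to the fitted value produces a nontrivial, improving per-epoch
#'   validation trace. No randomness is involved.
#' * `segmenter_logistic()` — a small trainable model: voxelwise logistic
#'   regression on intensity, fitted by minibatch stochastic gradient
#'   descent with momentum and optional Nesterov acceleration (the training
#'   schedule fields of [train_config()]), shuffling cases each epoch from
#'   the run seed.
#' * `segmenter_nnunet()` — an adapter for an externally installed nnU-Net:
#'   fitting errors with an install hint when the executable is absent;
#'   [parse_nnunet_progress()] extracts per-epoch pseudo-Dice values from
#'   its progress log.
#'
#' @param thresholds Candidate thresholds (in normalized intensity units)
#'   for the grid search.
#' @return A segmenter object usable as `train_config(segmenter = )`.
#' @name segmenters
NULL

#' @rdname segmenters
#' @export
segmenter_threshold <- function(thresholds = seq(0.5, 4, by = 0.1)) {
  structure(
    list(name = "toy_threshold", thresholds = thresholds),
    class = c("fcd_segmenter_threshold", "fcd_segmenter")
  )
}

#' @rdname segmenters
#' @export
segmenter_logistic <- function() {
  structure(
    list(name = "toy_logistic"),
    class = c("fcd_segmenter_logistic", "fcd_segmenter")
  )
}

#' @rdname segmenters
#' @param command Name of the external training executable to look up on the
#'   PATH.
#' @export
segmenter_nnunet <- function(command = "nnUNetv2_train") {
  structure(
    list(name = "external_nnunet", command = command),
    class = c("fcd_segmenter_nnunet", "fcd_segmenter")
  )
}

as_segmenter <- function(x) {
  if (inherits(x, "fcd_segmenter")) return(x)
  switch(as.character(x),
    toy_threshold = segmenter_threshold(),
    toy_logistic = segmenter_logistic(),
    external_nnunet = segmenter_nnunet(),
    stop_fcd(sprintf("unknown segmenter '%s'", x), "config")
  )
}

#' Fit a segmenter on training cases and trace validation pseudo-Dice
#'
#' Generic entry point used by [run_fold()]: trains (or fits) the segmenter
#' on the training cases and evaluates the mean validation pseudo-Dice after
#' each epoch.
#'
#' @param segmenter A segmenter object (see [segmenters]).
#' @param train,val Lists of prepared cases, each a list with `volume` (the
#'   preprocessed, slab-extracted [fcd_volume]) and `mask` (the matching
#'   [fcd_mask]).
#' @param cfg A [train_config()].
#' @param metric_cfg A [metric_config()].
#' @param seed Integer seed for any stochastic training component.
#' @return A list with `trace` (a [score_trace()] of length `cfg$epochs`),
#'   `predictions` (final-epoch [fcd_mask] predictions for `val`), and
#'   `per_case` (tibble of final-epoch per-case dice/pseudo-dice).
#' @export
fit_segmenter <- function(segmenter, train, val, cfg, metric_cfg = metric_config(),
                          seed = 1L) {
  UseMethod("fit_segmenter")
}

val_epoch_pds <- function(preds, val, metric_cfg) {
  mean(map_dbl(seq_along(val), function(i) {
    pseudo_dice(preds[[i]], val[[i]]$mask, metric_cfg)
  }))
}

final_report <- function(preds, val, metric_cfg) {
  metric_report(
    preds, map(val, "mask"), metric_cfg,
    case_ids = map_chr_default(val)
  )
}

map_chr_default <- function(val) {
  ids <- map(val, "case_id")
  if (any(vapply(ids, is.null, logical(1)))) {
    sprintf("case_%03d", seq_along(val))
  } else {
    unlist(ids)
  }
}

#' @export
fit_segmenter.fcd_segmenter_threshold <- function(segmenter, train, val, cfg,
                                                  metric_cfg = metric_config(),
                                                  seed = 1L) {
  if (length(train) == 0L) stop_fcd("empty training split", "value")
  # fit: threshold maximizing mean training dice
  mean_train_dice <- function(thr) {
    mean(map_dbl(train, function(cs) {
      pred <- cs$volume$data > thr
      cnt_a <- sum(pred)
      cnt_b <- sum(cs$mask$data)
      if (cnt_a + cnt_b == 0) return(1)
      2 * sum(pred & (cs$mask$data == 1L)) / (cnt_a + cnt_b)
    }))
  }
  fit_scores <- vapply(segmenter$thresholds, mean_train_dice, numeric(1))
  thr_fit <- segmenter$thresholds[which.max(fit_scores)]

  epochs <- cfg$epochs
  trace <- numeric(epochs)
  preds <- NULL
  for (e in seq_len(epochs)) {
    # annealing schedule: linear path from 0 to the fitted threshold
    thr_e <- if (epochs == 1L) thr_fit else thr_fit * e / epochs
    preds <- map(val, function(cs) {
      binarize_mask(array(as.numeric(cs$volume$data > thr_e), dim(cs$volume$data)),
                    geometry = cs$volume)
    })
    trace[e] <- val_epoch_pds(preds, val, metric_cfg)
  }
  list(
    trace = score_trace(trace),
    predictions = preds,
    per_case = final_report(preds, val, metric_cfg),
    fitted = list(threshold = thr_fit)
  )
}

#' @export
fit_segmenter.fcd_segmenter_logistic <- function(segmenter, train, val, cfg,
                                                 metric_cfg = metric_config(),
                                                 seed = 1L) {
  if (length(train) == 0L) stop_fcd("empty training split", "value")
  withr::with_seed(seed, {
    w <- 0
    b <- 0
    vw <- 0
    vb <- 0
    lr <- cfg$learning_rate
    mom <- cfg$momentum
    epochs <- cfg$epochs
    trace <- numeric(epochs)
    preds <- NULL
    for (e in seq_len(epochs)) {
      idx <- sample(length(train))
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      for (batch in batches) {
        x <- unlist(map(train[batch], ~ as.vector(.x$volume$data)))
        ylab <- unlist(map(train[batch], ~ as.vector(.x$mask$data)))
        # nesterov look-ahead evaluation point
        we <- if (cfg$nesterov) w + mom * vw else w
        be <- if (cfg$nesterov) b + mom * vb else b
        p <- 1 / (1 + exp(-(we * x + be)))
        gw <- mean((p - ylab) * x)
        gb <- mean(p - ylab)
        vw <- mom * vw - lr * gw
        vb <- mom * vb - lr * gb
        w <- w + vw
        b <- b + vb
      }
      preds <- map(val, function(cs) {
        p <- 1 / (1 + exp(-(w * cs$volume$data + b)))
        binarize_mask(array(as.numeric(p > 0.5), dim(cs$volume$data)),
                      geometry = cs$volume)
      })
      trace[e] <- val_epoch_pds(preds, val, metric_cfg)
    }
    list(
      trace = score_trace(trace),
      predictions = preds,
      per_case = final_report(preds, val, metric_cfg),
      fitted = list(weight = w, bias = b)
    )
  })
}

#' @export
fit_segmenter.fcd_segmenter_nnunet <- function(segmenter, train, val, cfg,
                                               metric_cfg = metric_config(),
                                               seed = 1L) {
  if (!nzchar(Sys.which(segmenter$command))) {
    stop_fcd(
      sprintf(
        paste0(
          "external segmenter '%s' is not on the PATH; install nnU-Net ",
          "(e.g. `pip install nnunetv2`) or choose a built-in segmenter"
        ),
        segmenter$command
      ),
      "adapter"
    )
  }
  stop_fcd(
    "driving an external nnU-Net training run is not implemented; use parse_nnunet_progress() on its log",
    "adapter"
  )
}

#' Parse per-epoch pseudo-Dice values from an nnU-Net progress log
#'
#' Scans training-log lines for epoch markers and "Pseudo dice" entries and
#' returns the per-epoch trace, so externally trained models can be
#' summarized with the same fold statistics as the built-in segmenters.
#'
#' @param lines Character vector of log lines.
#' @return A tibble with columns `epoch` and `pseudo_dice`.
#' @examples
#' log <- c(
#'   "2024-01-01 10:00:00.0: Epoch 0",
#'   "2024-01-01 10:01:00.0: Pseudo dice [0.31]",
#'   "2024-01-01 10:02:00.0: Epoch 1",
#'   "2024-01-01 10:03:00.0: Pseudo dice [0.42]"
#' )
#' parse_nnunet_progress(log)
#' @export
parse_nnunet_progress <- function(lines) {
  epoch_pat <- "[Ee]poch[[:space:]]+([0-9]+)[[:space:]]*$"
  dice_pat <- "[Pp]seudo dice.*?([0-9]*\\.?[0-9]+)"
  cur_epoch <- NA_integer_
  out <- list()
  for (ln in lines) {
    em <- regmatches(ln, regexec(epoch_pat, ln))[[1]]
    if (length(em) == 2L) {
      cur_epoch <- as.integer(em[2])
      next
    }
    dm <- regmatches(ln, regexec(dice_pat, ln))[[1]]
    if (length(dm) == 2L) {
      out[[length(out) + 1L]] <- tibble(
        epoch = cur_epoch, pseudo_dice = as.numeric(dm[2])
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(epoch = integer(0), pseudo_dice = numeric(0)))
  }
  bind_rows(out)
}
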