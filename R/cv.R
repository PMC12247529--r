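#' Training schedule and model choice for a cross-validation run
#'
#' Defaults follow the study schedule: 100 epochs, batch size 4, learning
#' rate 0.01, SGD momentum 0.99 with Nesterov acceleration. The `segmenter`
#' is pluggable (see [segmenters]); the deterministic threshold segmenter is
#' the default so runs are cheap and reproducible.
#'
#' @param epochs Number of training epochs (default 100).
#' @param batch_size Cases per minibatch (default 4).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.99).
#' @param nesterov Use Nesterov acceleration (default TRUE).
#' @param segmenter A segmenter object or one of `"toy_threshold"`,
#'   `"toy_logistic"`, `"external_nnunet"`.
#' @return A list of class `fcd_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L, learning_rate = 0.01,
                         momentum = 0.99, nesterov = TRUE,
                         segmenter = "toy_threshold") {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 1L) stop_fcd("epochs must be >= 1", "value")
  if (is.na(batch_size) || batch_size < 1L) stop_fcd("batch_size must be >= 1", "value")
  if (learning_rate <= 0) stop_fcd("learning_rate must be > 0", "value")
  structure(
    list(
      epochs = epochs, batch_size = batch_size, learning_rate = learning_rate,
      momentum = momentum, nesterov = isTRUE(nesterov),
      segmenter = as_segmenter(segmenter)
    ),
    class = "fcd_train_config"
  )
}

#' Assign cases to balanced cross-validation folds
#'
#' Random balanced assignment: fold sizes differ by at most one and every
#' case appears in exactly one fold. Deterministic given `seed`.
#'
#' @param cases A `case_collection` tibble (see [generate_cohort()]) or any
#'   data frame with a `case_id` column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of class `fold_plan` with `k`, `seed` and `assignments`
#'   (tibble `case_id`, `fold`).
#' @examples
#' coh <- generate_cohort(7, seed = 9)
#' table(make_folds(coh, k = 5, seed = 1)$assignments$fold)
#' @export
make_folds <- function(cases, k = 5L, seed = 1L) {
  ids <- cases$case_id
  if (anyDuplicated(ids)) stop_fcd("case_ids must be unique", "value")
  n <- length(ids)
  k <- as.integer(k)
  if (n < k) {
    stop_fcd(sprintf("cannot split %d cases into %d folds", n, k), "value")
  }
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  structure(
    list(k = k, seed = as.integer(seed),
         assignments = tibble(case_id = ids, fold = folds)),
    class = "fold_plan"
  )
}

#' Preprocess and slice-select every case of a collection
#'
#' Applies [preprocess_case()] and [select_case()] to each case, returning
#' the prepared slabs the segmenters train on. Cases are read from disk when
#' the collection holds file paths, or taken from the in-memory `case`
#' column.
#'
#' @param cases A `case_collection`.
#' @param pre_cfg A [preprocess_config()].
#' @param criterion,k Slice-selection settings (see [select_case()]).
#' @return A named list (by `case_id`) of prepared cases: `volume`, `mask`,
#'   `ranking`, `case_id`.
#' @export
prepare_cases <- function(cases, pre_cfg = preprocess_config(),
                          criterion = "lesion_area", k = 5L) {
  prepared <- map(seq_len(nrow(cases)), function(i) {
    if ("case" %in% names(cases) && !is.null(cases$case[[i]])) {
      v <- cases$case[[i]]$volume
      m <- cases$case[[i]]$mask
    } else {
      v <- read_volume(cases$image[i])
      m <- read_mask(cases$mask[i], reference = v)
    }
    pp <- preprocess_case(v, m, pre_cfg)
    sel <- select_case(pp$volume, pp$mask, criterion = criterion, k = k)
    list(volume = sel$volume, mask = sel$mask, ranking = sel$ranking,
         case_id = cases$case_id[i])
  })
  names(prepared) <- cases$case_id
  prepared
}

#' Run one cross-validation fold
#'
#' Trains the configured segmenter on the out-of-fold cases and evaluates
#' the mean validation pseudo-Dice after every epoch, yielding the fold's
#' score trace and its summary (mean of the trace; trace value at the final
#' epoch). Fully reproducible given `seed` and the configuration.
#'
#' @param prepared Named list from [prepare_cases()].
#' @param plan A [make_folds()] plan.
#' @param fold_id Which fold (1..k) is held out for validation.
#' @param cfg A [train_config()].
#' @param metric_cfg A [metric_config()].
#' @param seed Integer seed for stochastic segmenters.
#' @return A list of class `fold_result`: `fold_id`, `trace`
#'   ([score_trace()] of length `cfg$epochs`), `summary` (one-row tibble
#'   `fold`, `mean_pds`, `pds_at_final`), `per_case`.
#' @export
run_fold <- function(prepared, plan, fold_id, cfg = train_config(),
                     metric_cfg = metric_config(), seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"))
  fold_id <- as.integer(fold_id)
  if (!fold_id %in% seq_len(plan$k)) {
    stop_fcd(sprintf("fold_id must lie in 1..%d", plan$k), "value")
  }
  assign <- plan$assignments
  val_ids <- assign$case_id[assign$fold == fold_id]
  train_ids <- assign$case_id[assign$fold != fold_id]
  if (length(train_ids) == 0L) stop_fcd("empty training split", "value")
  if (length(val_ids) == 0L) stop_fcd("empty validation split", "value")

  fit <- fit_segmenter(cfg$segmenter, prepared[train_ids], prepared[val_ids],
                       cfg, metric_cfg, seed = seed + fold_id)
  trace <- fit$trace
  structure(
    list(
      fold_id = fold_id,
      trace = trace,
      summary = tibble(
        fold = fold_id,
        mean_pds = mean_pds(trace),
        pds_at_final = unclass(trace)[length(trace)]
      ),
      per_case = fit$per_case,
      fitted = fit$fitted
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result> fold %d: mean PDS %.3f, final-epoch PDS %.3f (%d epochs)\n",
    x$fold_id, x$summary$mean_pds, x$summary$pds_at_final,
    length(unclass(x$trace))
  ))
  invisible(x)
}

#' Tidy a fold result into a per-epoch tibble
#'
#' @param x A `fold_result`.
#' @param window Moving-average window (default 10).
#' @param ... Unused.
#' @return A tibble with columns `fold`, `epoch`, `pseudo_dice`,
#'   `moving_average`.
#' @export
tidy.fold_result <- function(x, window = 10L, ...) {
  vals <- unclass(x$trace)
  tibble(
    fold = x$fold_id,
    epoch = seq_along(vals),
    pseudo_dice = vals,
    moving_average = moving_average_trace(vals, window)
  )
}

#' Summarize a cross-validation study
#'
#' Builds the fold-level results table (one row per fold: mean pseudo-Dice
#' over training and pseudo-Dice at the final epoch) and the accompanying
#' statistical analysis: descriptive statistics and Student-t 95% confidence
#' intervals for both columns, and a two-sided paired t-test between them.
#' When the paired test is degenerate (identical folds) a warning is issued
#' and the table is still produced.
#'
#' @param results List of `fold_result` objects (or a tibble already shaped
#'   like the fold table with columns `fold`, `mean_pds`, `pds_at_final`),
#'   at least 2 folds.
#' @return A list of class `study_summary`: `fold_table`, `stats` (tibble of
#'   describe + CI per column) and `paired_test` (tibble or NULL).
#' @examples
#' ref <- fcd_reference_folds()
#' summarize_study(
#'   tibble::tibble(fold = ref$fold, mean_pds = ref$mean_pds,
#'                  pds_at_final = ref$final_pds)
#' )
#' @export
summarize_study <- function(results) {
  if (is.data.frame(results)) {
    fold_table <- as_tibble(results)
  } else {
    if (length(results) < 2L) {
      stop_fcd("need at least 2 folds to summarize a study", "value")
    }
    fold_table <- bind_rows(map(results, "summary"))
  }
  if (nrow(fold_table) < 2L) {
    stop_fcd("need at least 2 folds to summarize a study", "value")
  }

  col_stats <- function(vals, label) {
    desc <- describe_scores(vals)
    ci <- tryCatch(ci95(vals), fcdseg_error = function(e) c(lower = NA_real_,
                                                            upper = NA_real_))
    mutate(desc, metric = label, ci_lower = ci[["lower"]],
           ci_upper = ci[["upper"]], .before = 1)
  }
  stats_tbl <- bind_rows(
    col_stats(fold_table$mean_pds, "mean_pds"),
    col_stats(fold_table$pds_at_final, "pds_at_final")
  )

  test <- tryCatch(
    paired_t(fold_table$mean_pds, fold_table$pds_at_final),
    fcdseg_error_degenerate = function(e) {
      rlang::warn(paste("paired t-test skipped:", conditionMessage(e)))
      NULL
    }
  )

  structure(
    list(fold_table = fold_table, stats = stats_tbl, paired_test = test),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Five-fold cross-validation results\n")
  cat("Fold  Mean pseudo dice  Pseudo dice at final epoch\n")
  for (i in seq_len(nrow(x$fold_table))) {
    cat(sprintf(
      "%4d  %16.2f  %26.2f\n",
      x$fold_table$fold[i],
      round_half_up(x$fold_table$mean_pds[i]),
      round_half_up(x$fold_table$pds_at_final[i])
    ))
  }
  for (i in seq_len(nrow(x$stats))) {
    s <- x$stats[i, ]
    cat(sprintf(
      "%s: mean %.2f, sd %.2f, median %.2f, 95%% CI (%.2f, %.2f)\n",
      s$metric, round_half_up(s$mean), round_half_up(s$sd),
      round_half_up(s$median), round_half_up(s$ci_lower),
      round_half_up(s$ci_upper)
    ))
  }
  if (!is.null(x$paired_test)) {
    cat(sprintf(
      "paired t-test: t = %.2f, df = %d, p = %.2f\n",
      round_half_up(x$paired_test$statistic), x$paired_test$df,
      round_half_up(x$paired_test$p_value)
    ))
  }
  invisible(x)
}

#' @export
tidy.study_summary <- function(x, ...) x$fold_table

#' @export
glance.study_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$stats,
    names_from = "metric",
    values_from = c("mean", "sd", "median", "ci_lower", "ci_upper", "n")
  )
  if (!is.null(x$paired_test)) {
    wide$t_statistic <- x$paired_test$statistic
    wide$t_df <- x$paired_test$df
    wide$t_p_value <- x$paired_test$p_value
  }
  wide
}

#' Plot per-epoch validation traces across folds
#'
#' @param object A list of `fold_result` objects or a single one.
#' @param window Moving-average window.
#' @param ... Unused.
#' @return A ggplot of pseudo-Dice and its moving average against epoch,
#'   one panel per fold.
#' @export
plot_traces <- function(object, window = 10L, ...) {
  results <- if (inherits(object, "fold_result")) list(object) else object
  df <- bind_rows(map(results, tidy, window = window))
  long <- tidyr::pivot_longer(df, c("pseudo_dice", "moving_average"),
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_wrap(~fold, labeller = ggplot2::label_both) +
    labs(x = "epoch", y = "validation pseudo-Dice", colour = NULL) +
    theme_minimal()
}

#' Run a full cross-validation study end to end
#'
#' Convenience wrapper: prepare every case (preprocess + slice selection),
#' build the fold plan, run each fold, and summarize. This is the end-to-end
#' pipeline from a case collection to the fold-level report.
#'
#' @param cases A `case_collection` (e.g. from [generate_cohort()]).
#' @param k Number of folds (default 5).
#' @param cfg,pre_cfg,metric_cfg Configurations.
#' @param criterion,slices Slice-selection criterion and slab size.
#' @param seed Integer seed.
#' @return A list of class `fcd_study`: `plan`, `folds` (list of
#'   `fold_result`), `summary` (a `study_summary`), `per_case` (tibble of
#'   final-epoch per-case metrics across all validation folds).
#' @export
run_study <- function(cases, k = 5L, cfg = train_config(),
                      pre_cfg = preprocess_config(),
                      metric_cfg = metric_config(),
                      criterion = "lesion_area", slices = 5L, seed = 1L) {
  prepared <- prepare_cases(cases, pre_cfg, criterion = criterion, k = slices)
  plan <- make_folds(cases, k = k, seed = seed)
  folds <- map(seq_len(k), function(f) {
    run_fold(prepared, plan, f, cfg, metric_cfg, seed = seed)
  })
  per_case <- bind_rows(
    map(folds, function(fr) mutate(fr$per_case, fold = fr$fold_id))
  )
  structure(
    list(plan = plan, folds = folds, summary = summarize_study(folds),
         per_case = per_case),
    class = "fcd_study"
  )
}

#' @export
print.fcd_study <- function(x, ...) {
  cat(sprintf("<fcd_study> %d folds, %d cases\n",
              x$plan$k, nrow(x$plan$assignments)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.fcd_study <- function(x, ...) x$summary$fold_table

#' @export
glance.fcd_study <- function(x, ...) glance(x$summary)

#' @export
autoplot.fcd_study <- function(object, window = 10L, ...) {
  plot_traces(object$folds, window = window)
}
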