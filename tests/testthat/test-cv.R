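make_cases <- function(n, seed = 1) generate_cohort(n, seed = seed)

test_that("fold assignment is balanced, exhaustive and deterministic", {
  ids <- tibble::tibble(case_id = sprintf("s%03d", 1:85))
  plan <- make_folds(ids, k = 5, seed = 11)
  sizes <- table(plan$assignments$fold)
  expect_true(all(sizes == 17))
  # partition: every case in exactly one fold
  expect_identical(sort(plan$assignments$case_id), sort(ids$case_id))

  small <- tibble::tibble(case_id = letters[1:7])
  sizes7 <- sort(as.integer(table(make_folds(small, 5, 1)$assignments$fold)))
  expect_identical(sizes7, c(1L, 1L, 1L, 2L, 2L))

  expect_identical(make_folds(ids, 5, 3)$assignments,
                   make_folds(ids, 5, 3)$assignments)
  expect_false(identical(make_folds(ids, 5, 3)$assignments$fold,
                         make_folds(ids, 5, 4)$assignments$fold))

  expect_error(make_folds(tibble::tibble(case_id = c("a", "b")), k = 5),
               class = "fcdseg_error_value")
})

prepared_small <- local({
  coh <- make_cases(6, seed = 21)
  list(cases = coh, prepared = prepare_cases(coh))
})

test_that("a single-epoch fold has a one-value trace equal to its summary", {
  plan <- make_folds(prepared_small$cases, k = 3, seed = 2)
  fr <- run_fold(prepared_small$prepared, plan, 1,
                 train_config(epochs = 1), seed = 5)
  expect_length(unclass(fr$trace), 1L)
  expect_equal(fr$summary$mean_pds, fr$summary$pds_at_final)
})

test_that("fold summaries are pure functions of the trace", {
  plan <- make_folds(prepared_small$cases, k = 3, seed = 2)
  fr <- run_fold(prepared_small$prepared, plan, 2,
                 train_config(epochs = 12), seed = 5)
  expect_length(unclass(fr$trace), 12L)
  expect_equal(fr$summary$mean_pds, mean(unclass(fr$trace)), tolerance = 1e-12)
  expect_equal(fr$summary$pds_at_final, unclass(fr$trace)[12])
})

test_that("identical seeds and configurations give identical traces", {
  plan <- make_folds(prepared_small$cases, k = 3, seed = 2)
  cfg <- train_config(epochs = 8)
  a <- run_fold(prepared_small$prepared, plan, 1, cfg, seed = 9)
  b <- run_fold(prepared_small$prepared, plan, 1, cfg, seed = 9)
  expect_identical(unclass(a$trace), unclass(b$trace))

  cfg_log <- train_config(epochs = 4, segmenter = "toy_logistic")
  c1 <- run_fold(prepared_small$prepared, plan, 1, cfg_log, seed = 9)
  c2 <- run_fold(prepared_small$prepared, plan, 1, cfg_log, seed = 9)
  expect_identical(unclass(c1$trace), unclass(c2$trace))
  expect_true(all(is.finite(unclass(c1$trace))))
})

test_that("the threshold segmenter recovers hyperintense phantom lesions", {
  plan <- make_folds(prepared_small$cases, k = 3, seed = 2)
  fr <- run_fold(prepared_small$prepared, plan, 3,
                 train_config(epochs = 10), seed = 1)
  expect_true(all(fr$per_case$dice >= 0.7))
})

test_that("study summaries reproduce the published statistics when fed the published folds", {
  ref <- fcd_reference_folds()
  st <- summarize_study(
    tibble::tibble(fold = ref$fold, mean_pds = ref$mean_pds,
                   pds_at_final = ref$final_pds)
  )
  stats <- st$stats
  mp <- stats[stats$metric == "mean_pds", ]
  expect_equal(round_half_up(c(mp$mean, mp$sd, mp$median)), c(0.37, 0.07, 0.35))
  expect_equal(round_half_up(c(mp$ci_lower, mp$ci_upper)), c(0.28, 0.46))
  fp <- stats[stats$metric == "pds_at_final", ]
  expect_equal(round_half_up(c(fp$mean, fp$sd, fp$median)), c(0.45, 0.05, 0.42))
  expect_equal(round_half_up(c(fp$ci_lower, fp$ci_upper)), c(0.39, 0.51))
  expect_equal(round_half_up(st$paired_test$statistic), -3.06)
  expect_identical(st$paired_test$df, 4)

  out <- capture.output(print(st))
  expect_true(any(grepl("t = -3.06", out)))
})

test_that("degenerate and undersized studies are handled", {
  same <- tibble::tibble(fold = 1:3, mean_pds = rep(0.4, 3),
                         pds_at_final = rep(0.5, 3))
  expect_warning(st <- summarize_study(same), "degenerate|zero variance")
  expect_null(st$paired_test)
  expect_identical(nrow(st$fold_table), 3L)

  one <- tibble::tibble(fold = 1, mean_pds = 0.4, pds_at_final = 0.5)
  expect_error(summarize_study(one), class = "fcdseg_error_value")
})

test_that("slice selection enriches the study-level pseudo-Dice", {
  coh <- make_cases(8, seed = 33)
  cfg <- train_config(epochs = 10)
  with_sel <- run_study(coh, k = 4, cfg = cfg, slices = 5, seed = 2)
  # selection disabled: keep every axial slice, lesion diluted by empty slices
  without_sel <- run_study(coh, k = 4, cfg = cfg, slices = 10000, seed = 2)
  expect_gt(mean(with_sel$summary$fold_table$mean_pds),
            mean(without_sel$summary$fold_table$mean_pds))
})

test_that("tidiers and plots expose the study results", {
  coh <- make_cases(5, seed = 41)
  st <- run_study(coh, k = 5, cfg = train_config(epochs = 6), seed = 3)
  td <- tidy(st)
  expect_identical(nrow(td), 5L)
  expect_true(all(c("fold", "mean_pds", "pds_at_final") %in% names(td)))
  gl <- glance(st)
  expect_identical(nrow(gl), 1L)
  expect_true("t_statistic" %in% names(gl))
  expect_s3_class(autoplot(st), "ggplot")
  ep <- tidy(st$folds[[1]])
  expect_identical(nrow(ep), 6L)
  expect_true(all(c("epoch", "pseudo_dice", "moving_average") %in% names(ep)))
})
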