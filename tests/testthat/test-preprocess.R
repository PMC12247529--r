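test_that("resampling follows the closed-form shape rule", {
  v <- fcd_volume(array(rnorm(40^3, 100), c(40, 40, 40)), spacing = c(1, 1, 1))
  out <- resample_volume(v, c(2, 2, 2))
  expect_identical(dim(out), c(20L, 20L, 20L))
  expect_equal(out$spacing, c(2, 2, 2))
  # world extent preserved to within one voxel
  old_extent <- dim(v) * v$spacing
  new_extent <- dim(out) * out$spacing
  expect_true(all(abs(old_extent - new_extent) <= out$spacing))

  aniso <- fcd_volume(array(rnorm(24 * 30 * 10), c(24, 30, 10)),
                      spacing = c(0.5, 1, 3))
  out2 <- resample_volume(aniso, c(1, 1, 1))
  expect_identical(dim(out2), c(12L, 30L, 30L))
})

test_that("identity resampling and constants are preserved", {
  ph <- tiny_phantom(seed = 1)
  for (ord in 1:3) {
    same <- resample_volume(ph$volume, ph$volume$spacing, order = ord)
    expect_equal(same$data, ph$volume$data, tolerance = 1e-6)
  }
  const <- fcd_volume(array(7, c(12, 12, 12)), spacing = c(1, 1, 1))
  down <- resample_volume(const, c(1.7, 1.3, 2.1), order = 3)
  expect_true(all(abs(down$data - 7) < 1e-9))
})

test_that("non-positive target spacing is rejected", {
  ph <- tiny_phantom(seed = 2)
  expect_error(resample_volume(ph$volume, c(1, -1, 1)),
               class = "fcdseg_error_value")
})

test_that("mask resampling keeps labels binary and lesions non-empty", {
  ph <- tiny_phantom(seed = 3, lesion_radius_range = c(4, 5))
  down <- resample_volume(ph$mask, c(2, 2, 2))
  expect_true(all(down$data %in% c(0L, 1L)))
  expect_gt(sum(down$data), 0)
  up <- resample_volume(ph$mask, c(0.8, 0.8, 0.8))
  expect_true(all(up$data %in% c(0L, 1L)))
})

test_that("skull stripping recovers the phantom brain and is degenerate-safe", {
  ph <- tiny_phantom(seed = 4)
  ss <- skull_strip(ph$volume)
  truth <- array(as.integer(ph$brain), dim(ph$brain))
  expect_gte(dice(ss$brain_mask$data, truth), 0.95)
  expect_true(all(ss$volume$data[ss$brain_mask$data == 0L] == 0))

  const <- fcd_volume(array(5, c(10, 10, 10)))
  expect_error(skull_strip(const), class = "fcdseg_error_degenerate")
})

test_that("a small bright satellite blob is excluded by the largest-component rule", {
  shape <- c(36, 36, 24)
  centre <- (shape + 1) / 2
  rho2 <- outer(
    outer(((seq_len(shape[1]) - centre[1]) / 12)^2,
          ((seq_len(shape[2]) - centre[2]) / 12)^2, `+`),
    ((seq_len(shape[3]) - centre[3]) / 8)^2, `+`
  )
  brain <- rho2 <= 1
  x <- array(0, shape)
  x[brain] <- 100
  x[1:3, 1:3, 1:3] <- 100 # 27-voxel satellite far from the brain
  x <- x + array(rnorm(prod(shape), 0, 2), shape)
  ss <- skull_strip(fcd_volume(x))
  expect_identical(sum(ss$brain_mask$data[1:3, 1:3, 1:3]), 0L)
  expect_gte(dice(ss$brain_mask$data, array(as.integer(brain), shape)), 0.95)
})

test_that("normalization standardizes, is idempotent, and ignores affine intensity maps", {
  ph <- tiny_phantom(seed = 5)
  brain <- fcd_mask(array(as.integer(ph$brain), dim(ph$brain)),
                    affine = ph$volume$affine)
  z <- normalize_intensity(ph$volume, brain)
  inb <- z$data[brain$data == 1L]
  expect_lt(abs(mean(inb)), 1e-6)
  expect_lt(abs(sd(inb) - 1), 1e-6)
  expect_true(all(z$data[brain$data == 0L] == 0))

  z2 <- normalize_intensity(z, brain)
  expect_equal(z2$data, z$data, tolerance = 1e-6)

  shifted <- fcd_volume(3.7 * ph$volume$data + 42, affine = ph$volume$affine)
  z3 <- normalize_intensity(shifted, brain)
  expect_equal(z3$data, z$data, tolerance = 1e-6)
})

test_that("normalization degenerate inputs raise typed errors", {
  v <- fcd_volume(array(1, c(8, 8, 8)))
  empty <- fcd_mask(array(0L, c(8, 8, 8)))
  full <- fcd_mask(array(1L, c(8, 8, 8)))
  expect_error(normalize_intensity(v, empty), class = "fcdseg_error_degenerate")
  expect_error(normalize_intensity(v, full), class = "fcdseg_error_degenerate")
})

test_that("binarization applies the strict-threshold rule", {
  raw <- array(c(0, 0.4, 0.6, 1, rep(0, 4)), c(8, 1, 1))
  out <- binarize_mask(raw, 0.5)
  expect_identical(as.vector(out$data)[1:4], c(0L, 0L, 1L, 1L))
  expect_identical(sum(binarize_mask(array(0, c(4, 4, 4)))$data), 0L)
  already <- array(as.integer(runif(64) < 0.3), c(4, 4, 4))
  expect_identical(binarize_mask(already, 0.5)$data, already)
  bad <- array(c(NA, rep(0, 7)), c(8, 1, 1))
  expect_error(binarize_mask(bad), class = "fcdseg_error_value")
})

test_that("preprocess_case with an identity configuration is a no-op", {
  ph <- tiny_phantom(seed = 6)
  cfg <- preprocess_config(
    target_spacing = ph$volume$spacing,
    skullstrip_method = "none", normalization = "none"
  )
  out <- preprocess_case(ph$volume, ph$mask, cfg)
  expect_equal(out$volume$data, ph$volume$data, tolerance = 1e-12)
  expect_identical(out$mask$data, ph$mask$data)
})

test_that("full preprocessing keeps masks binary and lesion counts stable at native spacing", {
  ph <- tiny_phantom(seed = 7)
  out <- preprocess_case(ph$volume, ph$mask, preprocess_config())
  expect_true(all(out$mask$data %in% c(0L, 1L)))
  expect_identical(sum(out$mask$data), sum(ph$mask$data))

  down <- preprocess_case(ph$volume, ph$mask,
                          preprocess_config(target_spacing = c(2, 2, 2)))
  expect_true(all(down$mask$data %in% c(0L, 1L)))
  expect_gt(sum(down$mask$data), 0)
})

test_that("stage failures are annotated with the stage name", {
  v <- fcd_volume(array(1, c(10, 10, 10)))
  m <- fcd_mask(array(0L, c(10, 10, 10)))
  err <- tryCatch(
    preprocess_case(v, m, preprocess_config()),
    error = function(e) e
  )
  expect_match(conditionMessage(err), "\\[stage skull_strip\\]")
})

test_that("preprocessing configurations round-trip through YAML", {
  cfg <- preprocess_config(target_spacing = c(1, 1, 2), image_interp_order = 1,
                           normalization = "zscore_global")
  f <- tempfile(fileext = ".yaml")
  write_preprocess_config(cfg, f)
  expect_equal(read_preprocess_config(f), cfg)
})
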