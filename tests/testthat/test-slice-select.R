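# builds a 5-slice volume whose per-slice lesion-voxel counts are exactly
# `counts`, with the image brightest where the mask is
fixture_counts <- function(counts, nx = 8, ny = 8) {
  nz <- length(counts)
  m <- array(0L, c(nx, ny, nz))
  v <- array(rnorm(nx * ny * nz, 10, 1), c(nx, ny, nz))
  for (z in seq_len(nz)) {
    if (counts[z] > 0) {
      m[seq_len(counts[z]), 1, z] <- 1L
      v[seq_len(counts[z]), 1, z] <- 100
    }
  }
  list(v = fcd_volume(v), m = fcd_mask(m))
}

test_that("slice scores equal per-slice lesion counts and intensity maxima", {
  fx <- fixture_counts(c(0, 3, 7, 7, 1))
  rk <- score_slices(fx$v, fx$m, "lesion_area")
  expect_equal(rk$scores, c(0, 3, 7, 7, 1))

  zero <- fcd_mask(array(0L, dim(fx$m$data)))
  expect_equal(score_slices(fx$v, zero, "lesion_area")$scores, rep(0, 5))

  v <- array(1, c(4, 4, 5))
  v[2, 3, 4] <- 9
  rk2 <- score_slices(fcd_volume(v), criterion = "peak_intensity")
  expect_equal(rk2$scores[4], 9)
  expect_true(all(rk2$scores[-4] == 1))

  expect_error(score_slices(fx$v, criterion = "lesion_area"),
               class = "fcdseg_error_config")
})

test_that("top-k selection matches hand-worked rankings and tie-breaks", {
  mk <- function(scores) {
    structure(
      list(scores = scores, criterion = "peak_intensity",
           selected = integer(0), k = NA_integer_, axial_axis = 3L),
      class = "slice_ranking"
    )
  }
  expect_identical(select_top_k(mk(c(5, 1, 9, 3, 7)), 3)$selected, c(1L, 3L, 5L))
  expect_identical(select_top_k(mk(c(7, 7, 7)), 2)$selected, c(1L, 2L))
  expect_identical(select_top_k(mk(c(2, 1)), 10)$selected, c(1L, 2L))
  expect_error(select_top_k(mk(c(1, 2)), 0), class = "fcdseg_error_value")
})

test_that("top-k selection agrees with the exhaustive subset oracle", {
  withr::with_seed(71, {
    for (rep in 1:100) {
      n <- sample(2:8, 1)
      k <- sample(1:n, 1)
      # coarse scores so ties happen often
      scores <- sample(0:3, n, replace = TRUE)
      rk <- structure(
        list(scores = as.numeric(scores), criterion = "peak_intensity",
             selected = integer(0), k = NA_integer_, axial_axis = 3L),
        class = "slice_ranking"
      )
      expect_identical(select_top_k(rk, k)$selected,
                       as.integer(oracle_top_k(scores, k)))
    }
  })
})

test_that("slab extraction preserves data, geometry and lesion totals", {
  fx <- fixture_counts(c(0, 3, 7, 7, 1))

  all_slices <- extract_slab(fx$v, fx$m, 1:5)
  expect_equal(all_slices$volume$data, fx$v$data)
  expect_identical(all_slices$mask$data, fx$m$data)
  expect_equal(all_slices$volume$affine, fx$v$affine)

  single <- extract_slab(fx$v, fx$m, 3)
  expect_equal(dim(single$volume)[3], 1L)
  expect_equal(single$volume$data[, , 1], fx$v$data[, , 3])

  sel <- select_case(fx$v, fx$m, "lesion_area", k = 5)
  expect_identical(sum(sel$mask$data), sum(fx$m$data))

  # axial origin moves to the first selected slice's world position
  sub <- extract_slab(fx$v, fx$m, c(2, 4))
  expect_equal(sub$volume$affine[, 4],
               as.vector(fx$v$affine %*% c(0, 0, 1, 1)))
  expect_equal(attr(sub$volume, "slice_gaps"), 2L)

  expect_error(extract_slab(fx$v, fx$m, c(1, 9)), class = "fcdseg_error_index")
  expect_error(extract_slab(fx$v, fx$m, c(3, 2)), class = "fcdseg_error_value")
})

test_that("selection is enriching and keeps all lesion voxels when k spans the lesion", {
  for (seed in 1:5) {
    ph <- tiny_phantom(seed = seed)
    sel <- select_case(ph$volume, ph$mask, "lesion_area", k = 5)
    expect_identical(sum(sel$mask$data), sum(ph$mask$data))
    slab_frac <- mean(sel$mask$data)
    full_frac <- mean(ph$mask$data)
    expect_gte(slab_frac, full_frac)
  }
})

test_that("selection handles short volumes and is deterministic", {
  fx <- fixture_counts(c(2, 0, 1, 3))
  sel <- select_case(fx$v, fx$m, "lesion_area", k = 5)
  expect_equal(dim(sel$volume)[3], 4L)

  a <- select_case(fx$v, fx$m, "lesion_area", k = 2)
  b <- select_case(fx$v, fx$m, "lesion_area", k = 2)
  expect_identical(a$ranking$selected, b$ranking$selected)
  expect_identical(a$volume$data, b$volume$data)
})

test_that("rankings tidy into one row per slice", {
  fx <- fixture_counts(c(0, 3, 7))
  rk <- select_top_k(score_slices(fx$v, fx$m, "lesion_area"), 2)
  td <- tidy(rk)
  expect_identical(nrow(td), 3L)
  expect_identical(td$selected, c(FALSE, TRUE, TRUE))
  expect_s3_class(autoplot(rk), "ggplot")
})
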