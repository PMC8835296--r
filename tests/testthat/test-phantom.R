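test_that("same spec and seed give bit-identical exams", {
  spec <- sample_phantom_spec(seed = 3, image_size = 48L, n_slices = 12L,
                              pixel_spacing = 7)
  a <- generate_exam(spec)
  b <- generate_exam(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(unclass(a$pp_mask), unclass(b$pp_mask))
  expect_identical(a$gt_pp_volume_ml, b$gt_pp_volume_ml)
})

test_that("plaque-free control exam has empty masks", {
  spec <- phantom_spec(image_size = 48L, n_slices = 6L,
                       plaque_params = plaque_params(), seed = 2L)
  ex <- generate_exam(spec)
  expect_equal(sum(ex$pp_mask), 0)
  expect_equal(sum(ex$calc_mask), 0)
  expect_equal(ex$gt_pp_volume_ml, 0)
})

test_that("ground-truth volume equals a brute-force voxel-counting oracle", {
  spec <- phantom_spec(
    image_size = 48L, pixel_spacing = 7, slice_spacing = 1.25, n_slices = 10L,
    plaque_params = plaque_params("left", 180, 80, 14, 3L, 5L, FALSE),
    seed = 9L)
  ex <- generate_exam(spec)
  # independent recount: loop over slices, count positive pixels one by one
  n <- 0L
  for (s in seq_len(dim(ex$pp_mask)[3]))
    for (v in as.integer(ex$pp_mask[, , s])) if (v == 1L) n <- n + 1L
  expect_gt(n, 0L)
  expect_equal(ex$gt_pp_volume_ml, n * 7 * 7 * 1.25 / 1000)
})

test_that("calcified mask is a subset of the plaque mask and HU bounds hold", {
  for (seed in c(21, 22, 23)) {
    spec <- sample_phantom_spec(seed = seed, image_size = 48L, n_slices = 10L,
                                pixel_spacing = 7)
    ex <- generate_exam(spec)
    expect_true(all(ex$calc_mask <= ex$pp_mask))
    if (sum(ex$pp_mask) > 0)
      expect_gte(min(ex$volume$voxels[ex$pp_mask == 1]),
                 spec$plaque_soft_hu - 3 * spec$noise_sd)
    # calcified pixels stay at or above the 100-HU threshold by construction
    if (sum(ex$calc_mask) > 0)
      expect_gte(min(ex$volume$voxels[ex$calc_mask == 1]), 100)
    # lung voxels (from the noise-free template) stay below 0 HU
    spec0 <- spec; spec0$noise_sd <- 0
    tmpl <- generate_exam(spec0)
    lung <- tmpl$volume$voxels == spec$lung_hu & ex$pp_mask == 0
    expect_true(all(ex$volume$voxels[lung] < 0))
  }
})

test_that("identity growth reproduces the same ground-truth volume", {
  spec <- sample_phantom_spec(seed = 31, image_size = 48L, n_slices = 15L,
                              pixel_spacing = 7)
  pair <- generate_longitudinal_pair(spec, growth_factor = 1,
                                     participant_id = "p1")
  expect_equal(pair$round3$gt_pp_volume_ml, pair$round2$gt_pp_volume_ml,
               tolerance = 0.02)
  expect_identical(pair$round2$volume$round, 2L)
  expect_identical(pair$round3$volume$round, 3L)
  expect_identical(pair$round2$volume$participant_id,
                   pair$round3$volume$participant_id)
})

test_that("growth factor 1.7 lands in the rasterization tolerance band", {
  ratios <- vapply(c(41, 42, 43, 44), function(seed) {
    spec <- sample_phantom_spec(seed = seed, image_size = 64L, n_slices = 20L,
                                pixel_spacing = 5.5)
    pair <- generate_longitudinal_pair(spec, 1.7)
    pair$round3$gt_pp_volume_ml / pair$round2$gt_pp_volume_ml
  }, numeric(1))
  expect_true(all(ratios >= 1.5 & ratios <= 1.9))
})

test_that("distinct seeds give distinct plaque patterns", {
  exs <- lapply(1:4, function(s)
    generate_exam(sample_phantom_spec(seed = 300 + s, image_size = 48L,
                                      n_slices = 10L, pixel_spacing = 7)))
  sigs <- vapply(exs, function(e) paste(which(e$pp_mask == 1), collapse = ","),
                 character(1))
  expect_equal(length(unique(sigs)), 4L)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(phantom_spec(plaque_soft_hu = 120), "plaque_soft_hu")
  expect_error(phantom_spec(lung_hu = 50), "lung_hu")
  expect_error(phantom_spec(pixel_spacing = -1), "pixel_spacing")
  expect_error(phantom_spec(n_slices = 5L,
                            plaque_params = plaque_params("left", 0, 30, 5,
                                                          4L, 5L, FALSE)),
               "slice_start")
  expect_error(generate_longitudinal_pair(
    sample_phantom_spec(seed = 1, image_size = 48L, n_slices = 10L,
                        pixel_spacing = 7), 0.5),
    "growth_factor")
})
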