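# independent scalar re-implementations of the losses, used as oracles:
# plain loops, no shared code with the package internals
oracle_bce <- function(y, yh, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(y)) {
    p <- min(max(yh[i], eps), 1 - eps)
    tot <- tot - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  tot / length(y)
}
oracle_dice <- function(y, yh) {
  num <- 0; sy <- 0; sp <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] * yh[i]; sy <- sy + y[i]; sp <- sp + yh[i]
  }
  1 - (2 * num + 1) / (sy + sp + 1)
}

test_that("loss formulas match hand-computed single-pixel values", {
  y1 <- matrix(1, 1, 1); p5 <- matrix(0.5, 1, 1)
  expect_equal(bce_loss(y1, p5), -log(0.5), tolerance = 1e-12)
  expect_equal(dice_loss(y1, p5), 0.2, tolerance = 1e-12)
  expect_equal(combined_loss(y1, p5), -log(0.5) + 0.2, tolerance = 1e-12)
})

test_that("loss edge cases behave as defined", {
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(bce_loss(y, y), 1e-5)             # perfect binary prediction
  expect_equal(dice_loss(y * 0, y * 0), 0)    # empty/empty via smoothing
  ones <- matrix(1, 4, 4)
  expect_equal(dice_loss(ones, ones), 0)
  # fully wrong prediction is finite thanks to clipping
  expect_equal(bce_loss(y, 1 - y), -log(1e-7), tolerance = 1e-3)
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
  # combined dominates each component
  set.seed(1)
  yr <- matrix(rbinom(64, 1, 0.4), 8, 8)
  pr <- matrix(runif(64), 8, 8)
  expect_gte(combined_loss(yr, pr), bce_loss(yr, pr))
  expect_gte(combined_loss(yr, pr), dice_loss(yr, pr))
})

test_that("losses match the scalar oracle on random grids", {
  set.seed(42)
  for (rep in seq_len(100)) {
    y <- matrix(rbinom(256, 1, runif(1, 0.05, 0.6)), 16, 16)
    yh <- matrix(runif(256), 16, 16)
    expect_equal(bce_loss(y, yh), oracle_bce(y, yh), tolerance = 1e-6)
    expect_equal(dice_loss(y, yh), oracle_dice(y, yh), tolerance = 1e-6)
    expect_equal(combined_loss(y, yh), oracle_bce(y, yh) + oracle_dice(y, yh),
                 tolerance = 1e-6)
  }
})

test_that("flip augmentation is a paired involution preserving mask volume", {
  set.seed(3)
  img <- matrix(rnorm(64), 8, 8)
  msk <- matrix(rbinom(64, 1, 0.3), 8, 8)
  a <- augment_flip(img, msk, draws = c(0.1, 0.9)) # flip rows only
  b <- augment_flip(a$image, a$mask, draws = c(0.1, 0.9))
  expect_equal(b$image, img)
  expect_equal(b$mask, msk)
  expect_equal(sum(a$mask), sum(msk))
  # image and mask receive the same flip
  expect_equal(a$image[1, ], img[8, ])
  expect_equal(a$mask[1, ], msk[8, ])
  # seeded reproducibility
  r1 <- augment_flip(img, msk, seed = 7)
  r2 <- augment_flip(img, msk, seed = 7)
  expect_identical(r1$flips, r2$flips)
})

test_that("analytic gradients match finite differences on a tiny network", {
  pv <- asNamespace("plaquevol")
  cfg <- train_config(input_resolution = 8L, base_filters = 2L, depth = 2L,
                      epochs = 1L, dropout_rate = 0, seed = 3L)
  params <- pv$init_unet_params(cfg)
  set.seed(42)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU kink
  for (nm in grep("_b$", names(params), value = TRUE))
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), 0, 0.05)
  x <- array(runif(64), dim = c(8, 8, 1))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  lossfun <- function(pp) {
    fwd <- pv$unet_forward(x, pp, cfg, training = FALSE)
    combined_loss(y, fwd$probs[, , 1])
  }
  fwd <- pv$unet_forward(x, params, cfg, training = FALSE)
  gz <- array(pv$grad_combined_logits(as.numeric(y), as.numeric(fwd$probs)),
              dim = dim(fwd$probs))
  grads <- pv$unet_backward(fwd, gz, params, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("encoder channel widths double per level", {
  model <- tiny_model()
  ps <- unet_param_summary(model)
  enc1 <- ps[ps$layer == "enc1_conv1", ]
  expect_equal(enc1$in_channels, 1)
  expect_equal(enc1$out_channels, model$config$base_filters)
  for (i in seq_len(model$config$depth - 1)) {
    a <- ps[ps$layer == sprintf("enc%d_conv2", i), "out_channels"]
    b <- ps[ps$layer == sprintf("enc%d_conv2", i + 1), "out_channels"]
    expect_equal(b, 2 * a)
  }
  # the default-resolution configuration starts at 24 and doubles: 24, 48, ...
  cfg <- train_config()
  pv <- asNamespace("plaquevol")
  expect_equal(pv$unet_channels(cfg), c(24, 48, 96, 192, 384))
})

test_that("training reduces the loss and is seed-reproducible", {
  exams <- gen_cohort(3, 450, image_size = 16L, n_slices = 10L,
                      pixel_spacing = 22, n_plaques = 2L)
  tr <- slabify(exams)
  cfg <- train_config(input_resolution = 16L, base_filters = 4L, depth = 3L,
                      epochs = 5L, seed = 21L)
  m1 <- train_unet(tr$images, tr$masks, cfg)
  expect_lt(m1$loss_log$loss[nrow(m1$loss_log)], m1$loss_log$loss[1])
  m2 <- train_unet(tr$images, tr$masks, cfg)
  expect_identical(m1$loss_log$loss, m2$loss_log$loss)
  expect_identical(m1$params, m2$params)
})

test_that("training input validation and degenerate targets behave", {
  cfg <- train_config(input_resolution = 16L, base_filters = 4L, depth = 2L,
                      epochs = 40L, seed = 2L)
  expect_error(train_unet(list(), list(), cfg), "non-empty")
  # mask = entire image drives predictions toward 1 everywhere
  set.seed(1)
  img <- matrix(rnorm(256, 0, 50), 16, 16)
  ones <- matrix(1, 16, 16)
  m <- train_unet(list(img, img), list(ones, ones), cfg)
  p <- predict_unet(m, img)
  expect_gt(mean(p), 0.95)
})

test_that("inference is deterministic, ordered, and in [0,1]", {
  model <- tiny_model()
  exams <- gen_cohort(1, 480, image_size = 16L, n_slices = 10L,
                      pixel_spacing = 22, n_plaques = 2L)
  st <- compute_mip(exams[[1]]$volume, 5)
  p1 <- predict_unet(model, st)
  p2 <- predict_unet(model, st)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(dim(p1), dim(st$slabs))
  # slice order matches input order: permuting input permutes output
  perm <- c(2, 1)
  sub <- st$slabs[, , perm]
  p_perm <- predict_unet(model, sub)
  expect_equal(p_perm[, , 1], p1[, , 2], tolerance = 1e-12)
  # resolution mismatch without resampling is an error
  expect_error(predict_unet(model, matrix(0, 20, 20)), "resolution")
  pr <- predict_unet(model, matrix(0, 20, 20), resample = TRUE)
  expect_equal(dim(pr), c(20L, 20L))
})

test_that("models round-trip through disk with fingerprint checking", {
  model <- tiny_model()
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  broken <- model
  broken$fingerprint <- "tampered"
  path2 <- tempfile(fileext = ".rds")
  saveRDS(broken, path2)
  expect_error(load_model(path2), "consistent")
})

test_that("config invariants are enforced", {
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(dropout_rate = 1), "dropout_rate")
  expect_error(train_config(input_resolution = 100L, depth = 5L),
               "divisible")
  expect_error(train_config(batch_size = 2L), "batch_size")
})

test_that("a trained model predicts near-nothing on an all-air image", {
  model <- trained_desk_model()
  air <- matrix(-1000, 64, 64)
  p <- predict_unet(model, air)
  expect_lt(mean(p >= 0.5), 0.001)
})
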