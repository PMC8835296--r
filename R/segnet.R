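#' Training configuration for the 2D U-Net
#'
#' Holds the architecture and optimization settings of the segmentation
#' network: a U-Net with `depth` encoder blocks of two 3x3 convolutions
#' each, channel width doubling per level from `base_filters` (24, 48, ...
#' at the default), 2x2 max-pool downsampling, bilinear upsampling with
#' concatenation skip connections in the decoder, dropout after each
#' descending-path block, a single input channel (the CT image) and a
#' sigmoid output. Training uses the combined loss
#' `L = L_BCE + L_DL`, the Adam optimizer at learning rate 0.001, batch
#' size 1, and random horizontal/vertical flip augmentation.
#'
#' @param input_resolution Square input size in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param base_filters Channels of the first encoder level; doubled per level.
#' @param depth Number of encoder blocks (the last is the bottleneck).
#' @param batch_size Samples per optimizer step (the reference setting is 1,
#'   the only value implemented).
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param epochs Training epochs.
#' @param dropout_rate Dropout probability applied after each encoder block
#'   during training, in `[0, 1)`.
#' @param augment_flips Randomly flip image and mask together along each axis
#'   with probability 0.5 during training.
#' @param hu_window HU window mapped linearly to `[0, 1]` at the network
#'   input; fixed (never per-exam) so the 100-HU calcification semantics stay
#'   stable across exams. The default `[-200, 800]` spans soft tissue through
#'   calcification and rib while preserving the small soft-plaque/muscle
#'   contrast that a full `[-1000, 1000]` window would compress tenfold.
#' @param seed Integer seed controlling initialization, sample order,
#'   augmentation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(input_resolution = 512L, base_filters = 24L,
                         depth = 5L, batch_size = 1L, learning_rate = 0.001,
                         optimizer = "adam", epochs = 200L,
                         dropout_rate = 0.5, augment_flips = TRUE,
                         hu_window = c(-200, 800), seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  if (depth < 2L) stop("`depth` must be at least 2")
  if (input_resolution %% 2^(depth - 1) != 0)
    stop("`input_resolution` must be divisible by 2^(depth - 1) = ",
         2^(depth - 1))
  if (batch_size != 1L)
    stop("only `batch_size` = 1 is implemented")
  if (!identical(optimizer, "adam"))
    stop("only the Adam optimizer is implemented")
  if (length(hu_window) != 2L || hu_window[1] >= hu_window[2])
    stop("`hu_window` must be c(lo, hi) with lo < hi")
  structure(list(input_resolution = as.integer(input_resolution),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth), batch_size = 1L,
                 learning_rate = learning_rate, optimizer = "adam",
                 epochs = as.integer(epochs), dropout_rate = dropout_rate,
                 augment_flips = isTRUE(augment_flips),
                 hu_window = as.numeric(hu_window), seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale configuration preset
#'
#' The same network scaled to run on a laptop CPU: 64 x 64 inputs, 8 base
#' filters and few epochs. A preset of [train_config()], not a separate code
#' path.
#'
#' @param epochs Training epochs (kept small; the synthetic task converges
#'   quickly).
#' @param ... Further overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_scale_config <- function(epochs = 25L, ...) {
  train_config(input_resolution = 64L, base_filters = 8L, epochs = epochs, ...)
}

#' Map HU to the network input range
#'
#' Clamps to the configured HU window and rescales linearly to `[0, 1]`.
#'
#' @param x Numeric matrix/array of HU values.
#' @param window `c(lo, hi)` in HU.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_hu <- function(x, window = c(-200, 800)) {
  (pmin(pmax(x, window[1]), window[2]) - window[1]) / (window[2] - window[1])
}

check_same_shape <- function(y, yhat) {
  dy <- if (is.null(dim(y))) length(y) else dim(y)
  dp <- if (is.null(dim(yhat))) length(yhat) else dim(yhat)
  if (!identical(as.integer(dy), as.integer(dp)))
    stop("shape mismatch: y is ", paste(dy, collapse = "x"),
         ", yhat is ", paste(dp, collapse = "x"))
}

#' Segmentation losses
#'
#' `bce_loss` is the pixel-mean binary cross-entropy
#' \eqn{-[y \log\hat y + (1-y)\log(1-\hat y)]} with predictions clipped to
#' `[eps, 1 - eps]`. `dice_loss` is the smoothed soft Dice loss
#' \eqn{1 - (2\sum y\hat y + 1) / (\sum y + \sum\hat y + 1)} with sums over
#' all pixels of the sample and smoothing constant 1, so the empty/empty
#' case is well defined. `combined_loss` is their sum, the training
#' objective.
#'
#' @param y Ground-truth mask (0/1), any shape.
#' @param yhat Predicted probabilities in `[0, 1]`, same shape.
#' @param eps Clipping constant for the cross-entropy.
#' @return A non-negative scalar (`dice_loss` lies in `[0, 1]`).
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  check_same_shape(y, yhat)
  yh <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yh) + (1 - y) * log(1 - yh))
}

#' @rdname bce_loss
#' @export
dice_loss <- function(y, yhat) {
  check_same_shape(y, yhat)
  1 - (2 * sum(y * yhat) + 1) / (sum(y) + sum(yhat) + 1)
}

#' @rdname bce_loss
#' @export
combined_loss <- function(y, yhat, eps = 1e-7) {
  bce_loss(y, yhat, eps) + dice_loss(y, yhat)
}

# gradient of the combined loss w.r.t. the logits, given probabilities p
grad_combined_logits <- function(y, p) {
  n <- length(p)
  g_bce <- (p - y) / n
  sy <- sum(y); sp <- sum(p); s1 <- sum(y * p)
  denom <- sy + sp + 1
  g_dice_p <- -(2 * y * denom - (2 * s1 + 1)) / denom^2
  g_bce + g_dice_p * p * (1 - p)
}

#' Paired flip augmentation
#'
#' Flips image and mask together: each axis is flipped independently with
#' probability 0.5. Flipping is an involution and preserves the mask pixel
#' count.
#'
#' @param image,mask Matrices of identical shape.
#' @param seed Optional seed; if `NULL`, `draws` (or the current RNG stream)
#'   decides.
#' @param draws Optional two uniform draws in `[0, 1]`; an axis flips when
#'   its draw is `< 0.5`.
#' @return List with flipped `image` and `mask` plus the logical `flips`
#'   applied.
#' @export
augment_flip <- function(image, mask, seed = NULL, draws = NULL) {
  check_same_shape(image, mask)
  if (is.null(draws))
    draws <- if (is.null(seed)) stats::runif(2)
             else with_seed_(seed, stats::runif(2))
  flips <- draws < 0.5
  if (flips[1]) { image <- image[nrow(image):1, , drop = FALSE]
                  mask <- mask[nrow(mask):1, , drop = FALSE] }
  if (flips[2]) { image <- image[, ncol(image):1, drop = FALSE]
                  mask <- mask[, ncol(mask):1, drop = FALSE] }
  list(image = image, mask = mask, flips = flips)
}

# --- network internals ------------------------------------------------------

unet_channels <- function(cfg) cfg$base_filters * 2^(seq_len(cfg$depth) - 1)

# parameter set: flat named list of weight matrices (Cout x k*k*Cin, column
# order di, dj, cin to match the C++ kernels) and bias vectors
init_unet_params <- function(cfg) {
  C <- unet_channels(cfg)
  D <- cfg$depth
  params <- list()
  he <- function(cin, cout, k) {
    matrix(stats::rnorm(cout * k * k * cin, 0, sqrt(2 / (k * k * cin))),
           nrow = cout, ncol = k * k * cin)
  }
  with_seed_(cfg$seed, {
    for (i in seq_len(D)) {
      cin <- if (i == 1L) 1L else C[i - 1]
      params[[sprintf("enc%d_conv1_W", i)]] <- he(cin, C[i], 3)
      params[[sprintf("enc%d_conv1_b", i)]] <- numeric(C[i])
      params[[sprintf("enc%d_conv2_W", i)]] <- he(C[i], C[i], 3)
      params[[sprintf("enc%d_conv2_b", i)]] <- numeric(C[i])
    }
    for (j in seq_len(D - 1)) {
      cin <- C[j] + C[j + 1]
      params[[sprintf("dec%d_conv1_W", j)]] <- he(cin, C[j], 3)
      params[[sprintf("dec%d_conv1_b", j)]] <- numeric(C[j])
      params[[sprintf("dec%d_conv2_W", j)]] <- he(C[j], C[j], 3)
      params[[sprintf("dec%d_conv2_b", j)]] <- numeric(C[j])
    }
    params[["out_W"]] <- he(C[1], 1L, 1)
    params[["out_b"]] <- numeric(1)
  })
  params
}

relu_ <- function(a) { a[a < 0] <- 0; a }

# forward pass on one normalized sample x (H x W x 1 array); returns the
# probability map and, when training, every intermediate needed by backward
unet_forward <- function(x, params, cfg, training = FALSE) {
  D <- cfg$depth
  drop_p <- if (training) cfg$dropout_rate else 0
  enc <- vector("list", D)
  h <- x
  for (i in seq_len(D)) {
    a1 <- relu_(.conv2d_fwd(h, params[[sprintf("enc%d_conv1_W", i)]],
                            params[[sprintf("enc%d_conv1_b", i)]], 3L))
    a2 <- relu_(.conv2d_fwd(a1, params[[sprintf("enc%d_conv2_W", i)]],
                            params[[sprintf("enc%d_conv2_b", i)]], 3L))
    # dropout regularizes the tensor that continues down the descending
    # path; the lateral skip copy is the block output itself
    mask <- NULL
    a2d <- a2
    if (drop_p > 0) {
      mask <- array((stats::runif(length(a2)) >= drop_p) / (1 - drop_p),
                    dim = dim(a2))
      a2d <- a2 * mask
    }
    pool <- NULL
    if (i < D) pool <- .maxpool2_fwd(a2d)
    enc[[i]] <- list(input = h, a1 = a1, a2 = a2, drop_mask = mask,
                     a2d = a2d, pool_idx = pool$idx)
    if (i < D) h <- pool$y
  }
  dec <- vector("list", D - 1)
  h <- enc[[D]]$a2d
  for (j in rev(seq_len(D - 1))) {
    up <- .upsample2_fwd(h)
    cat_in <- array(c(enc[[j]]$a2, up),
                    dim = c(dim(up)[1:2], dim(enc[[j]]$a2)[3] + dim(up)[3]))
    a1 <- relu_(.conv2d_fwd(cat_in, params[[sprintf("dec%d_conv1_W", j)]],
                            params[[sprintf("dec%d_conv1_b", j)]], 3L))
    a2 <- relu_(.conv2d_fwd(a1, params[[sprintf("dec%d_conv2_W", j)]],
                            params[[sprintf("dec%d_conv2_b", j)]], 3L))
    dec[[j]] <- list(input = cat_in, a1 = a1, a2 = a2,
                     up_src_dim = dim(h))
    h <- a2
  }
  logits <- .conv2d_fwd(h, params[["out_W"]], params[["out_b"]], 1L)
  probs <- 1 / (1 + exp(-logits))
  list(probs = probs, logits = logits, enc = enc, dec = dec)
}

# backward pass: gradient of the loss w.r.t. every parameter, given the
# gradient w.r.t. the logits
unet_backward <- function(fwd, g_logits, params, cfg) {
  D <- cfg$depth
  grads <- list()
  h_top <- if (D > 1L) fwd$dec[[1]]$a2 else fwd$enc[[D]]$a2d
  bo <- .conv2d_bwd(h_top, params[["out_W"]], g_logits, 1L)
  grads[["out_W"]] <- bo$gw
  grads[["out_b"]] <- bo$gb
  g <- bo$gx
  g_skip <- vector("list", D)
  for (j in seq_len(D - 1)) {
    dc <- fwd$dec[[j]]
    gz2 <- g * (dc$a2 > 0)
    b2 <- .conv2d_bwd(dc$a1, params[[sprintf("dec%d_conv2_W", j)]], gz2, 3L)
    grads[[sprintf("dec%d_conv2_W", j)]] <- b2$gw
    grads[[sprintf("dec%d_conv2_b", j)]] <- b2$gb
    gz1 <- b2$gx * (dc$a1 > 0)
    b1 <- .conv2d_bwd(dc$input, params[[sprintf("dec%d_conv1_W", j)]], gz1, 3L)
    grads[[sprintf("dec%d_conv1_W", j)]] <- b1$gw
    grads[[sprintf("dec%d_conv1_b", j)]] <- b1$gb
    nskip <- dim(fwd$enc[[j]]$a2)[3]
    gcat <- b1$gx
    g_skip[[j]] <- gcat[, , seq_len(nskip), drop = FALSE]
    g_up <- gcat[, , nskip + seq_len(dim(gcat)[3] - nskip), drop = FALSE]
    g <- .upsample2_bwd(g_up, dc$up_src_dim[1], dc$up_src_dim[2])
  }
  # g now holds the gradient on the bottleneck block output (enc D, dropped)
  g_next_input <- NULL
  for (i in rev(seq_len(D))) {
    ec <- fwd$enc[[i]]
    # gradient through the dropped descending path, plus (for i < D) the
    # undropped lateral skip
    if (i == D) {
      g_a2 <- if (is.null(ec$drop_mask)) g else g * ec$drop_mask
    } else {
      hw <- dim(ec$a2)
      g_pool <- .maxpool2_bwd(ec$pool_idx, g_next_input, hw[1], hw[2])
      if (!is.null(ec$drop_mask)) g_pool <- g_pool * ec$drop_mask
      g_a2 <- g_skip[[i]] + g_pool
    }
    gz2 <- g_a2 * (ec$a2 > 0)
    b2 <- .conv2d_bwd(ec$a1, params[[sprintf("enc%d_conv2_W", i)]], gz2, 3L)
    grads[[sprintf("enc%d_conv2_W", i)]] <- b2$gw
    grads[[sprintf("enc%d_conv2_b", i)]] <- b2$gb
    gz1 <- b2$gx * (ec$a1 > 0)
    b1 <- .conv2d_bwd(ec$input, params[[sprintf("enc%d_conv1_W", i)]], gz1, 3L)
    grads[[sprintf("enc%d_conv1_W", i)]] <- b1$gw
    grads[[sprintf("enc%d_conv1_b", i)]] <- b1$gb
    g_next_input <- b1$gx
  }
  grads
}

#' Train the U-Net on image/mask pairs
#'
#' Runs seeded stochastic training with batch size 1: per epoch the sample
#' order is reshuffled, each sample is optionally flip-augmented, the
#' combined BCE + Dice loss is backpropagated through the network and the
#' parameters are updated with Adam. All randomness (initialization, order,
#' flips, dropout) derives from `config$seed`, so identical data and config
#' reproduce the identical model.
#'
#' @param images List of square HU matrices at `config$input_resolution`.
#' @param masks List of matching 0/1 mask matrices.
#' @param config A [train_config()].
#' @param verbose Print the per-epoch mean loss.
#' @return An object of class `unet_model`: `params`, `config`,
#'   `loss_log` (data frame epoch/loss/bce/dice) and a config `fingerprint`.
#' @export
train_unet <- function(images, masks, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  n <- length(images)
  if (n == 0L || length(masks) != n)
    stop("need a non-empty train set with one mask per image")
  res <- config$input_resolution
  prep <- function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == res)) m <- resize_nearest(m, res)
    m
  }
  xs <- lapply(images, function(m)
    normalize_hu(prep(m), config$hu_window))
  ys <- lapply(masks, prep)
  params <- init_unet_params(config)
  m_st <- lapply(params, function(p) p * 0)
  v_st <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  log_rows <- vector("list", config$epochs)
  with_seed_(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- c(loss = 0, bce = 0, dice = 0)
      for (s in ord) {
        xi <- xs[[s]]; yi <- ys[[s]]
        if (config$augment_flips) {
          au <- augment_flip(xi, yi)
          xi <- au$image; yi <- au$mask
        }
        x <- array(xi, dim = c(res, res, 1L))
        fwd <- unet_forward(x, params, config, training = TRUE)
        p <- fwd$probs[, , 1]
        lb <- bce_loss(yi, p); ld <- dice_loss(yi, p)
        if (!is.finite(lb + ld))
          stop("non-finite training loss at epoch ", epoch, " (sample ", s, ")")
        tot <- tot + c(lb + ld, lb, ld)
        gz <- array(grad_combined_logits(as.numeric(yi), as.numeric(p)),
                    dim = c(dim(p), 1L))
        grads <- unet_backward(fwd, gz, params, config)
        t <- t + 1L
        lr_t <- config$learning_rate * sqrt(1 - b2^t) / (1 - b1^t)
        for (nm in names(params)) {
          g <- grads[[nm]]
          m_st[[nm]] <- b1 * m_st[[nm]] + (1 - b1) * g
          v_st[[nm]] <- b2 * v_st[[nm]] + (1 - b2) * g * g
          params[[nm]] <- params[[nm]] -
            lr_t * m_st[[nm]] / (sqrt(v_st[[nm]]) + eps)
        }
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, loss = tot[1] / n,
                                      bce = tot[2] / n, dice = tot[3] / n)
      if (verbose)
        message(sprintf("epoch %3d  L = %.4f (BCE %.4f, Dice %.4f)",
                        epoch, tot[1] / n, tot[2] / n, tot[3] / n))
    }
  })
  structure(list(params = params, config = config,
                 loss_log = do.call(rbind, log_rows),
                 fingerprint = config_fingerprint(config)),
            class = "unet_model")
}

config_fingerprint <- function(cfg) {
  paste(cfg$input_resolution, cfg$base_filters, cfg$depth, cfg$learning_rate,
        cfg$epochs, cfg$dropout_rate, cfg$augment_flips, cfg$seed,
        paste(cfg$hu_window, collapse = ":"), sep = "|")
}

#' @export
print.unet_model <- function(x, ...) {
  C <- unet_channels(x$config)
  cat(sprintf("<unet_model> depth %d U-Net, channels %s, input %dx%d\n",
              x$config$depth, paste(C, collapse = "-"),
              x$config$input_resolution, x$config$input_resolution))
  if (!is.null(x$loss_log))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                nrow(x$loss_log), x$loss_log$loss[nrow(x$loss_log)]))
  invisible(x)
}

#' Per-layer channel summary of a model
#'
#' Reports input and output channels of every convolution, e.g. to verify
#' the doubling pattern 24, 48, 96, ... of the encoder.
#'
#' @param model A `unet_model`.
#' @return Data frame with `layer`, `in_channels`, `out_channels`.
#' @export
unet_param_summary <- function(model) {
  cfg <- model$config
  rows <- lapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    if (!is.matrix(p)) return(NULL)
    k <- if (nm == "out_W") 1L else 3L
    data.frame(layer = sub("_W$", "", nm),
               in_channels = ncol(p) / (k * k),
               out_channels = nrow(p))
  })
  do.call(rbind, rows)
}

# nearest-neighbour resize of a square matrix (used for resolution adaption
# of images and masks alike, so mask values stay binary)
resize_nearest <- function(m, out_n) {
  idx_r <- pmin(nrow(m), pmax(1L, round((seq_len(out_n) - 0.5) *
                                          nrow(m) / out_n + 0.5)))
  idx_c <- pmin(ncol(m), pmax(1L, round((seq_len(out_n) - 0.5) *
                                          ncol(m) / out_n + 0.5)))
  m[idx_r, idx_c, drop = FALSE]
}

#' Run inference slice by slice
#'
#' Applies a trained network to every image of the input, in input order,
#' without dropout — repeated calls on identical input give identical
#' output. Accepts a [compute_mip()] stack, a [ct_volume] (native slices),
#' a 3-D array of HU images, a list of matrices, or a single matrix.
#'
#' @param model A `unet_model` from [train_unet()].
#' @param input Images in HU (see above).
#' @param resample Allow nearest-neighbour resampling to the model
#'   resolution (predictions are mapped back to the input grid). If `FALSE`
#'   a resolution mismatch is an error.
#' @return A 3-D array of probabilities in `[0, 1]` (rows x cols x n_images;
#'   a single matrix input returns a matrix).
#' @export
predict_unet <- function(model, input, resample = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$config
  res <- cfg$input_resolution
  imgs <- if (inherits(input, "mip_stack")) input$slabs
          else if (inherits(input, "ct_volume")) input$voxels
          else if (is.list(input)) simplify2array(input)
          else input
  single <- is.matrix(imgs)
  if (single) imgs <- array(imgs, dim = c(dim(imgs), 1L))
  d <- dim(imgs)
  if (!(d[1] == res && d[2] == res)) {
    if (!resample)
      stop("input resolution ", d[1], "x", d[2], " does not match model (",
           res, "x", res, "); set resample = TRUE to resize")
  }
  out <- array(0, dim = d)
  for (s in seq_len(d[3])) {
    m <- imgs[, , s]
    if (!(d[1] == res && d[2] == res)) m <- resize_nearest(m, res)
    x <- array(normalize_hu(m, cfg$hu_window), dim = c(res, res, 1L))
    p <- unet_forward(x, model$params, cfg, training = FALSE)$probs[, , 1]
    if (!(d[1] == res && d[2] == res)) {
      full <- matrix(0, d[1], d[2]) # map back by nearest source pixel
      idx_r <- pmin(res, pmax(1L, round((seq_len(d[1]) - 0.5) * res / d[1] + 0.5)))
      idx_c <- pmin(res, pmax(1L, round((seq_len(d[2]) - 0.5) * res / d[2] + 0.5)))
      full <- p[idx_r, idx_c]
      p <- full
    }
    out[, , s] <- p
  }
  if (single) out[, , 1] else out
}

#' Save / load a trained model
#'
#' The serialized file carries the parameters together with the config
#' fingerprint; loading verifies the fingerprint so weights cannot silently
#' be applied under a different architecture.
#'
#' @param model A `unet_model`.
#' @param path File path (`.rds`).
#' @return `load_model` returns the `unet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model") ||
      !identical(model$fingerprint, config_fingerprint(model$config)))
    stop("file does not contain a consistent unet_model: ", path)
  model
}
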