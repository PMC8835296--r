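# Shared fixtures: phantom cohorts, slab extraction, and cached trained
# models so expensive training runs once per test session.

gen_cohort <- function(n_exams, seed0, ...) {
  lapply(seq_len(n_exams), function(e) {
    spec <- sample_phantom_spec(seed = seed0 + e, ...)
    generate_exam(spec, exam_id = sprintf("e%04d", seed0 + e),
                  participant_id = sprintf("p%04d", seed0 + e))
  })
}

# flatten exams into per-slab image/mask training pairs (5-mm MIP geometry)
slabify <- function(exams, thickness = 5) {
  imgs <- list(); msks <- list()
  for (ex in exams) {
    st <- compute_mip(ex$volume, thickness)
    gm <- mask_to_mip(ex$pp_mask, st)
    for (s in seq_len(dim(st$slabs)[3])) {
      imgs[[length(imgs) + 1L]] <- st$slabs[, , s]
      msks[[length(msks) + 1L]] <- gm[, , s]
    }
  }
  list(images = imgs, masks = msks)
}

.model_cache <- new.env(parent = emptyenv())

# desk-scale model trained on a seeded synthetic cohort; cached per session
trained_desk_model <- function() {
  if (!is.null(.model_cache$desk)) return(.model_cache$desk)
  train_ex <- gen_cohort(75, 1000)
  tr <- slabify(train_ex)
  cfg <- desk_scale_config(epochs = 25L, seed = 11L)
  .model_cache$desk <- train_unet(tr$images, tr$masks, cfg)
  .model_cache$desk
}

# small, quickly trained model for structural tests that only need a valid
# unet_model object (16x16 inputs, depth 3)
tiny_model <- function() {
  if (!is.null(.model_cache$tiny)) return(.model_cache$tiny)
  exams <- gen_cohort(2, 600, image_size = 16L, n_slices = 10L,
                      pixel_spacing = 22, n_plaques = 2L)
  tr <- slabify(exams)
  cfg <- train_config(input_resolution = 16L, base_filters = 4L, depth = 3L,
                      epochs = 4L, seed = 5L)
  .model_cache$tiny <- train_unet(tr$images, tr$masks, cfg)
  .model_cache$tiny
}
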