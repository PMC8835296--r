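#' Binarize a probability map
#'
#' A pixel is positive when its probability is greater than or equal to the
#' threshold (inclusive rule, so an exact 0.5 is positive at the default).
#'
#' @param prob Numeric matrix/array of probabilities in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return A [binary_mask] of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (is.null(dim(prob))) stop("`prob` must be a matrix or array")
  binary_mask(array(as.integer(prob >= threshold), dim = dim(prob)))
}

#' Split the calcified part out of a plaque mask
#'
#' Calcified plaque is the subset of the plaque mask whose HU meets or
#' exceeds the threshold (inclusive; 100 HU by default). On MIP slabs the
#' slab image itself is a valid HU reference because the maximum projection
#' preserves maxima: a calcified pixel keeps HU >= 100 after projection.
#'
#' @param mask A [binary_mask].
#' @param image HU image of identical shape (native slice stack or MIP
#'   slabs).
#' @param hu_threshold Calcification threshold in HU.
#' @return A [binary_mask], always a subset of `mask`.
#' @export
split_calcified <- function(mask, image, hu_threshold = 100) {
  if (!identical(as.integer(dim(mask)), as.integer(dim(image))))
    stop("mask geometry (", paste(dim(mask), collapse = "x"),
         ") does not match HU image (", paste(dim(image), collapse = "x"), ")")
  binary_mask(array(as.integer(mask == 1L & image >= hu_threshold),
                    dim = dim(mask)))
}

#' Fully automated per-exam plaque quantification
#'
#' Runs the complete measurement chain on one exam: network inference,
#' binarization at `prob_threshold`, calcification splitting at
#' `hu_threshold`, and millilitre volumetrics — on either the MIP path
#' (inference on 5-mm slabs, slab-geometry volumes) or the native path
#' (inference per native slice, voxel volumes).
#'
#' @param vol A [ct_volume].
#' @param model A trained `unet_model`.
#' @param source `"mip"` or `"native"`.
#' @param mip_thickness_mm Slab thickness for the MIP path.
#' @param prob_threshold Probability threshold for [binarize()].
#' @param hu_threshold HU threshold for [split_calcified()].
#' @param resample Passed to [predict_unet()].
#' @return One-row data frame (class `plaque_quant`): `exam_id`,
#'   `participant_id`, `round`, `source`, `pp_volume_ml`, `calc_volume_ml`.
#' @export
quantify_exam <- function(vol, model, source = c("mip", "native"),
                          mip_thickness_mm = 5, prob_threshold = 0.5,
                          hu_threshold = 100, resample = FALSE) {
  stopifnot(inherits(vol, "ct_volume"))
  source <- match.arg(source)
  if (source == "mip") {
    stack <- compute_mip(vol, mip_thickness_mm)
    probs <- predict_unet(model, stack, resample = resample)
    mask <- binarize(probs, prob_threshold)
    calc <- split_calcified(mask, stack$slabs, hu_threshold)
    ppv <- slab_mask_volume_ml(mask, stack)
    ccv <- slab_mask_volume_ml(calc, stack)
  } else {
    probs <- predict_unet(model, vol, resample = resample)
    mask <- binarize(probs, prob_threshold)
    calc <- split_calcified(mask, vol$voxels, hu_threshold)
    ppv <- native_mask_volume_ml(mask, vol)
    ccv <- native_mask_volume_ml(calc, vol)
  }
  out <- data.frame(exam_id = vol$exam_id, participant_id = vol$participant_id,
                    round = vol$round, source = source,
                    pp_volume_ml = ppv, calc_volume_ml = ccv,
                    stringsAsFactors = FALSE)
  class(out) <- c("plaque_quant", class(out))
  out
}

#' Longitudinal comparison of paired plaque volumes
#'
#' Compares per-participant volumes between screening rounds 2 and 3:
#' median absolute difference and median percent increase with seeded
#' bootstrap percentile confidence intervals, plus the two-sided paired
#' Wilcoxon signed-rank p-value. Participants with a zero round-2 volume
#' are excluded from the percent-increase summary (with a message) but kept
#' in the absolute differences.
#'
#' @param quants Data frame with `participant_id`, `round` (2 and 3), and a
#'   volume column.
#' @param volume_col Name of the volume column, default `"pp_volume_ml"`.
#' @param n_boot Bootstrap resamples for the CIs.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return List of class `longitudinal_result`: `pairs` (data frame with
#'   `participant_id`, `v2`, `v3`), `median_diff_ml` (+ `ci`),
#'   `median_pct_increase` (+ `ci`), `p_value`, `n`, `n_pct`.
#' @export
longitudinal_compare <- function(quants, volume_col = "pp_volume_ml",
                                 n_boot = 2000L, conf = 0.95, seed = 1L) {
  stopifnot(is.data.frame(quants),
            all(c("participant_id", "round", volume_col) %in% names(quants)))
  ids <- unique(quants$participant_id)
  rows <- lapply(ids, function(id) {
    q2 <- quants[quants$participant_id == id & quants$round == 2, volume_col]
    q3 <- quants[quants$participant_id == id & quants$round == 3, volume_col]
    c(n2 = length(q2), n3 = length(q3),
      v2 = if (length(q2)) q2[1] else NA_real_,
      v3 = if (length(q3)) q3[1] else NA_real_)
  })
  tab <- do.call(rbind, rows)
  bad <- ids[tab[, "n2"] != 1 | tab[, "n3"] != 1]
  if (length(bad))
    stop("each participant needs exactly one round-2 and one round-3 record; ",
         "offending: ", paste(bad, collapse = ", "))
  pairs <- data.frame(participant_id = as.character(ids),
                      v2 = tab[, "v2"], v3 = tab[, "v3"],
                      row.names = NULL, stringsAsFactors = FALSE)
  d <- pairs$v3 - pairs$v2
  pos <- pairs$v2 > 0
  if (any(!pos))
    message("longitudinal_compare: excluding ", sum(!pos),
            " participant(s) with zero round-2 volume from percent increases")
  pct <- 100 * d[pos] / pairs$v2[pos]
  alpha <- (1 - conf) / 2
  boot_ci <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_))
    meds <- with_seed_(seed, vapply(seq_len(n_boot), function(b)
      stats::median(sample(v, replace = TRUE)), numeric(1)))
    unname(stats::quantile(meds, c(alpha, 1 - alpha)))
  }
  wt <- paired_wilcoxon(pairs$v2, pairs$v3)
  structure(list(pairs = pairs,
                 median_diff_ml = stats::median(d),
                 median_diff_ci = boot_ci(d),
                 median_pct_increase = if (length(pct)) stats::median(pct)
                                       else NA_real_,
                 median_pct_ci = boot_ci(pct),
                 p_value = wt$p_value, n = nrow(pairs), n_pct = length(pct)),
            class = "longitudinal_result")
}

#' @export
print.longitudinal_result <- function(x, ...) {
  cat(sprintf("Longitudinal comparison (n = %d participants)\n", x$n))
  cat(sprintf("  median difference: %.2f mL (95%% CI %.2f to %.2f)\n",
              x$median_diff_ml, x$median_diff_ci[1], x$median_diff_ci[2]))
  cat(sprintf("  median %% increase: %.1f%% (95%% CI %.1f to %.1f; n = %d)\n",
              x$median_pct_increase, x$median_pct_ci[1], x$median_pct_ci[2],
              x$n_pct))
  cat(sprintf("  paired signed-rank p = %.4g\n", x$p_value))
  invisible(x)
}
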