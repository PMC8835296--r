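#' Pooled 2D pixel similarity between mask sets
#'
#' Micro-averaged similarity between predicted and ground-truth masks: the
#' per-pixel confusion counts (TP, FP, FN, TN) are pooled over all slices
#' first and the metrics computed once from the pooled counts. Pooling
#' handles plaque-free slices naturally — per-slice Dice would be undefined
#' on an empty/empty slice, whereas pooled counts just contribute true
#' negatives. The fully empty pooled case returns Dice 1 by convention, as
#' do precision and recall when their denominators vanish.
#'
#' @param pred,gt Binary masks (arrays/matrices of identical shape, or lists
#'   of matching slices).
#' @return List of class `similarity_report`: `dice`, `balanced_accuracy`,
#'   `recall`, `precision`, and the pooled `counts`.
#' @export
pixel_similarity <- function(pred, gt) {
  if (is.list(pred) || is.list(gt)) {
    if (!is.list(pred) || !is.list(gt) || length(pred) != length(gt))
      stop("pred and gt must have the same number of slices")
    pred <- simplify2array(pred)
    gt <- simplify2array(gt)
  }
  if (!identical(as.integer(dim(pred)), as.integer(dim(gt))))
    stop("pred geometry (", paste(dim(pred), collapse = "x"),
         ") does not match gt (", paste(dim(gt), collapse = "x"), ")")
  p <- as.integer(pred == 1)
  g <- as.integer(gt == 1)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  safe <- function(num, den) if (den == 0) 1 else num / den
  dice <- safe(2 * tp, 2 * tp + fp + fn)
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  specificity <- safe(tn, tn + fp)
  structure(list(dice = dice,
                 balanced_accuracy = (recall + specificity) / 2,
                 recall = recall, precision = precision,
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(paste0("2D pixel similarity (pooled over %s pixels)\n",
                     "  Balanced accuracy  %.3f\n  DICE               %.3f\n",
                     "  Recall             %.3f\n  Precision          %.3f\n"),
              format(sum(x$counts), big.mark = ","), x$balanced_accuracy,
              x$dice, x$recall, x$precision))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' CCC between two measurement series, the agreement-with-identity analogue
#' of Pearson correlation:
#' \eqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (n-denominator) moments, Lin's original definition. The
#' confidence interval uses the Fisher z-transform with Lin's asymptotic
#' standard error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param conf Confidence level.
#' @return List with `ccc`, `ci` (length 2), `n`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("CCC undefined: both series constant with equal means")
  ccc <- 2 * sxy / denom
  ci <- c(NA_real_, NA_real_)
  if (sx2 > 0 && sy2 > 0) {
    r <- sxy / sqrt(sx2 * sy2)
    if (abs(r) > 0 && abs(ccc) < 1) {
      u <- (mx - my) / (sx2 * sy2)^0.25
      z <- atanh(ccc)
      sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
      if (is.finite(sz2) && sz2 >= 0) {
        q <- stats::qnorm(1 - (1 - conf) / 2)
        ci <- tanh(z + c(-1, 1) * q * sqrt(sz2))
      }
    } else if (abs(ccc) == 1) ci <- c(ccc, ccc)
  }
  list(ccc = ccc, ci = ci, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and limits of agreement (mean +/- 1.96 sample SD of the
#' differences) of paired measurements, `d = x - y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `mean_diff`, `loa` (lower, upper), `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa = c(m - 1.96 * s, m + 1.96 * s), sd_diff = s,
       n = length(d))
}

#' Visual extent score of pleural plaques
#'
#' Ordinal product score used by expert readers: the thickness category of
#' the most thickened plaque (1: < 2 mm, 2: 2-5 mm, 3: 5-10 mm, 4: > 10 mm)
#' times the cumulative-extent category (1-4, fractions of the hemithorax
#' perimeter) times the plaque-count category (1: one, 2: two, 3: more than
#' two), giving a score in 1..48.
#'
#' @param thickness_cat Integer in 1..4.
#' @param extent_cat Integer in 1..4.
#' @param count_cat Integer in 1..3.
#' @return Integer score (vectorized).
#' @export
visual_extent_score <- function(thickness_cat, extent_cat, count_cat) {
  chk <- function(v, hi, nm) {
    v <- as.integer(v)
    if (any(is.na(v) | v < 1L | v > hi))
      stop("`", nm, "` must be an integer in 1..", hi)
    v
  }
  chk(thickness_cat, 4L, "thickness_cat") *
    chk(extent_cat, 4L, "extent_cat") *
    chk(count_cat, 3L, "count_cat")
}

#' Spearman correlation between volumes and visual scores
#'
#' Rank correlation (average ranks for ties) with the two-sided p-value of
#' the standard t approximation.
#'
#' @param volumes Numeric vector (e.g. AI-driven mL volumes).
#' @param scores Numeric/integer vector (e.g. visual extent scores).
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate_scores <- function(volumes, scores) {
  stopifnot(length(volumes) == length(scores), length(volumes) >= 3L)
  ct <- suppressWarnings(
    stats::cor.test(volumes, scores, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(volumes))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired volumes, zero differences dropped
#' (the standard convention). If every difference is zero the test is
#' degenerate; `p = 1` is reported with a warning.
#'
#' @param v2,v3 Paired numeric vectors (e.g. round-2 and round-3 volumes).
#' @return List with `statistic`, `p_value`, `n_nonzero`,
#'   `median_diff` (of v3 - v2).
#' @export
paired_wilcoxon <- function(v2, v3) {
  stopifnot(length(v2) == length(v3), length(v2) >= 1L)
  d <- v3 - v2
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("all paired differences are zero; reporting p = 1")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                median_diff = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(v3, v2, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = nz, median_diff = stats::median(d))
}

#' Assemble the full evaluation report
#'
#' Pools 2D similarity over a test set and computes the per-exam 3D
#' concordance (CCC and Bland-Altman) for total and calcified plaque, the
#' table layout of a test-cohort evaluation.
#'
#' @param pred_masks,gt_masks Lists (or arrays) of predicted / ground-truth
#'   plaque masks.
#' @param pred_calc,gt_calc The calcified counterparts.
#' @param pred_volumes,gt_volumes Per-exam total-plaque volumes in mL.
#' @param pred_calc_volumes,gt_calc_volumes Per-exam calcified volumes.
#' @return List of class `eval_report` with components `similarity_pp`,
#'   `similarity_calc`, `ccc_pp`, `ccc_calc`, `ba_pp`, `ba_calc`.
#' @export
evaluation_report <- function(pred_masks, gt_masks, pred_calc, gt_calc,
                              pred_volumes, gt_volumes,
                              pred_calc_volumes, gt_calc_volumes) {
  structure(list(
    similarity_pp = pixel_similarity(pred_masks, gt_masks),
    similarity_calc = pixel_similarity(pred_calc, gt_calc),
    ccc_pp = lin_ccc(pred_volumes, gt_volumes),
    ccc_calc = lin_ccc(pred_calc_volumes, gt_calc_volumes),
    ba_pp = bland_altman(pred_volumes, gt_volumes),
    ba_calc = bland_altman(pred_calc_volumes, gt_calc_volumes)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("== 2D pixel similarity (pooled) ==\n")
  cat(sprintf("%-20s %10s %10s\n", "", "Plaques", "Calcified"))
  for (m in c("balanced_accuracy", "dice", "recall", "precision"))
    cat(sprintf("%-20s %10.3f %10.3f\n", m,
                x$similarity_pp[[m]], x$similarity_calc[[m]]))
  cat("== 3D volume concordance ==\n")
  cat(sprintf("CCC                  %10.3f %10.3f\n",
              x$ccc_pp$ccc, x$ccc_calc$ccc))
  cat(sprintf("Bland-Altman mean    %10.2f %10.2f  mL\n",
              x$ba_pp$mean_diff, x$ba_calc$mean_diff))
  cat(sprintf("Bland-Altman LOA     (%.2f, %.2f) (%.2f, %.2f)  mL\n",
              x$ba_pp$loa[1], x$ba_pp$loa[2],
              x$ba_calc$loa[1], x$ba_calc$loa[2]))
  invisible(x)
}
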