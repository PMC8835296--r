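# brute-force confusion-matrix oracle: per-pixel loop
oracle_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

test_that("pixel similarity matches hand counts", {
  gt <- matrix(0L, 4, 4); gt[1:6] <- 1L
  pred <- matrix(0L, 4, 4); pred[c(1:3, 8)] <- 1L # overlap 3, |pred| 4
  s <- pixel_similarity(pred, gt)
  expect_equal(s$dice, 2 * 3 / (4 + 6))
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 0.5)
  expect_equal(s$balanced_accuracy, (0.5 + 9 / 10) / 2)
})

test_that("pixel similarity degenerate cases follow the conventions", {
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  s <- pixel_similarity(m, m)
  expect_equal(unlist(s[c("dice", "balanced_accuracy", "recall",
                          "precision")]),
               c(dice = 1, balanced_accuracy = 1, recall = 1, precision = 1))
  # predict-everything: recall 1, specificity 0 -> balanced accuracy 0.5
  all1 <- matrix(1L, 2, 2)
  s2 <- pixel_similarity(all1, m)
  expect_equal(s2$recall, 1)
  expect_equal(s2$balanced_accuracy, 0.5)
  # empty/empty pooled case: dice 1 by convention
  z <- matrix(0L, 2, 2)
  expect_equal(pixel_similarity(z, z)$dice, 1)
  expect_error(pixel_similarity(list(m), list(m, m)), "same number")
})

test_that("pooled metrics equal the brute-force oracle on random masks", {
  set.seed(99)
  for (rep in 1:20) {
    pred <- matrix(rbinom(256, 1, runif(1, 0, 0.5)), 16, 16)
    gt <- matrix(rbinom(256, 1, runif(1, 0, 0.5)), 16, 16)
    cf <- oracle_confusion(pred, gt)
    s <- pixel_similarity(pred, gt)
    expect_identical(s$counts, cf)
    if (2 * cf["tp"] + cf["fp"] + cf["fn"] > 0)
      expect_equal(s$dice,
                   unname(2 * cf["tp"] / (2 * cf["tp"] + cf["fp"] + cf["fn"])))
  }
})

test_that("Lin CCC matches closed-form cases", {
  expect_equal(lin_ccc(c(1, 5, 9), c(1, 5, 9))$ccc, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1))$ccc, -1)
  expect_error(lin_ccc(c(2, 2, 2), c(2, 2, 2)), "undefined")
})

test_that("CCC equals Pearson r when means and variances agree", {
  set.seed(7)
  x <- rnorm(40)
  y <- rev(sort(rnorm(40))) # arbitrary second series
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x) # match moments
  expect_equal(lin_ccc(x, y)$ccc, cor(x, y), tolerance = 1e-10)
})

test_that("CCC is invariant under a common permutation and |ccc| <= |r|", {
  set.seed(8)
  x <- runif(25, 0, 50); y <- x + rnorm(25, 2, 4)
  perm <- sample(25)
  expect_equal(lin_ccc(x[perm], y[perm])$ccc, lin_ccc(x, y)$ccc)
  expect_lte(abs(lin_ccc(x, y)$ccc), abs(cor(x, y)))
})

test_that("Bland-Altman mean difference and LOA are exact", {
  x <- c(4, 7, 1)
  expect_equal(bland_altman(x, x)$mean_diff, 0)
  expect_equal(bland_altman(x, x)$loa, c(0, 0))
  expect_equal(bland_altman(x + 2, x)$loa, c(2, 2))
  ba <- bland_altman(c(1, 2, 3), c(0, 0, 0)) # d = (1,2,3), sd = 1
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$loa, c(2 - 1.96, 2 + 1.96))
})

test_that("visual extent score is the validated category product", {
  expect_equal(visual_extent_score(1, 1, 1), 1L)
  expect_equal(visual_extent_score(4, 4, 3), 48L)
  expect_equal(visual_extent_score(2, 3, 1), 6L)
  expect_equal(visual_extent_score(c(1, 4), c(1, 4), c(1, 3)), c(1L, 48L))
  expect_error(visual_extent_score(5, 1, 1), "thickness_cat")
  expect_error(visual_extent_score(1, 0, 1), "extent_cat")
  expect_error(visual_extent_score(1, 1, 4), "count_cat")
})

test_that("Spearman correlation recovers monotone relations", {
  v <- c(2, 9, 4, 30, 12)
  expect_equal(correlate_scores(v, rank(v))$rho, 1)
  expect_equal(correlate_scores(v, -v)$rho, -1)
  # volumes coarsened into noisy ordinal scores stay strongly correlated
  set.seed(10)
  vols <- runif(40, 1, 80)
  scores <- pmin(48, pmax(1, round(vols / 2 + rnorm(40, 0, 4))))
  cs <- correlate_scores(vols, scores)
  expect_gt(cs$rho, 0.5)
  expect_lt(cs$p_value, 0.001)
})

test_that("paired Wilcoxon behaves across degenerate and shifted inputs", {
  v <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10)
  expect_warning(w0 <- paired_wilcoxon(v, v), "zero")
  expect_equal(w0$p_value, 1)
  w1 <- paired_wilcoxon(v, v + 1) # all positive differences, n = 10
  expect_lt(w1$p_value, 0.01)
  w2 <- paired_wilcoxon(v + 1, v)
  expect_equal(w2$p_value, w1$p_value)
  expect_equal(w2$median_diff, -w1$median_diff)
})

test_that("CCC confidence intervals bracket the estimate and tighten with n", {
  set.seed(12)
  x <- runif(10, 0, 60); y <- x + rnorm(10, 0, 3)
  small <- lin_ccc(x, y)
  expect_true(small$ci[1] <= small$ccc && small$ccc <= small$ci[2])
  expect_true(all(abs(small$ci) <= 1))
  xl <- runif(60, 0, 60); yl <- xl + rnorm(60, 0, 3)
  large <- lin_ccc(xl, yl)
  expect_lt(diff(large$ci), diff(small$ci))
})
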