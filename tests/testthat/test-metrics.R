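# Confusion-matrix metrics and their algebraic identities.

test_that("confusion counts pixels with lesion as positive", {
  ones <- matrix(1, 5, 5)
  zeros <- matrix(0, 5, 5)
  cm <- confusion(ones, ones)
  expect_equal(unclass(cm), list(TP = 25L, FP = 0L, FN = 0L, TN = 0L),
               ignore_attr = TRUE)
  cm2 <- confusion(ones, zeros)
  expect_equal(cm2$TP, 0L)
  expect_equal(cm2$FP, 25L)
  # complement: no agreement at all
  set.seed(1)
  g <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cm3 <- confusion(1 - g, g)
  expect_equal(cm3$TP, 0L)
  expect_equal(cm3$TN, 0L)
  expect_error(confusion(ones, matrix(1, 4, 4)), "shapes differ")
  expect_error(confusion(matrix(2, 5, 5), ones), "binary")
})

test_that("confusion agrees with a per-pixel counting oracle on random masks", {
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(rbinom(100, 1, runif(1)), 10, 10)
    g <- matrix(rbinom(100, 1, runif(1)), 10, 10)
    cm <- confusion(p, g)
    # independent elementwise loop
    tp <- fp <- fn <- tn <- 0L
    for (k in seq_along(p)) {
      if (p[k] == 1 && g[k] == 1) tp <- tp + 1L
      else if (p[k] == 1) fp <- fp + 1L
      else if (g[k] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(c(cm$TP, cm$FP, cm$FN, cm$TN), c(tp, fp, fn, tn))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, length(p))
  }
})

test_that("metric formulas evaluate exactly", {
  cm <- structure(list(TP = 2, FP = 1, FN = 1, TN = 6), class = "confusion_matrix")
  expect_equal(dice(cm), 4 / 6)
  expect_equal(iou(cm), 0.5)
  expect_equal(accuracy(cm), 8 / 10)
  expect_equal(sensitivity(cm), 2 / 3)
  expect_equal(specificity(cm), 6 / 7)
  perfect <- confusion(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 0, 1, 0), 2))
  for (f in list(accuracy, dice, iou, sensitivity, specificity)) {
    expect_equal(as.numeric(f(perfect)), 1)
  }
})

test_that("Dice = 2 IoU / (1 + IoU) and bounds hold on 10,000 random matrices", {
  set.seed(7)
  n <- 10000L
  TP <- sample(0:500, n, replace = TRUE)
  FP <- sample(0:500, n, replace = TRUE)
  FN <- sample(0:500, n, replace = TRUE)
  TN <- sample(0:500, n, replace = TRUE)
  res <- vapply(seq_len(n), function(k) {
    cm <- structure(list(TP = TP[k], FP = FP[k], FN = FN[k], TN = TN[k]),
                    class = "confusion_matrix")
    c(as.numeric(dice(cm)), as.numeric(iou(cm)), accuracy(cm),
      as.numeric(sensitivity(cm)), as.numeric(specificity(cm)))
  }, numeric(5))
  d <- res[1, ]; i <- res[2, ]
  expect_lt(max(abs(d - 2 * i / (1 + i))), 1e-12)
  expect_true(all(d >= i))
  expect_true(all(res >= 0 & res <= 1))
})

test_that("metrics agree with a set-intersection oracle on random masks", {
  set.seed(11)
  for (i in 1:25) {
    p <- matrix(rbinom(144, 1, runif(1, 0.1, 0.9)), 12, 12)
    g <- matrix(rbinom(144, 1, runif(1, 0.1, 0.9)), 12, 12)
    A <- which(p == 1); B <- which(g == 1)
    inter <- length(intersect(A, B)); uni <- length(union(A, B))
    cm <- confusion(p, g)
    if (uni > 0) {
      expect_equal(as.numeric(iou(cm)), inter / uni)
      expect_equal(as.numeric(dice(cm)), 2 * inter / (length(A) + length(B)))
    }
    if (length(B) > 0) expect_equal(as.numeric(sensitivity(cm)), inter / length(B))
  }
})

test_that("empty-empty pairs count as correct rejection; other degenerate denominators flag 0", {
  empty <- matrix(0, 4, 4)
  cm <- confusion(empty, empty)
  expect_equal(as.numeric(dice(cm)), 1)
  expect_equal(as.numeric(iou(cm)), 1)
  expect_equal(as.numeric(sensitivity(cm)), 1)
  # prediction marks pixels where there is no lesion at all
  cm2 <- confusion(matrix(c(1, rep(0, 15)), 4, 4), empty)
  expect_equal(as.numeric(sensitivity(cm2)), 0)
  expect_true(attr(sensitivity(cm2), "degenerate"))
})

test_that("pooled and per-slice aggregation behave as documented", {
  m1 <- matrix(c(1, 1, 0, 0), 2, 2)
  # single slice: both modes identical
  r1 <- evaluate_masks(list(m1), list(m1))
  expect_equal(r1$dice[r1$mode == "pooled"], r1$dice[r1$mode == "per_slice_mean"])
  # two identical slices: still identical
  r2 <- evaluate_masks(list(m1, m1), list(m1, m1))
  expect_equal(r2$dice[1], r2$dice[2])
  # constructed unequal case, hand-computed:
  # slice A: pred = gt, 4 lesion pixels -> dice 1
  # slice B: pred 2 pixels, gt 4 pixels, overlap 2 -> dice 2*2/(2+4) = 2/3
  gtB <- matrix(c(1, 1, 1, 1, rep(0, 12)), 4, 4)
  prB <- matrix(c(1, 1, rep(0, 14)), 4, 4)
  r3 <- evaluate_masks(list(m1, prB), list(m1, gtB))
  per <- r3$dice[r3$mode == "per_slice_mean"]
  pooled <- r3$dice[r3$mode == "pooled"]
  expect_equal(per, (1 + 2 / 3) / 2)
  # pooled: TP = 2+2, FP = 0, FN = 0+2 -> dice = 8/10
  expect_equal(pooled, 8 / 10)
  expect_true(abs(per - pooled) > 1e-6)
  expect_error(evaluate_masks(list(m1), list(m1, m1)), "different lengths")
})

test_that("metric reports round-trip through CSV", {
  r <- evaluate_masks(list(matrix(c(1, 0, 0, 1), 2)), list(matrix(c(1, 1, 0, 0), 2)))
  path <- tempfile(fileext = ".csv")
  write_metric_report(r, path)
  back <- read.csv(path)
  expect_equal(back$dice, r$dice)
  expect_true(all(c("accuracy", "iou", "dice", "sensitivity", "specificity") %in% names(back)))
})
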