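test_that("confusion counts match a hand-enumerated 2x2 toy case", {
  p <- matrix(c(1L, 1L, 0L, 2L), 2, 2)
  t_ <- matrix(c(1L, 0L, 0L, 2L), 2, 2)
  cf <- confusion(p, t_)
  # by hand: pixel-wise pairs (pred,truth) = (1,1), (1,0), (0,0), (2,2)
  expect_identical(cf["lumen", ], c(TP = 1L, FP = 1L, FN = 0L, TN = 2L))
  expect_identical(cf["background", ], c(TP = 1L, FP = 0L, FN = 1L, TN = 2L))
  expect_identical(cf["media_plaque", ], c(TP = 1L, FP = 0L, FN = 0L, TN = 3L))
  expect_identical(cf["stent", ], c(TP = 0L, FP = 0L, FN = 0L, TN = 4L))
  # every class row sums to the pixel count
  expect_true(all(rowSums(cf) == 4L))

  # identical masks: no errors anywhere
  cf2 <- confusion(t_, t_)
  expect_true(all(cf2[, c("FP", "FN")] == 0L))

  # conservation: TP + FN equals the truth pixel count of each class
  withr::local_seed(12)
  a <- random_mask(16); b <- random_mask(16)
  cf3 <- confusion(a, b)
  expect_identical(unname(cf3[, "TP"] + cf3[, "FN"]),
                   vapply(0:4, function(cl) sum(b$labels == cl), integer(1)))
  expect_error(confusion(matrix(0L, 3, 3), matrix(0L, 4, 4)), "shapes differ")
})

test_that("IoU, Dice and their algebraic identity hold on count triples", {
  expect_equal(iou(86, 7, 7), 0.86)
  expect_equal(dice(86, 7, 7), 2 * 86 / 186)
  expect_equal(iou(0, 5, 3), 0)
  expect_equal(dice(0, 5, 3), 0)
  # absent-class convention
  expect_equal(iou(0, 0, 0), 1)
  expect_equal(dice(0, 0, 0), 1)
  # Dice = 2 IoU / (1 + IoU) for arbitrary counts
  withr::local_seed(13)
  for (i in 1:50) {
    tp <- sample(0:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    i_ <- iou(tp, fp, fn)
    expect_equal(dice(tp, fp, fn), 2 * i_ / (1 + i_), tolerance = 1e-12)
  }
})

test_that("accuracy, recall and precision follow the 2x2 formulas", {
  m <- binary_metrics(tp = 19, fp = 1, tn = 79, fn = 1)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$recall, 0.95)
  expect_equal(m$precision, 0.95)
  all_ok <- binary_metrics(10, 0, 90, 0)
  expect_equal(unlist(all_ok), c(accuracy = 1, recall = 1, precision = 1))
  # 0/0 conventions
  expect_equal(binary_metrics(0, 0, 5, 0)$recall, 1)
  expect_equal(binary_metrics(0, 0, 5, 0)$precision, 1)
  expect_error(binary_metrics(0, 0, 0, 0), "empty tally")

  # random flag vectors against a hand tally
  withr::local_seed(14)
  tf <- runif(200) < 0.3; pf <- ifelse(runif(200) < 0.15, !tf, tf)
  tally <- table(factor(pf, c(FALSE, TRUE)), factor(tf, c(FALSE, TRUE)))
  m2 <- binary_metrics(tp = tally["TRUE", "TRUE"], fp = tally["TRUE", "FALSE"],
                       tn = tally["FALSE", "FALSE"], fn = tally["FALSE", "TRUE"])
  expect_equal(m2$accuracy, mean(pf == tf))
  expect_equal(m2$recall, sum(pf & tf) / sum(tf))
  expect_equal(m2$precision, sum(pf & tf) / sum(pf))
})

test_that("pooled and macro aggregation modes are tagged and hand-verifiable", {
  # single pair: both modes agree
  withr::local_seed(15)
  a <- random_mask(16); b <- random_mask(16)
  mp <- aggregate_metrics(list(a), list(b), "pooled")
  mm <- aggregate_metrics(list(a), list(b), "macro_per_image")
  expect_equal(mp$per_class$iou, mm$per_class$iou)
  expect_identical(mp$aggregation_mode, "pooled")
  expect_identical(mm$aggregation_mode, "macro_per_image")

  # perfect predictions: all ones in both modes
  for (mode in c("pooled", "macro_per_image")) {
    r <- aggregate_metrics(list(b, a), list(b, a), mode)
    expect_equal(r$mean_iou, 1)
    expect_equal(r$mean_dice, 1)
  }

  # two constructed pairs with unequal class-1 sizes: modes differ and each
  # equals its hand computation
  t1 <- matrix(0L, 4, 4); t1[1:2, 1:2] <- 1L       # 4 lumen px
  p1 <- t1; p1[1, 1] <- 0L                         # miss 1 -> im1: TP 3 FN 1
  t2 <- matrix(0L, 4, 4); t2[1, 1] <- 1L           # 1 lumen px
  p2 <- t2                                         # exact  -> im2: TP 1
  pool <- aggregate_metrics(list(p1, p2), list(t1, t2), "pooled")
  macro <- aggregate_metrics(list(p1, p2), list(t1, t2), "macro_per_image")
  expect_equal(pool$per_class$iou[2], 4 / 5)               # (3+1)/(3+1+1)
  expect_equal(macro$per_class$iou[2], (3 / 4 + 1) / 2)    # mean(3/4, 1/1)
  expect_false(isTRUE(all.equal(pool$per_class$iou[2], macro$per_class$iou[2])))

  # classes absent from every truth mask are excluded from the means
  expect_identical(pool$n, 2L)                     # background + lumen only
  expect_error(aggregate_metrics(list(), list()), "argument error")
})

test_that("binary-collapse IoU equals the one-vs-rest IoU of the same class", {
  withr::local_seed(16)
  for (i in 1:5) {
    a <- random_mask(24); b <- random_mask(24)
    cf <- confusion(a, b)
    for (cl in names(ivus_classes())) {
      ba <- collapse_to_binary(a, cl); bb <- collapse_to_binary(b, cl)
      tp <- sum(ba == 1 & bb == 1); fp <- sum(ba == 1 & bb == 0)
      fn <- sum(ba == 0 & bb == 1)
      expect_equal(iou(cf[cl, "TP"], cf[cl, "FP"], cf[cl, "FN"]),
                   iou(tp, fp, fn))
    }
  }
})

test_that("metrics are invariant under a shared pixel permutation", {
  withr::local_seed(17)
  a <- random_mask(16); b <- random_mask(16)
  perm <- sample(16 * 16)
  ap <- label_mask(matrix(a$labels[perm], 16, 16), a$pixel_spacing)
  bp <- label_mask(matrix(b$labels[perm], 16, 16), b$pixel_spacing)
  expect_identical(confusion(a, b), confusion(ap, bp))
})

test_that("image-level classification tallies planted disagreements", {
  # frames encoded as 2x2 masks; rule: any lumen pixel
  mk_pos <- label_mask(matrix(c(1L, 0L, 0L, 0L), 2, 2), 1)
  mk_neg <- label_mask(matrix(0L, 2, 2), 1)
  rule <- function(m) any(m$labels == 1L)
  truth <- c(rep(list(mk_pos), 30), rep(list(mk_neg), 70))
  pred <- truth
  pred[1:3] <- list(mk_neg)      # 3 false negatives
  pred[31:32] <- list(mk_pos)    # 2 false positives
  r <- image_level_classification(truth, pred, rule)
  expect_equal(r$accuracy, 0.95)
  expect_equal(r$recall, 27 / 30)
  expect_equal(r$precision, 27 / 29)
  all1 <- image_level_classification(truth, truth, rule)
  expect_equal(unlist(all1[c("accuracy", "recall", "precision")]),
               c(accuracy = 1, recall = 1, precision = 1))
  expect_error(image_level_classification(list(), list(), rule), "argument error")
})

test_that("lumen-area correlation reports Spearman rho, R2, and p-value", {
  x <- c(1.2, 2.5, 3.1, 4.7, 5.0, 6.3, 7.8, 8.1, 9.9, 11.4)
  expect_equal(lumen_area_correlation(x, x)$rho, 1)
  expect_equal(lumen_area_correlation(x, x)$r_squared, 1)
  expect_equal(lumen_area_correlation(x, rev(x))$rho, -1)

  # hand rank-formula oracle (no ties): rho = 1 - 6 sum(d^2) / (n(n^2-1))
  withr::local_seed(18)
  y <- x + rnorm(10, sd = 2)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (10 * (100 - 1))
  r <- lumen_area_correlation(x, y)
  expect_equal(r$rho, rho_hand)
  expect_equal(r$r_squared, cor(x, y)^2)
  expect_true(r$p_value >= 0 && r$p_value <= 1)

  expect_error(lumen_area_correlation(x[1:2], x[1:2]), "at least 3")
  expect_error(lumen_area_correlation(rep(1, 5), x[1:5]), "zero variance")
  expect_error(lumen_area_correlation(x, x[1:5]), "length")
})
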