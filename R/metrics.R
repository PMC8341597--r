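#' One-vs-rest pixel confusion counts
#'
#' For each of the five classes, pixels are tallied into TP/FP/TN/FN by
#' treating that class against all others, on the basis of per-pixel
#' agreement between the predicted and ground-truth masks. The four counts
#' sum to the total pixel count for every class.
#'
#' @param pred,truth `ivus_mask` objects (or integer label matrices) of
#'   identical shape.
#' @return An `ivus_confusion`: 5 x 4 integer matrix (rows classes, columns
#'   TP, FP, FN, TN).
#' @export
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "ivus_mask")) pred$labels else pred
  t_ <- if (inherits(truth, "ivus_mask")) truth$labels else truth
  if (!all(dim(p) == dim(t_)))
    stop("argument error: mask shapes differ", call. = FALSE)
  tab <- table(factor(p, levels = 0:4), factor(t_, levels = 0:4))
  tp <- diag(tab)
  fp <- rowSums(tab) - tp    # predicted c, truth other
  fn <- colSums(tab) - tp    # truth c, predicted other
  tn <- length(p) - tp - fp - fn
  out <- cbind(TP = as.integer(tp), FP = as.integer(fp),
               FN = as.integer(fn), TN = as.integer(tn))
  rownames(out) <- names(IVUS_CLASSES)
  structure(out, class = c("ivus_confusion", class(out)))
}

#' Intersection over union from confusion counts
#'
#' IoU = TP / (TP + FP + FN), with the convention that a class absent from
#' both masks (TP = FP = FN = 0) scores 1.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return IoU values in \[0, 1\].
#' @export
iou <- function(tp, fp, fn) {
  den <- tp + fp + fn
  ifelse(den == 0, 1, tp / den)
}

#' Dice score from confusion counts
#'
#' Dice = 2 TP / (2 TP + FP + FN); same absent-class convention as [iou()].
#' Algebraically Dice = 2 IoU / (1 + IoU) when computed from the same
#' counts.
#'
#' @inheritParams iou
#' @return Dice values in \[0, 1\].
#' @export
dice <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 1, 2 * tp / den)
}

#' Binary classification metrics from a 2x2 tally
#'
#' accuracy = (TP + TN) / all, recall = TP / (TP + FN),
#' precision = TP / (TP + FP). Recall and precision return 1 on an empty
#' denominator (nothing to miss / no false alarms possible).
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return List with `accuracy`, `recall`, `precision`.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) stop("argument error: empty tally", call. = FALSE)
  list(accuracy = (tp + tn) / total,
       recall = if (tp + fn == 0) 1 else tp / (tp + fn),
       precision = if (tp + fp == 0) 1 else tp / (tp + fp))
}

#' Aggregate segmentation metrics over mask pairs
#'
#' Two explicit aggregation modes, always tagged in the report, because
#' mixing them silently produces incomparable means:
#' * `pooled` — confusion counts are summed over all pairs, per-class IoU
#'   and Dice are computed from the pooled counts, and the means average the
#'   classes present in at least one truth mask.
#' * `macro_per_image` — IoU/Dice are computed per image per class, averaged
#'   over the images whose truth contains the class, then averaged over
#'   classes present somewhere.
#'
#' Classes absent from every truth mask are excluded from the means (the
#' absent-class convention would otherwise let a stent-free evaluation set
#' inflate them).
#'
#' @param pred_masks,truth_masks Lists of masks (same length, >= 1).
#' @param mode `"pooled"` or `"macro_per_image"`.
#' @return A `metrics_report`: per-class table, `mean_iou`, `mean_dice`,
#'   `aggregation_mode`, and `n` (number of classes averaged).
#' @export
aggregate_metrics <- function(pred_masks, truth_masks,
                              mode = c("pooled", "macro_per_image")) {
  mode <- match.arg(mode)
  n <- length(pred_masks)
  if (n == 0L || length(truth_masks) != n)
    stop("argument error: need >= 1 prediction/truth pair of equal count",
         call. = FALSE)
  confs <- lapply(seq_len(n), function(i) confusion(pred_masks[[i]], truth_masks[[i]]))
  truth_present <- sapply(confs, function(cf) cf[, "TP"] + cf[, "FN"] > 0)  # 5 x n
  class_in_any <- rowSums(truth_present) > 0

  if (mode == "pooled") {
    pool <- Reduce(`+`, confs)
    per_iou <- iou(pool[, "TP"], pool[, "FP"], pool[, "FN"])
    per_dice <- dice(pool[, "TP"], pool[, "FP"], pool[, "FN"])
  } else {
    per_iou <- per_dice <- rep(NA_real_, 5)
    for (c in 1:5) {
      imgs <- which(truth_present[c, ])
      if (!length(imgs)) next
      vi <- vapply(imgs, function(i)
        iou(confs[[i]][c, "TP"], confs[[i]][c, "FP"], confs[[i]][c, "FN"]),
        numeric(1))
      vd <- vapply(imgs, function(i)
        dice(confs[[i]][c, "TP"], confs[[i]][c, "FP"], confs[[i]][c, "FN"]),
        numeric(1))
      per_iou[c] <- mean(vi); per_dice[c] <- mean(vd)
    }
  }
  keep <- class_in_any
  per_class <- data.frame(class = names(IVUS_CLASSES),
                          iou = as.numeric(per_iou),
                          dice = as.numeric(per_dice),
                          in_truth = as.logical(class_in_any),
                          row.names = NULL)
  structure(list(per_class = per_class,
                 mean_iou = mean(per_iou[keep]),
                 mean_dice = mean(per_dice[keep]),
                 aggregation_mode = mode,
                 n = sum(keep)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> mode = %s (n = %d classes averaged)\n",
              x$aggregation_mode, x$n))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("mean IoU %.4f   mean Dice %.4f\n", x$mean_iou, x$mean_dice))
  invisible(x)
}

#' Image-level classification metrics for a clinical rule
#'
#' Applies a mask-to-flag rule (for instance "lumen area < 4 mm^2" or
#' "severe calcification") to every ground-truth and predicted mask, tallies
#' the frame-level 2x2 table, and reports accuracy, recall, precision.
#'
#' @param truth_masks,pred_masks Lists of masks (same nonzero length).
#' @param rule Function mapping a mask to a single logical flag.
#' @param pred_rule Optional distinct rule for predictions (defaults to
#'   `rule`).
#' @return List with `accuracy`, `recall`, `precision` and the `counts`
#'   (tp, fp, tn, fn).
#' @export
image_level_classification <- function(truth_masks, pred_masks, rule,
                                       pred_rule = rule) {
  n <- length(truth_masks)
  if (n == 0L || length(pred_masks) != n)
    stop("argument error: empty or mismatched frame sets", call. = FALSE)
  tf <- vapply(truth_masks, function(m) isTRUE(rule(m)), logical(1))
  pf <- vapply(pred_masks, function(m) isTRUE(pred_rule(m)), logical(1))
  tp <- sum(pf & tf); fp <- sum(pf & !tf)
  fn <- sum(!pf & tf); tn <- sum(!pf & !tf)
  out <- binary_metrics(tp, fp, tn, fn)
  out$counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}

#' Correlation between true and predicted lumen areas
#'
#' Spearman's rank correlation (tie-corrected ranks; exact null distribution
#' for n <= 10, t-approximation beyond) plus the squared Pearson correlation
#' as the coefficient of determination of the simple regression.
#'
#' @param truth_areas,pred_areas Equal-length numeric vectors, n >= 3.
#' @return List with `rho`, `r_squared`, `p_value`, `n`.
#' @export
lumen_area_correlation <- function(truth_areas, pred_areas) {
  n <- length(truth_areas)
  if (n != length(pred_areas))
    stop("argument error: area vectors differ in length", call. = FALSE)
  if (n < 3L)
    stop("undefined statistic: need at least 3 paired areas", call. = FALSE)
  if (stats::sd(truth_areas) == 0 || stats::sd(pred_areas) == 0)
    stop("undefined statistic: zero variance in areas", call. = FALSE)
  has_ties <- anyDuplicated(truth_areas) || anyDuplicated(pred_areas)
  ct <- suppressWarnings(
    cor.test(truth_areas, pred_areas, method = "spearman",
             exact = n <= 10 && !has_ties))
  list(rho = unname(ct$estimate),
       r_squared = cor(truth_areas, pred_areas)^2,
       p_value = ct$p.value,
       n = n)
}

#' Write a metrics report as JSON and CSV
#'
#' CSV rows are IoU and Dice, columns the four vessel classes (background
#' excluded), mirroring the usual result-table layout; the JSON carries the
#' full report including the aggregation-mode tag.
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      aggregation_mode = report$aggregation_mode,
      n_classes_averaged = report$n,
      per_class = report$per_class,
      mean_iou = report$mean_iou, mean_dice = report$mean_dice),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    pc <- report$per_class[report$per_class$class != "background", ]
    tab <- rbind(IoU = pc$iou, Dice = pc$dice)
    colnames(tab) <- pc$class
    write.csv(tab, csv_path)
  }
  invisible(report)
}
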