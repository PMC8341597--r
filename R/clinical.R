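#' Lumen cross-sectional area of a mask
#'
#' Pixel-count estimator: number of lumen pixels times the squared pixel
#' spacing. Additive and monotone in the lumen pixel count; zero iff the
#' mask contains no lumen.
#'
#' @param mask An `ivus_mask`.
#' @return Lumen area in mm^2.
#' @export
lumen_area <- function(mask) {
  validate_mask(mask)
  sum(mask$labels == IVUS_CLASSES[["lumen"]]) * mask$pixel_spacing^2
}

#' Classify a lumen as significantly narrowed
#'
#' A lumen is significantly narrowed when its area is strictly below
#' 4 mm^2, the threshold associating non-culprit lesions with elevated risk
#' of major adverse cardiac events. The inequality is strict: 4.00 mm^2 is
#' not narrowed.
#'
#' @param area Lumen area in mm^2 (>= 0).
#' @param threshold_mm2 Decision threshold, mm^2.
#' @return Logical flag.
#' @export
classify_narrowed <- function(area, threshold_mm2 = 4.0) {
  if (any(!is.finite(area)) || any(area < 0))
    stop("argument error: area must be non-negative", call. = FALSE)
  area < threshold_mm2
}

#' Calcification arc, quadrant count, and severity
#'
#' Angles of all calcification pixels about the lumen centroid are binned
#' into 1-degree bins; the arc is the count of occupied bins (so several
#' disjoint deposits sum their occupied angle rather than spanning their
#' convex hull). Quadrants are the four fixed 90-degree sectors
#' (0-90, 90-180, 180-270, 270-360, measured from the image +x axis toward
#' +y). Severe calcification means an arc in more than two quadrants
#' (`quadrant_count > 2`); the alternative `"arc180"` rule flags arcs wider
#' than 180 degrees instead.
#'
#' @param mask An `ivus_mask`.
#' @param rule Severity rule: `"quadrants"` (default) or `"arc180"`.
#' @param center_fallback If no lumen pixels exist while calcification does,
#'   fall back to the image center as angular reference instead of erroring.
#' @return List with `calc_arc_deg`, `quadrant_count`, `severe_calc`, and
#'   the occupied `quadrants`.
#' @export
calcification_arc <- function(mask, rule = c("quadrants", "arc180"),
                              center_fallback = FALSE) {
  validate_mask(mask)
  rule <- match.arg(rule)
  lab <- mask$labels
  calc <- which(lab == IVUS_CLASSES[["calcification"]], arr.ind = TRUE)
  if (nrow(calc) == 0L)
    return(list(calc_arc_deg = 0L, quadrant_count = 0L, severe_calc = FALSE,
                quadrants = integer(0)))
  lum <- which(lab == IVUS_CLASSES[["lumen"]], arr.ind = TRUE)
  if (nrow(lum) == 0L) {
    if (!center_fallback)
      stop("reference error: calcification present but no lumen pixels ",
           "(set center_fallback = TRUE to use the image center)", call. = FALSE)
    cx <- (ncol(lab) - 1) / 2; cy <- (nrow(lab) - 1) / 2
  } else {
    cx <- mean(lum[, "col"] - 1); cy <- mean(lum[, "row"] - 1)
  }
  ang <- (atan2(calc[, "row"] - 1 - cy, calc[, "col"] - 1 - cx) * 180 / pi) %% 360
  bins <- unique(floor(ang))
  quads <- sort(unique(bins %/% 90L))
  arc <- length(bins)
  nq <- length(quads)
  severe <- if (rule == "quadrants") nq > 2L else arc > 180L
  list(calc_arc_deg = arc, quadrant_count = nq, severe_calc = severe,
       quadrants = quads)
}

#' Extract stent-strut centroids from a mask
#'
#' Connected components (8-connectivity) of the stent class with at least
#' `min_pixels` pixels, each reported by its pixel centroid. The size floor
#' suppresses single-pixel noise.
#'
#' @param mask An `ivus_mask`.
#' @param min_pixels Minimum component size in pixels.
#' @return Matrix with columns `x`, `y` (0-based pixel coordinates), one
#'   row per detected strut.
#' @export
extract_struts <- function(mask, min_pixels = 3L) {
  validate_mask(mask)
  bin <- matrix(as.integer(mask$labels == IVUS_CLASSES[["stent"]]),
                nrow(mask$labels), ncol(mask$labels))
  comp <- cpp_label_components(bin)
  ids <- setdiff(unique(as.integer(comp)), 0L)
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  for (id in ids) {
    px <- which(comp == id, arr.ind = TRUE)
    if (nrow(px) >= min_pixels)
      out <- rbind(out, c(x = mean(px[, "col"] - 1), y = mean(px[, "row"] - 1)))
  }
  out
}

#' Strut detection recall
#'
#' One-to-one matching between predicted and true strut centroids within a
#' distance tolerance, then `recall = matched / n_true`. The matching is the
#' maximum-cardinality assignment within `tol_px` (exact for up to 14 struts
#' on the smaller side, greedy nearest-pair beyond), with ties broken by
#' minimum total distance, so the score does not depend on input ordering.
#' When no true struts exist the recall is defined as 1 (such frames are
#' excluded from stent-frame aggregates).
#'
#' @param predicted,truth Matrices with columns `x`, `y` (px), one row per
#'   strut.
#' @param tol_px Match tolerance, px (> 0).
#' @return Recall in \[0, 1\].
#' @export
strut_recall <- function(predicted, truth, tol_px = 5) {
  if (tol_px <= 0) stop("argument error: tol_px must be > 0", call. = FALSE)
  predicted <- as_strut_matrix(predicted); truth <- as_strut_matrix(truth)
  nt <- nrow(truth)
  if (nt == 0L) return(1)
  np <- nrow(predicted)
  if (np == 0L) return(0)
  d <- sqrt(outer(truth[, 1], predicted[, 1], "-")^2 +
            outer(truth[, 2], predicted[, 2], "-")^2)   # nt x np
  small_is_truth <- nt <= np
  dmat <- if (small_is_truth) d else t(d)
  if (nrow(dmat) <= 14L) {
    m <- cpp_max_matching(dmat, tol_px)$n_matched
  } else {
    m <- greedy_matching(dmat, tol_px)
  }
  m / nt
}

as_strut_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), 0, 2))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("strut centroids must be n x 2 (x, y)", call. = FALSE)
  x
}

# greedy globally-closest pairing, used only beyond the exact-DP size limit
greedy_matching <- function(dmat, tol) {
  m <- 0L
  repeat {
    if (!length(dmat) || min(dmat) > tol) break
    ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    m <- m + 1L
    dmat <- dmat[-ij[1], -ij[2], drop = FALSE]
  }
  m
}

#' Full clinical assessment of one mask
#'
#' Bundles the per-frame clinically interpreted quantities: lumen area and
#' the narrowed flag, calcification arc / quadrant count / severity, and
#' stent-strut centroids.
#'
#' @param mask An `ivus_mask`.
#' @param narrowed_mm2 Narrowed-lumen threshold, mm^2.
#' @param rule Calcification severity rule, see [calcification_arc()].
#' @param min_strut_pixels Minimum strut component size.
#' @param center_fallback Passed to [calcification_arc()].
#' @return A `clinical_assessment` list.
#' @export
assess_frame <- function(mask, narrowed_mm2 = 4.0, rule = "quadrants",
                         min_strut_pixels = 3L, center_fallback = FALSE) {
  area <- lumen_area(mask)
  calc <- calcification_arc(mask, rule = rule, center_fallback = center_fallback)
  struts <- extract_struts(mask, min_pixels = min_strut_pixels)
  structure(list(lumen_area = area,
                 narrowed = classify_narrowed(area, narrowed_mm2),
                 calc_arc_deg = calc$calc_arc_deg,
                 quadrant_count = calc$quadrant_count,
                 severe_calc = calc$severe_calc,
                 strut_centroids = struts),
            class = "clinical_assessment")
}

#' Per-frame clinical report table
#'
#' One row per frame: lumen area and narrowed flag, calcification arc and
#' severity, true/predicted strut counts and the strut recall of the
#' prediction against the truth.
#'
#' @param truth_masks,pred_masks Lists of `ivus_mask` (same length).
#' @param frame_ids Optional identifiers (default sequential).
#' @param tol_px Strut matching tolerance, px.
#' @param ... Passed to [assess_frame()].
#' @return Data frame with columns frame_id, lumen_area_mm2, narrowed,
#'   calc_arc_deg, quadrant_count, severe_calc, n_struts_true,
#'   n_struts_pred, strut_recall.
#' @export
clinical_report <- function(truth_masks, pred_masks, frame_ids = NULL,
                            tol_px = 5, ...) {
  n <- length(pred_masks)
  if (length(truth_masks) != n)
    stop("argument error: mask lists differ in length", call. = FALSE)
  if (is.null(frame_ids)) frame_ids <- seq_len(n)
  rows <- lapply(seq_len(n), function(i) {
    ap <- assess_frame(pred_masks[[i]], ...)
    at <- assess_frame(truth_masks[[i]], ...)
    data.frame(frame_id = frame_ids[i],
               lumen_area_mm2 = ap$lumen_area,
               narrowed = ap$narrowed,
               calc_arc_deg = ap$calc_arc_deg,
               quadrant_count = ap$quadrant_count,
               severe_calc = ap$severe_calc,
               n_struts_true = nrow(at$strut_centroids),
               n_struts_pred = nrow(ap$strut_centroids),
               strut_recall = strut_recall(ap$strut_centroids,
                                           at$strut_centroids, tol_px))
  })
  do.call(rbind, rows)
}
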