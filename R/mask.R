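#' Construct a label mask
#'
#' A label mask is the ground-truth and prediction currency of the pipeline:
#' a square integer grid in which every pixel carries one of five class codes
#' (0 background, 1 lumen, 2 media+plaque, 3 calcification, 4 stent),
#' together with the physical pixel spacing in mm/px that converts pixel
#' counts to areas.
#'
#' @param labels Integer matrix (H x W, H = W) with values in 0..4.
#' @param pixel_spacing Pixel edge length in mm/px (> 0).
#' @return An object of class `ivus_mask`.
#' @export
label_mask <- function(labels, pixel_spacing) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  m <- structure(list(labels = labels, pixel_spacing = as.numeric(pixel_spacing)),
                 class = "ivus_mask")
  validate_mask(m)
  m
}

#' Validate a label mask
#'
#' Checks the mask invariants: square grid, class codes restricted to 0..4,
#' strictly positive pixel spacing.
#'
#' @param mask An `ivus_mask`.
#' @return The mask, invisibly; errors on violation.
#' @export
validate_mask <- function(mask) {
  if (!inherits(mask, "ivus_mask")) stop("not an `ivus_mask`", call. = FALSE)
  lab <- mask$labels
  if (nrow(lab) != ncol(lab)) stop("label grid must be square", call. = FALSE)
  if (anyNA(lab) || any(lab < 0L) || any(lab > 4L))
    stop("label values must lie in 0..4", call. = FALSE)
  if (!is.finite(mask$pixel_spacing) || mask$pixel_spacing <= 0)
    stop("pixel_spacing must be > 0", call. = FALSE)
  invisible(mask)
}

#' @export
print.ivus_mask <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("<ivus_mask> %dx%d px, %.4g mm/px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_spacing))
  cat(sprintf("  %s: %d px\n", names(IVUS_CLASSES), tab), sep = "")
  invisible(x)
}

#' Collapse a mask to a one-vs-rest binary mask
#'
#' Used when grouping the five classes into "target class vs others" (for
#' instance lumen vs all other classes) before binary overlap metrics.
#'
#' @param mask An `ivus_mask`.
#' @param target_class Class name (`"lumen"`, ...) or integer code 0..4.
#' @return Integer 0/1 matrix of the same size.
#' @export
collapse_to_binary <- function(mask, target_class) {
  validate_mask(mask)
  code <- resolve_class(target_class)
  out <- (mask$labels == code) + 0L
  dim(out) <- dim(mask$labels)
  out
}

resolve_class <- function(target_class) {
  if (is.character(target_class)) {
    if (!target_class %in% names(IVUS_CLASSES))
      stop("unknown class name: ", target_class, call. = FALSE)
    return(unname(IVUS_CLASSES[target_class]))
  }
  code <- as.integer(target_class)
  if (is.na(code) || code < 0L || code > 4L)
    stop("unknown class code: ", target_class, call. = FALSE)
  code
}
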