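#' Color palette of the mask PNG convention
#'
#' Masks are stored as 8-bit RGB PNGs with one flat color per class:
#' black background, green lumen, red media+plaque, orange calcification,
#' blue stent. The exact RGB values (pure primaries plus web-orange) are
#' chosen so nearest-color decoding is unambiguous.
#'
#' @return 5 x 3 integer matrix of RGB values in 0..255, rows named by class.
#' @export
ivus_palette <- function() {
  pal <- rbind(
    background    = c(0L,   0L,   0L),
    lumen         = c(0L,   255L, 0L),
    media_plaque  = c(255L, 0L,   0L),
    calcification = c(255L, 165L, 0L),
    stent         = c(0L,   0L,   255L)
  )
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Write a label mask as a color-coded RGB PNG
#'
#' @param mask An `ivus_mask`.
#' @param path Output file path.
#' @param palette Class-to-RGB matrix as returned by [ivus_palette()].
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, palette = ivus_palette()) {
  validate_mask(mask)
  lab <- mask$labels
  h <- nrow(lab); w <- ncol(lab)
  arr <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- palette[lab + 1L, ch] / 255
  ok <- tryCatch({ png::writePNG(arr, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write mask PNG to ", path, call. = FALSE)
  invisible(path)
}

#' Read a color-coded mask PNG back into a label mask
#'
#' Each pixel is assigned the palette class whose color is nearest under the
#' max-channel (Chebyshev) distance. Pixels farther than `tolerance` from
#' every palette color are treated as foreign and raise a decode error that
#' lists offending coordinates.
#'
#' @param path PNG file path.
#' @param pixel_spacing Pixel spacing (mm/px) to attach to the mask.
#' @param palette Class-to-RGB matrix.
#' @param tolerance Max-channel distance (0..255) accepted per pixel.
#' @return An `ivus_mask`.
#' @export
read_mask <- function(path, pixel_spacing, palette = ivus_palette(),
                      tolerance = 10) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("cannot read PNG file ", path, ": ", conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 2L)          # grayscale: replicate channels
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- round(img * 255)
  n <- h * w
  dists <- matrix(0, n, nrow(palette))
  for (k in seq_len(nrow(palette))) {
    d <- abs(rgb[, , 1] - palette[k, 1])
    d <- pmax(d, abs(rgb[, , 2] - palette[k, 2]))
    d <- pmax(d, abs(rgb[, , 3] - palette[k, 3]))
    dists[, k] <- d
  }
  nearest <- max.col(-dists, ties.method = "first")
  mind <- dists[cbind(seq_len(n), nearest)]
  bad <- which(mind > tolerance)
  if (length(bad)) {
    coords <- sprintf("(%d,%d)", ((bad - 1L) %% h) + 1L, ((bad - 1L) %/% h) + 1L)
    shown <- paste(utils::head(coords, 20L), collapse = " ")
    stop(sprintf(
      "decode error: %d pixel(s) beyond color tolerance %g; first at %s",
      length(bad), tolerance, shown), call. = FALSE)
  }
  lab <- matrix(as.integer(nearest - 1L), h, w)
  label_mask(lab, pixel_spacing)
}

#' Write the palette as a machine-readable JSON sidecar
#'
#' @param path Output JSON path.
#' @param palette Class-to-RGB matrix.
#' @return `path`, invisibly.
#' @export
write_palette_json <- function(path, palette = ivus_palette()) {
  obj <- lapply(rownames(palette), function(cl) {
    list(class = cl, code = unname(IVUS_CLASSES[cl]),
         rgb = as.integer(palette[cl, ]))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a B-mode frame as an 8-bit grayscale PNG
#'
#' @param frame Numeric matrix with intensities in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  if (!is.matrix(frame) || anyNA(frame) || min(frame) < 0 || max(frame) > 1)
    stop("frame must be a numeric matrix with values in [0, 1]", call. = FALSE)
  png::writePNG(frame, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG frame
#'
#' @param path PNG file path.
#' @return Numeric matrix with intensities in \[0, 1\].
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
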