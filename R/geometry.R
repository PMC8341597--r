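#' Construct a vessel cross-section geometry
#'
#' Parametric description of one IVUS cross-section: an elliptical lumen
#' inside an elliptical outer vessel border (leading edge of the adventitia),
#' optional calcification arcs carved into the media+plaque annulus, optional
#' stent struts on a ring hugging the lumen border, and an optional bright
#' wire-artifact ray. All radii are physical (mm); positions are in pixels.
#'
#' @param lumen_center Length-2 numeric, (x, y) center in px (0-based).
#' @param lumen_radii Length-2 numeric, lumen semi-axes (a, b) in mm.
#' @param lumen_rotation Rotation of the ellipse axes, degrees.
#' @param media_outer_radii Length-2 numeric, outer vessel border semi-axes
#'   in mm; must exceed `lumen_radii` componentwise.
#' @param calc_arcs Data frame with columns `start_deg`, `extent_deg`,
#'   `radial_offset_mm`, `thickness_mm` (zero rows for none).
#' @param struts_deg Numeric vector of strut angular positions, degrees.
#' @param strut_ring_offset_mm Radial offset of the strut ring outward of the
#'   lumen border (>= 0 so the ring radius is at least the lumen radius).
#' @param strut_radius_mm Radius of one rendered strut blob, mm.
#' @param wire_artifact_angle Angle (degrees) of a bright wire artifact ray,
#'   or `NA` for none.
#' @param pixel_spacing Pixel edge length, mm/px.
#' @param image_size Image side length, px.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(lumen_center, lumen_radii, lumen_rotation = 0,
                            media_outer_radii,
                            calc_arcs = empty_calc_arcs(),
                            struts_deg = numeric(0),
                            strut_ring_offset_mm = 0.05,
                            strut_radius_mm = 0.09,
                            wire_artifact_angle = NA_real_,
                            pixel_spacing = 0.02, image_size = 256L) {
  g <- structure(list(
    lumen_center = as.numeric(lumen_center),
    lumen_radii = as.numeric(lumen_radii),
    lumen_rotation = as.numeric(lumen_rotation),
    media_outer_radii = as.numeric(media_outer_radii),
    calc_arcs = as.data.frame(calc_arcs),
    struts_deg = as.numeric(struts_deg),
    strut_ring_offset_mm = as.numeric(strut_ring_offset_mm),
    strut_radius_mm = as.numeric(strut_radius_mm),
    wire_artifact_angle = as.numeric(wire_artifact_angle),
    pixel_spacing = as.numeric(pixel_spacing),
    image_size = as.integer(image_size)
  ), class = "vessel_geometry")
  validate_geometry(g)
  g
}

#' Empty calcification-arc table
#'
#' @return Zero-row data frame with the `calc_arcs` columns of
#'   [vessel_geometry()].
#' @export
empty_calc_arcs <- function() {
  data.frame(start_deg = numeric(0), extent_deg = numeric(0),
             radial_offset_mm = numeric(0), thickness_mm = numeric(0))
}

#' Validate a vessel geometry
#'
#' Enforces the geometry invariants: outer border strictly larger than the
#' lumen on both axes, arc extents in (0, 360], non-negative strut ring
#' offset (so the ring radius is at least the lumen radius), positive
#' spacing and size.
#'
#' @param geom A `vessel_geometry`.
#' @return The geometry, invisibly; errors on violation.
#' @export
validate_geometry <- function(geom) {
  if (!inherits(geom, "vessel_geometry")) stop("not a `vessel_geometry`", call. = FALSE)
  if (length(geom$lumen_radii) != 2L || any(geom$lumen_radii <= 0))
    stop("lumen_radii must be two positive semi-axes", call. = FALSE)
  if (length(geom$media_outer_radii) != 2L ||
      any(geom$media_outer_radii <= geom$lumen_radii))
    stop("media_outer_radii must exceed lumen_radii componentwise", call. = FALSE)
  ca <- geom$calc_arcs
  need <- c("start_deg", "extent_deg", "radial_offset_mm", "thickness_mm")
  if (!all(need %in% names(ca)))
    stop("calc_arcs must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(ca) && (any(ca$extent_deg <= 0) || any(ca$extent_deg > 360)))
    stop("calc arc extents must lie in (0, 360]", call. = FALSE)
  if (nrow(ca) && (any(ca$radial_offset_mm < 0) || any(ca$thickness_mm <= 0)))
    stop("calc arcs need radial_offset_mm >= 0 and thickness_mm > 0", call. = FALSE)
  if (geom$strut_ring_offset_mm < 0)
    stop("strut_ring_offset_mm must be >= 0", call. = FALSE)
  if (geom$pixel_spacing <= 0 || geom$image_size < 8L)
    stop("pixel_spacing must be > 0 and image_size >= 8", call. = FALSE)
  invisible(geom)
}

# radius of a rotated ellipse (semi-axes a, b, axis rotation rot_deg) along
# polar angle ang_deg, measured from its center
ellipse_radius <- function(a, b, rot_deg, ang_deg) {
  d <- (ang_deg - rot_deg) * pi / 180
  a * b / sqrt((b * cos(d))^2 + (a * sin(d))^2)
}

# is angle `ang` inside the arc [start, start + extent) (degrees, mod 360)?
in_arc <- function(ang, start, extent) ((ang - start) %% 360) < extent

# pixel-center coordinate grids relative to a center, in mm
pixel_grid <- function(image_size, pixel_spacing, cx, cy) {
  n <- image_size
  xg <- matrix(rep(0:(n - 1L), each = n), n, n)
  yg <- matrix(rep(0:(n - 1L), times = n), n, n)
  dx <- (xg - cx) * pixel_spacing
  dy <- (yg - cy) * pixel_spacing
  list(xg = xg, yg = yg, dx = dx, dy = dy,
       r = sqrt(dx^2 + dy^2),
       ang = (atan2(dy, dx) * 180 / pi) %% 360)
}

#' Analytic ground truth of a vessel geometry
#'
#' Computes the quantities the phantom knows exactly: lumen area (pi a b),
#' the occupied calcification angle in whole degrees, quadrant occupancy of
#' the four fixed 90-degree sectors, strut centroid positions in pixels, and
#' the presence flags.
#'
#' @param geom A `vessel_geometry`.
#' @return A list with fields `true_lumen_area`, `true_calc_arc`,
#'   `true_quadrant_count`, `true_strut_positions` (n x 2 matrix, columns x
#'   and y in px), `has_calcification`, `has_stent`.
#' @export
ground_truth <- function(geom) {
  validate_geometry(geom)
  area <- pi * geom$lumen_radii[1] * geom$lumen_radii[2]
  ca <- geom$calc_arcs
  if (nrow(ca)) {
    bins <- unlist(lapply(seq_len(nrow(ca)), function(i) {
      s <- ca$start_deg[i]; e <- ca$extent_deg[i]
      unique(floor((s + seq(0.05, e - 0.05, by = 0.1)) %% 360))
    }))
    bins <- unique(bins)
    arc <- length(bins)
    quad <- length(unique(bins %/% 90L))
  } else {
    arc <- 0L; quad <- 0L
  }
  if (length(geom$struts_deg)) {
    phi <- geom$struts_deg
    rr <- ellipse_radius(geom$lumen_radii[1], geom$lumen_radii[2],
                         geom$lumen_rotation, phi) + geom$strut_ring_offset_mm
    pos <- cbind(x = geom$lumen_center[1] + rr * cos(phi * pi / 180) / geom$pixel_spacing,
                 y = geom$lumen_center[2] + rr * sin(phi * pi / 180) / geom$pixel_spacing)
  } else {
    pos <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  }
  list(true_lumen_area = area,
       true_calc_arc = arc,
       true_quadrant_count = quad,
       true_strut_positions = pos,
       has_calcification = nrow(ca) > 0L,
       has_stent = length(geom$struts_deg) > 0L)
}

#' Rasterize a vessel geometry into a label mask
#'
#' Every pixel receives exactly one of the five classes. Priority where
#' regions overlap: stent struts override everything local to them (they sit
#' on the lumen border, as in their clinical appearance), calcification is
#' carved out of the media+plaque annulus, lumen overrides media.
#'
#' @param geom A `vessel_geometry`.
#' @return An `ivus_mask`.
#' @export
rasterize_mask <- function(geom) {
  validate_geometry(geom)
  n <- geom$image_size; sp <- geom$pixel_spacing
  cx <- geom$lumen_center[1]; cy <- geom$lumen_center[2]
  gp <- pixel_grid(n, sp, cx, cy)
  th <- geom$lumen_rotation * pi / 180
  u <- gp$dx * cos(th) + gp$dy * sin(th)
  v <- -gp$dx * sin(th) + gp$dy * cos(th)
  a <- geom$lumen_radii[1]; b <- geom$lumen_radii[2]
  A <- geom$media_outer_radii[1]; B <- geom$media_outer_radii[2]
  lum <- (u / a)^2 + (v / b)^2 <= 1
  med <- (u / A)^2 + (v / B)^2 <= 1
  lab <- matrix(0L, n, n)
  lab[med] <- IVUS_CLASSES[["media_plaque"]]
  lab[lum] <- IVUS_CLASSES[["lumen"]]
  ca <- geom$calc_arcs
  if (nrow(ca)) {
    rl <- ellipse_radius(a, b, geom$lumen_rotation, gp$ang)
    for (i in seq_len(nrow(ca))) {
      sel <- in_arc(gp$ang, ca$start_deg[i], ca$extent_deg[i]) &
        gp$r >= rl + ca$radial_offset_mm[i] &
        gp$r <= rl + ca$radial_offset_mm[i] + ca$thickness_mm[i] &
        med & !lum
      lab[sel] <- IVUS_CLASSES[["calcification"]]
    }
  }
  if (length(geom$struts_deg)) {
    rad_px <- geom$strut_radius_mm / sp
    for (phi in geom$struts_deg) {
      rr <- ellipse_radius(a, b, geom$lumen_rotation, phi) + geom$strut_ring_offset_mm
      sx <- cx + rr * cos(phi * pi / 180) / sp
      sy <- cy + rr * sin(phi * pi / 180) / sp
      sel <- (gp$xg - sx)^2 + (gp$yg - sy)^2 <= rad_px^2
      lab[sel] <- IVUS_CLASSES[["stent"]]
    }
  }
  label_mask(lab, sp)
}
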