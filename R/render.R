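# Echogenicity levels of the deterministic B-mode map. These are display
# conventions, not physical quantities; the constraints that matter are
# lumen < media+plaque and calcification/struts near saturation.
ECHO_LEVELS <- c(background = 0.18, lumen = 0.06, media_plaque = 0.45,
                 calcification = 0.95, stent = 1.00,
                 adventitia_rim = 0.55, catheter_ring = 0.85,
                 catheter_core = 0.10, wire = 0.85)

CATHETER_CORE_MM <- 0.22   # catheter interior radius (always at image center)
CATHETER_RING_MM <- 0.32   # outer radius of the bright ringdown ring

# separable 3x3 binomial (Gaussian-like) smoothing with replicated edges
smooth3 <- function(m) {
  n <- nrow(m)
  up <- rbind(m[1, ], m[-n, ]); dn <- rbind(m[-1, ], m[n, ])
  v <- (up + 2 * m + dn) / 4
  lf <- cbind(v[, 1], v[, -n]); rt <- cbind(v[, -1], v[, n])
  (lf + 2 * v + rt) / 4
}

#' Render a B-mode frame from a vessel geometry
#'
#' Builds the deterministic echogenicity map (dark lumen, mid-gray
#' media+plaque, bright adventitia rim, saturated calcification and struts
#' with radially-outward acoustic shadows, central catheter ring, optional
#' bright wire-artifact ray) and multiplies in smoothed Rayleigh speckle.
#' With `speckle_scale = 0` the returned frame equals the deterministic map
#' exactly.
#'
#' Speckle uses R's random number stream, so rendering is reproducible under
#' `set.seed()`.
#'
#' @param geom A `vessel_geometry`.
#' @param speckle_scale Dimensionless speckle contrast in \[0, 1\];
#'   0 disables noise.
#' @param shadow_attenuation Residual intensity fraction in \[0, 1\] kept
#'   behind calcification and struts (0.15 keeps 15 percent).
#' @return Numeric matrix (image_size x image_size) of intensities in \[0, 1\].
#' @export
render_bmode <- function(geom, speckle_scale = 0.6, shadow_attenuation = 0.15) {
  validate_geometry(geom)
  if (shadow_attenuation < 0 || shadow_attenuation > 1)
    stop("shadow_attenuation must lie in [0, 1]", call. = FALSE)
  if (speckle_scale < 0 || speckle_scale > 1)
    stop("speckle_scale must lie in [0, 1]", call. = FALSE)
  n <- geom$image_size; sp <- geom$pixel_spacing
  mask <- rasterize_mask(geom)
  lab <- mask$labels
  lev <- ECHO_LEVELS
  e <- matrix(lev[["background"]], n, n)
  e[lab == 1L] <- lev[["lumen"]]
  e[lab == 2L] <- lev[["media_plaque"]]
  e[lab == 3L] <- lev[["calcification"]]
  e[lab == 4L] <- lev[["stent"]]

  cx <- geom$lumen_center[1]; cy <- geom$lumen_center[2]
  gp <- pixel_grid(n, sp, cx, cy)
  rmed <- ellipse_radius(geom$media_outer_radii[1], geom$media_outer_radii[2],
                         geom$lumen_rotation, gp$ang)
  rim <- lab == 0L & gp$r > rmed & gp$r <= rmed + 0.30
  e[rim] <- lev[["adventitia_rim"]]

  # acoustic shadows: everything radially outward of a strong reflector,
  # within its angular sector, is attenuated to the residual fraction
  rl <- ellipse_radius(geom$lumen_radii[1], geom$lumen_radii[2],
                       geom$lumen_rotation, gp$ang)
  ca <- geom$calc_arcs
  if (nrow(ca)) {
    for (i in seq_len(nrow(ca))) {
      sel <- in_arc(gp$ang, ca$start_deg[i], ca$extent_deg[i]) &
        gp$r > rl + ca$radial_offset_mm[i] + ca$thickness_mm[i]
      e[sel] <- e[sel] * shadow_attenuation
    }
  }
  if (length(geom$struts_deg)) {
    for (phi in geom$struts_deg) {
      rs <- ellipse_radius(geom$lumen_radii[1], geom$lumen_radii[2],
                           geom$lumen_rotation, phi) + geom$strut_ring_offset_mm
      dphi <- abs(((gp$ang - phi + 180) %% 360) - 180)
      sel <- dphi <= 2.5 & gp$r > rs + geom$strut_radius_mm
      e[sel] <- e[sel] * shadow_attenuation
    }
  }

  # catheter ringdown at the image center (always present, not a class)
  c0 <- (n - 1) / 2
  gpc <- pixel_grid(n, sp, c0, c0)
  e[gpc$r <= CATHETER_RING_MM] <- lev[["catheter_ring"]]
  e[gpc$r <= CATHETER_CORE_MM] <- lev[["catheter_core"]]

  if (is.finite(geom$wire_artifact_angle)) {
    dphi <- abs(((gpc$ang - geom$wire_artifact_angle + 180) %% 360) - 180)
    sel <- dphi <= 1.2 & gpc$r > CATHETER_RING_MM
    e[sel] <- pmax(e[sel], lev[["wire"]])
  }

  if (speckle_scale > 0) {
    ray <- sqrt(-2 * log(runif(n * n)))       # Rayleigh(1) draws
    rn <- matrix(ray / sqrt(pi / 2), n, n)    # normalized to unit mean
    e <- e * (1 - speckle_scale + speckle_scale * smooth3(rn))
  }
  pmin(pmax(e, 0), 1)
}
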