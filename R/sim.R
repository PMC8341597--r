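#' Simulator configuration
#'
#' Study-level knobs of the phantom generator. The default lesion
#' composition mirrors a single-center complex-lesion cohort: 59.1 percent
#' of frames showing calcification, 12.3 percent showing a stent, with
#' severe (more than two quadrant) calcification in 28.7 percent of
#' calcified frames. Defaults of 24 patients and 156 frames per patient at
#' 0.5-mm pullback spacing give a dataset of about 3700 frames.
#'
#' @param n_patients Number of synthetic patients.
#' @param frames_per_patient Frames per pullback.
#' @param image_size Frame side length, px.
#' @param pixel_spacing Pixel edge, mm/px (0.02 on 256 px gives a ~5 mm
#'   field of view, plausible for a 60-MHz catheter).
#' @param calc_frame_fraction Probability a frame shows calcification.
#' @param stent_frame_fraction Probability a frame shows a stent.
#' @param narrowed_fraction Probability a frame has lumen area < 4 mm^2.
#' @param severe_calc_fraction Probability a calcified run is severe
#'   (arc in more than two quadrants).
#' @param speckle_scale Speckle contrast in \[0, 1\].
#' @param shadow_attenuation Residual intensity behind strong reflectors.
#' @param frame_interval Pullback spacing between frames, mm.
#' @param rng_seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 24L, frames_per_patient = 156L,
                       image_size = 256L, pixel_spacing = 0.02,
                       calc_frame_fraction = 0.591,
                       stent_frame_fraction = 0.123,
                       narrowed_fraction = 0.35,
                       severe_calc_fraction = 0.287,
                       speckle_scale = 0.6, shadow_attenuation = 0.15,
                       frame_interval = 0.5, rng_seed = NULL) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    frames_per_patient = as.integer(frames_per_patient),
    image_size = as.integer(image_size),
    pixel_spacing = as.numeric(pixel_spacing),
    calc_frame_fraction = as.numeric(calc_frame_fraction),
    stent_frame_fraction = as.numeric(stent_frame_fraction),
    narrowed_fraction = as.numeric(narrowed_fraction),
    severe_calc_fraction = as.numeric(severe_calc_fraction),
    speckle_scale = as.numeric(speckle_scale),
    shadow_attenuation = as.numeric(shadow_attenuation),
    frame_interval = as.numeric(frame_interval),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("not a `sim_config`", call. = FALSE)
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L)
    stop("configuration error: n_patients must be a positive integer", call. = FALSE)
  if (is.na(cfg$frames_per_patient) || cfg$frames_per_patient < 1L)
    stop("configuration error: frames_per_patient must be a positive integer",
         call. = FALSE)
  probs <- c(cfg$calc_frame_fraction, cfg$stent_frame_fraction,
             cfg$narrowed_fraction, cfg$severe_calc_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("configuration error: all fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$speckle_scale < 0 || cfg$speckle_scale > 1 ||
      cfg$shadow_attenuation < 0 || cfg$shadow_attenuation > 1)
    stop("configuration error: speckle_scale and shadow_attenuation must lie in [0, 1]",
         call. = FALSE)
  if (cfg$pixel_spacing <= 0 || cfg$image_size < 16L)
    stop("configuration error: need pixel_spacing > 0 and image_size >= 16",
         call. = FALSE)
  invisible(cfg)
}

# maximum per-frame change of a lumen semi-axis the trajectory construction
# guarantees (mm); see sample_patient
SMOOTHNESS_BOUND_MM <- 0.25

# bounded random walk with clipped steps
walk_clip <- function(n, x0, step, lo, hi) {
  x <- numeric(n); x[1] <- min(hi, max(lo, x0))
  if (n > 1) for (i in 2:n) x[i] <- min(hi, max(lo, x[i - 1] + runif(1, -step, step)))
  x
}

# contiguous run of length k placed inside n frames, kept `margin` frames
# away from the sequence edges when possible
place_run <- function(n, k, margin = 0L) {
  out <- rep(FALSE, n)
  if (k <= 0L) return(out)
  if (k >= n) return(rep(TRUE, n))
  lo <- min(margin + 1L, n - k + 1L); hi <- max(lo, n - k + 1L - margin)
  start <- if (hi > lo) sample(lo:hi, 1L) else lo
  out[start:(start + k - 1L)] <- TRUE
  out
}

# shift an arc start so both endpoints stay >= 4 degrees away from the fixed
# quadrant boundaries (multiples of 90), keeping ground-truth quadrant labels
# unambiguous under rasterization
snap_arc <- function(start, extent, margin = 4) {
  ok <- function(s) {
    r1 <- s %% 90; r2 <- (s + extent) %% 90
    r1 >= margin && r1 <= 90 - margin && r2 >= margin && r2 <= 90 - margin
  }
  for (d in seq(0, 45, by = 0.5)) {
    if (ok(start + d)) return((start + d) %% 360)
    if (ok(start - d)) return((start - d) %% 360)
  }
  start %% 360  # unreachable for extents clear of multiples of 90
}

#' Sample one patient's geometry trajectory
#'
#' Draws a smooth per-frame sequence of vessel geometries for one pullback.
#' Lesion attributes (stenosis, calcification, stent segment) occupy
#' contiguous frame runs, as in a real pullback; frame-to-frame geometry
#' evolves by bounded random walks, so consecutive frames are strongly
#' correlated. Per-frame lumen semi-axis changes are bounded by
#' `SMOOTHNESS_BOUND_MM` (0.25 mm) by construction.
#'
#' Per-patient lesion frame counts are drawn as Binomial(frames, fraction),
#' so dataset-level lesion fractions follow the configured probabilities
#' with binomial sampling error despite within-patient correlation.
#'
#' Uses R's RNG stream; call under `set.seed()` for reproducibility.
#'
#' @param config A `sim_config`.
#' @param patient_id Identifier stored with the trajectory.
#' @return List with `patient_id`, `geoms` (list of `vessel_geometry`), and
#'   the logical run vectors `narrowed_run`, `calc_run`, `stent_run`;
#'   attribute `smoothness_bound_mm` states the guaranteed bound.
#' @export
sample_patient <- function(config, patient_id = "P01") {
  validate_sim_config(config)
  nf <- config$frames_per_patient
  sp <- config$pixel_spacing
  n <- config$image_size
  c0 <- (n - 1) / 2

  # geometry walks (areas in mm^2, lengths in mm)
  aspect <- walk_clip(nf, runif(1, 1.0, 1.15), 0.01, 1.0, 1.15)
  rot <- cumsum(c(runif(1, 0, 180), runif(max(nf - 1, 0), -3, 3)))
  offx <- walk_clip(nf, runif(1, -0.05, 0.05), 0.02, -0.1, 0.1)
  offy <- walk_clip(nf, runif(1, -0.05, 0.05), 0.02, -0.1, 0.1)
  wall <- walk_clip(nf, runif(1, 0.7, 1.2), 0.03, 0.6, 1.3)
  area <- walk_clip(nf, runif(1, 5, 7), 0.2, 4.4, 7.0)

  # narrowed segment: lumen area dips below 4 mm^2 on a contiguous run, with
  # entry/exit ramps outside the run keeping semi-axis steps within bound
  kn <- rbinom(1, nf, config$narrowed_fraction)
  if (kn > 0L) kn <- if (nf < kn + 8L) nf else max(6L, kn)
  narrowed_run <- place_run(nf, kn, margin = 4L)
  if (kn > 0L && kn < nf) {
    idx <- which(narrowed_run)
    amin <- runif(1, 1.8, 3.0)
    j <- seq_along(idx)
    area[idx] <- 3.8 - (3.8 - amin) * sin(pi * (j - 0.5) / kn)^2
    for (side in c(-1L, 1L)) {             # 4-frame cosine ramps to 4.4
      edge <- if (side < 0) idx[1] else idx[length(idx)]
      ramp <- edge + side * (1:4)
      ramp <- ramp[ramp >= 1L & ramp <= nf & !narrowed_run[pmin(pmax(ramp, 1L), nf)]]
      if (length(ramp)) {
        # ramp is ordered adjacent-to-run first; area climbs from 4.4 at the
        # run edge toward the baseline farther out
        far <- ramp[length(ramp)]
        w <- seq_len(length(ramp)) / (length(ramp) + 1)
        area[ramp] <- 4.4 + (area[far] - 4.4) * w
      }
    }
  } else if (kn == nf) {
    amin <- runif(1, 1.8, 3.0)
    area <- walk_clip(nf, runif(1, amin, 3.6), 0.15, amin, 3.8)
  }

  # calcification run: one solid arc; severe runs span > 180 degrees (always
  # more than two quadrants), non-severe stay <= 88 (never more than two)
  kc <- rbinom(1, nf, config$calc_frame_fraction)
  calc_run <- place_run(nf, kc)
  calc_pars <- NULL
  if (kc > 0L) {
    severe <- runif(1) < config$severe_calc_fraction
    ext0 <- if (severe) runif(1, 185, 300) else runif(1, 15, 88)
    elo <- if (severe) 185 else 15; ehi <- if (severe) 300 else 88
    ext <- walk_clip(kc, ext0, 1, elo, ehi)
    st <- cumsum(c(runif(1, 0, 360), runif(max(kc - 1, 0), -1.5, 1.5)))
    calc_pars <- list(start = st, extent = ext,
                      offset = runif(1, 0.03, 0.10),
                      thick = runif(1, 0.25, 0.40))
  }

  # stent run: ring of struts with per-strut jitter and slow drift
  ks <- rbinom(1, nf, config$stent_frame_fraction)
  stent_run <- place_run(nf, ks)
  stent_pars <- NULL
  if (ks > 0L) {
    nstr <- sample(7:10, 1)
    base <- seq(0, 360, length.out = nstr + 1)[-(nstr + 1)] +
      runif(1, 0, 360) + runif(nstr, -8, 8)
    drift <- cumsum(c(0, runif(max(ks - 1, 0), -1, 1)))
    stent_pars <- list(angles = base, drift = drift)
  }

  wire <- if (runif(1) < 0.3)
    cumsum(c(runif(1, 0, 360), runif(max(nf - 1, 0), -2, 2))) else rep(NA_real_, nf)

  geoms <- vector("list", nf)
  ci <- 0L; si <- 0L
  for (i in seq_len(nf)) {
    r0 <- sqrt(area[i] / pi)
    a <- r0 * aspect[i]; b <- r0 / aspect[i]
    arcs <- empty_calc_arcs()
    if (calc_run[i]) {
      ci <- ci + 1L
      th <- min(calc_pars$thick, wall[i] - calc_pars$offset - 0.05)
      s <- snap_arc(calc_pars$start[ci] %% 360, calc_pars$extent[ci])
      arcs <- data.frame(start_deg = s, extent_deg = calc_pars$extent[ci],
                         radial_offset_mm = calc_pars$offset, thickness_mm = th)
    }
    struts <- numeric(0)
    if (stent_run[i]) {
      si <- si + 1L
      struts <- (stent_pars$angles + stent_pars$drift[si]) %% 360
    }
    geoms[[i]] <- vessel_geometry(
      lumen_center = c(c0 + offx[i] / sp, c0 + offy[i] / sp),
      lumen_radii = c(a, b), lumen_rotation = rot[i] %% 360,
      media_outer_radii = c(a + wall[i], b + wall[i]),
      calc_arcs = arcs, struts_deg = struts,
      wire_artifact_angle = wire[i],
      pixel_spacing = sp, image_size = n)
  }
  structure(list(patient_id = patient_id, geoms = geoms,
                 narrowed_run = narrowed_run, calc_run = calc_run,
                 stent_run = stent_run),
            smoothness_bound_mm = SMOOTHNESS_BOUND_MM)
}

#' Simulate pullback sequences in memory
#'
#' Generates `n_patients` pullbacks, each a list of frames pairing a rendered
#' B-mode image with its rasterized label mask and analytic ground truth.
#'
#' @param config A `sim_config`. When `config$rng_seed` is set, the RNG is
#'   seeded so the dataset is fully reproducible.
#' @return List of pullback sequences; each has `patient_id`,
#'   `frame_interval`, and `frames`, a list of `list(bmode, mask, truth)`.
#' @export
simulate_pullbacks <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  lapply(seq_len(config$n_patients), function(p) {
    pid <- sprintf("P%02d", p)
    traj <- sample_patient(config, pid)
    frames <- lapply(traj$geoms, function(g) {
      list(bmode = render_bmode(g, config$speckle_scale, config$shadow_attenuation),
           mask = rasterize_mask(g),
           truth = ground_truth(g))
    })
    list(patient_id = pid, frame_interval = config$frame_interval,
         frames = frames)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes grayscale frame PNGs, color-coded mask PNGs, a palette JSON
#' sidecar, and a manifest CSV mapping every frame to its patient together
#' with the analytic ground-truth columns. The manifest's patient ids
#' partition the frames (no frame belongs to two patients), which is what
#' patient-level splitting relies on.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `sequences`, the `manifest` data frame
#'   and the manifest file `path`.
#' @export
generate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L)
    stop("I/O error: cannot write to output path ", out_dir, call. = FALSE)
  fdir <- file.path(out_dir, "frames"); mdir <- file.path(out_dir, "masks")
  dir.create(fdir, showWarnings = FALSE); dir.create(mdir, showWarnings = FALSE)
  seqs <- simulate_pullbacks(config)
  rows <- list()
  for (s in seqs) {
    for (i in seq_along(s$frames)) {
      fr <- s$frames[[i]]
      fp <- file.path("frames", sprintf("%s_f%04d.png", s$patient_id, i))
      mp <- file.path("masks", sprintf("%s_f%04d_mask.png", s$patient_id, i))
      write_frame(fr$bmode, file.path(out_dir, fp))
      write_mask(fr$mask, file.path(out_dir, mp))
      tr <- fr$truth
      pos <- tr$true_strut_positions
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = s$patient_id, frame_index = i,
        frame_path = fp, mask_path = mp,
        true_lumen_area = tr$true_lumen_area,
        true_calc_arc = tr$true_calc_arc,
        true_quadrant_count = tr$true_quadrant_count,
        has_calcification = tr$has_calcification,
        has_stent = tr$has_stent,
        true_strut_positions = paste(sprintf("%.2f:%.2f", pos[, 1], pos[, 2]),
                                     collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  write_palette_json(file.path(out_dir, "palette.json"))
  invisible(list(sequences = seqs, manifest = manifest, path = mpath))
}
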