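test_that("lumen area is the pixel count scaled by spacing squared", {
  lab <- matrix(0L, 64, 64)
  lab[sample(64 * 64, 400)] <- 1L
  expect_equal(lumen_area(label_mask(lab, 0.02)), 0.16)
  expect_equal(lumen_area(label_mask(matrix(0L, 8, 8), 0.02)), 0)

  # monotone additivity: adding lumen pixels can only grow the area
  lab2 <- lab; lab2[lab2 == 0L][1:10] <- 1L
  lab2 <- matrix(lab2, 64, 64)
  expect_gt(lumen_area(label_mask(lab2, 0.02)), lumen_area(label_mask(lab, 0.02)))

  # rasterized circle at the 4 mm^2 threshold radius recovers the analytic area
  g <- test_geometry(image_size = 256, pixel_spacing = 0.02,
                     lumen_radii = c(1.128, 1.128), rotation = 0)
  expect_lt(abs(lumen_area(rasterize_mask(g)) - 4.0) / 4.0, 0.02)
})

test_that("narrowed-lumen threshold is strict at 4 mm^2", {
  expect_true(classify_narrowed(3.99))
  expect_false(classify_narrowed(4.00))
  expect_false(classify_narrowed(10.2))
  expect_true(classify_narrowed(0))
  expect_error(classify_narrowed(-0.1), "argument error")
})

test_that("calcification arc, quadrants and severity match the phantom geometry", {
  # no calcification
  g0 <- test_geometry()
  r0 <- calcification_arc(rasterize_mask(g0))
  expect_identical(r0$calc_arc_deg, 0L)
  expect_identical(r0$quadrant_count, 0L)
  expect_false(r0$severe_calc)

  # full ring (at 0.02 mm/px so every 1-degree bin holds many pixels)
  gf <- test_geometry(image_size = 256, pixel_spacing = 0.02,
                      calc_arcs = data.frame(
    start_deg = 0, extent_deg = 360, radial_offset_mm = 0.05, thickness_mm = 0.3))
  rf <- calcification_arc(rasterize_mask(gf))
  expect_identical(rf$calc_arc_deg, 360L)
  expect_identical(rf$quadrant_count, 4L)
  expect_true(rf$severe_calc)

  # single solid arc 10..200 degrees: arc ~190, 3 quadrants, severe
  ga <- test_geometry(image_size = 256, pixel_spacing = 0.02, rotation = 0,
                      calc_arcs = data.frame(
    start_deg = 10, extent_deg = 190, radial_offset_mm = 0.05, thickness_mm = 0.3))
  ra <- calcification_arc(rasterize_mask(ga))
  expect_lt(abs(ra$calc_arc_deg - 190), 5)
  expect_identical(ra$quadrant_count, 3L)
  expect_true(ra$severe_calc)
  expect_identical(ground_truth(ga)$true_quadrant_count, 3L)

  # alternative arc > 180 severity rule
  expect_true(calcification_arc(rasterize_mask(ga), rule = "arc180")$severe_calc)

  # calcification with no lumen: reference error, image-center fallback
  lab <- matrix(0L, 64, 64); lab[10, 40:50] <- 3L
  mk <- label_mask(lab, 0.05)
  expect_error(calcification_arc(mk), "reference error")
  expect_silent(calcification_arc(mk, center_fallback = TRUE))
})

test_that("strut extraction uses 8-connected components with a size floor", {
  lab <- matrix(0L, 32, 32)
  expect_identical(nrow(extract_struts(label_mask(lab, 0.1))), 0L)

  # three disjoint blobs
  lab[2:3, 2:3] <- 4L; lab[10:11, 10:11] <- 4L; lab[25:26, 20:21] <- 4L
  st <- extract_struts(label_mask(lab, 0.1), min_pixels = 3)
  expect_identical(nrow(st), 3L)
  expect_true(any(abs(st[, "x"] - 1.5) < 1e-9 & abs(st[, "y"] - 1.5) < 1e-9))

  # two blobs touching only diagonally form one component
  lab2 <- matrix(0L, 16, 16)
  lab2[2:3, 2:3] <- 4L
  lab2[4:5, 4:5] <- 4L
  expect_identical(nrow(extract_struts(label_mask(lab2, 0.1), min_pixels = 3)), 1L)

  # components below the size floor are suppressed
  lab3 <- matrix(0L, 16, 16); lab3[8, 8] <- 4L
  expect_identical(nrow(extract_struts(label_mask(lab3, 0.1), min_pixels = 3)), 0L)
  expect_identical(nrow(extract_struts(label_mask(lab3, 0.1), min_pixels = 1)), 1L)
})

test_that("strut recall follows the exhaustive matching semantics", {
  tr <- cbind(c(0, 10, 20), c(0, 0, 0))
  pr <- cbind(c(0, 10), c(1, 1))
  expect_equal(strut_recall(pr, tr, tol_px = 5), 2 / 3)
  expect_equal(strut_recall(tr, tr, tol_px = 5), 1)
  expect_equal(strut_recall(NULL, tr, tol_px = 5), 0)
  expect_equal(strut_recall(pr, NULL, tol_px = 5), 1)  # documented convention
  expect_error(strut_recall(pr, tr, tol_px = 0), "tol_px")

  # invariance to row order, never exceeds 1, equals the exhaustive oracle
  withr::local_seed(31)
  for (i in 1:40) {
    nt <- sample(0:6, 1); np <- sample(0:6, 1)
    tru <- matrix(runif(2 * nt, 0, 30), ncol = 2)
    prd <- matrix(runif(2 * np, 0, 30), ncol = 2)
    r <- strut_recall(prd, tru, tol_px = 6)
    expect_lte(r, 1)
    if (nt > 0) {
      expect_equal(r, oracle_max_matches(tru, prd, 6) / nt)
      if (nt > 1 && np > 1) {
        perm <- sample(nt); permp <- sample(np)
        expect_equal(strut_recall(prd[permp, , drop = FALSE],
                                  tru[perm, , drop = FALSE], 6), r)
      }
    }
  }
})

test_that("phantom assessments recover the generator's clinical flags", {
  cfg <- sim_config(n_patients = 6, frames_per_patient = 12, image_size = 128,
                    pixel_spacing = 0.04, rng_seed = 55, speckle_scale = 0)
  set.seed(55)
  ok_narrow <- 0L; n_checked <- 0L
  for (p in 1:cfg$n_patients) {
    traj <- sample_patient(cfg, "P")
    for (g in traj$geoms) {
      tr <- ground_truth(g)
      mk <- rasterize_mask(g)
      if (abs(tr$true_lumen_area - 4) > 0.1) {
        n_checked <- n_checked + 1L
        ok_narrow <- ok_narrow +
          (classify_narrowed(lumen_area(mk)) == (tr$true_lumen_area < 4))
      }
    }
  }
  expect_gt(n_checked, 20)
  expect_identical(ok_narrow, n_checked)
})

test_that("clinical report carries per-frame areas, flags and strut recall", {
  g <- test_geometry(struts_deg = c(0, 120, 240),
                     calc_arcs = data.frame(start_deg = 200, extent_deg = 60,
                                            radial_offset_mm = 0.05,
                                            thickness_mm = 0.3))
  mk <- rasterize_mask(g)
  rep <- clinical_report(list(mk), list(mk))
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$strut_recall, 1)
  expect_identical(rep$n_struts_true, rep$n_struts_pred)
  expect_equal(rep$lumen_area_mm2, lumen_area(mk))
  expect_false(rep$severe_calc)
})
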