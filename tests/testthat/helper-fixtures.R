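# Shared fixtures and independent oracles used across the test files.

# brute-force one-vs-rest confusion tally via logical sums (independent of
# the table()-based implementation)
oracle_confusion <- function(p, t) {
  out <- matrix(0L, 5, 4,
                dimnames = list(names(ivus_classes()), c("TP", "FP", "FN", "TN")))
  for (cl in 0:4) {
    out[cl + 1, ] <- c(sum(p == cl & t == cl), sum(p == cl & t != cl),
                       sum(p != cl & t == cl), sum(p != cl & t != cl))
  }
  out
}

# exhaustive maximum matching: every truth point may take any unused
# prediction within tolerance or stay unmatched; returns the max match count
oracle_max_matches <- function(truth, pred, tol) {
  nt <- nrow(truth); np <- nrow(pred)
  if (nt == 0L || np == 0L) return(0L)
  d <- sqrt(outer(truth[, 1], pred[, 1], "-")^2 +
            outer(truth[, 2], pred[, 2], "-")^2)
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)             # leave truth i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && d[i, j] <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, np))
}

random_mask <- function(n = 64, spacing = 0.05) {
  label_mask(matrix(sample(0:4, n * n, replace = TRUE), n, n), spacing)
}

# simple concentric test geometry; arguments override individual fields
test_geometry <- function(image_size = 128, pixel_spacing = 0.04,
                          lumen_radii = c(1.2, 1.0), rotation = 20,
                          wall = 0.8, calc_arcs = empty_calc_arcs(),
                          struts_deg = numeric(0), ...) {
  c0 <- (image_size - 1) / 2
  vessel_geometry(lumen_center = c(c0, c0), lumen_radii = lumen_radii,
                  lumen_rotation = rotation,
                  media_outer_radii = lumen_radii + wall,
                  calc_arcs = calc_arcs, struts_deg = struts_deg,
                  pixel_spacing = pixel_spacing, image_size = image_size, ...)
}

# small in-memory dataset helper: frames/masks lists for given indices of a
# flat (patient, frame) table
seq_pairs <- function(seqs, man, idx) {
  list(frames = lapply(idx, function(i)
         seqs[[man$patient[i]]]$frames[[man$frame_index[i]]]$bmode),
       masks = lapply(idx, function(i)
         seqs[[man$patient[i]]]$frames[[man$frame_index[i]]]$mask),
       truth = lapply(idx, function(i)
         seqs[[man$patient[i]]]$frames[[man$frame_index[i]]]$truth))
}
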