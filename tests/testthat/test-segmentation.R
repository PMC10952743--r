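make_field <- function(G, S, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(G), ncol(G))
  structure(list(G = G, S = S, total_intensity = matrix(1, nrow(G), ncol(G)),
                 valid_mask = valid, harmonic = 1L, intensity_threshold = 0),
            class = "phasor_field")
}

square_gate <- function(name, lo, hi, priority = 1L, color = "#FFFFFF") {
  phasor_gate(name, rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi)),
              priority, color)
}

test_that("gate back-mapping assigns labels by containment and priority", {
  G <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2)
  S <- matrix(c(-0.5, -0.5, 0.5, 0.5), 2, 2)
  field <- make_field(G, S)
  # universal gate labels every valid pixel
  lab <- gate_segment(field, list(square_gate("all", -1, 1)))
  expect_true(all(lab$labels == 1L))
  # overlapping gates: the higher priority wins on the overlap; only the
  # (0.5, 0.5) pixel lies in the high-priority box
  gates <- list(square_gate("low", -1, 1, priority = 1L),
                square_gate("high", 0, 1, priority = 2L))
  lab <- gate_segment(field, gates)
  expect_identical(lab$labels, matrix(c(1L, 1L, 2L, 1L), 2, 2))
  # a point exactly on a gate edge counts as inside
  edge_field <- make_field(matrix(0.5), matrix(0))
  edge_gate <- phasor_gate("g", rbind(c(0.5, -1), c(1, -1), c(1, 1), c(0.5, 1)))
  lab <- gate_segment(edge_field, list(edge_gate))
  expect_identical(lab$labels[1, 1], 1L)
  # invalid pixels stay unlabelled under a universal gate
  field$valid_mask[1, 1] <- FALSE
  lab <- gate_segment(field, list(square_gate("all", -1, 1)))
  expect_identical(lab$labels[1, 1], 0L)
  expect_error(gate_segment(field, list(square_gate("x", -1, 0),
                                        square_gate("x", 0, 1, 2L))),
               "duplicate")
  expect_error(gate_segment(field, list(square_gate("a", -1, 0),
                                        square_gate("b", 0, 1))),
               "unique")
})

test_that("gate polygons must be simple", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(phasor_gate("bad", bowtie), "simple")
})

test_that("seeded k-means gating recovers separated populations exactly", {
  # two delta-spectrum populations at phasor (1, 0) and (-1, 0)
  arr <- array(0, c(10, 10, 8))
  left <- matrix(FALSE, 10, 10); left[, 1:5] <- TRUE
  for (k in 1:8) {
    plane <- matrix(0, 10, 10)
    if (k == 1) plane[!left] <- 1   # delta at first frame -> (1, 0)
    if (k == 5) plane[left] <- 1    # delta at half period -> (-1, 0)
    arr[, , k] <- plane
  }
  st <- hyperstack(arr, wavenumber_axis(1:8))
  field <- phasor_transform(st, intensity_threshold = 0)
  gates <- auto_cluster(field, k = 2L, seed = 7L)
  lab <- gate_segment(field, gates)
  expect_identical(length(unique(lab$labels[left])), 1L)
  expect_identical(length(unique(lab$labels[!left])), 1L)
  expect_false(lab$labels[1, 1] == lab$labels[1, 10])

  # k = 1: a single gate containing every valid point
  g1 <- auto_cluster(field, k = 1L, seed = 7L)
  expect_length(g1, 1L)
  lab1 <- gate_segment(field, g1)
  expect_true(all(lab1$labels[field$valid_mask] == 1L))

  # degenerate request: more clusters than distinct points
  expect_error(auto_cluster(field, k = 5L, seed = 1L), "degenerate")
})

test_that("auto_cluster is bit-reproducible under a fixed seed", {
  spec <- small_triplex_spec()
  truth <- build_scene(spec)
  field <- phasor_transform(concat_windows(render_stack(truth, spec, scan_plan())))
  g1 <- auto_cluster(field, k = 4L, seed = 123L)
  g2 <- auto_cluster(field, k = 4L, seed = 123L)
  expect_identical(g1, g2)
})

test_that("well-separated noisy scenes are recovered at high purity", {
  # default noise keeps class clusters > 4x their spread apart, the regime
  # in which k-means gating should reach IoU >= 0.9 per class
  for (seed in c(5L, 6L)) {
    spec <- small_triplex_spec(seed = seed)
    truth <- build_scene(spec)
    field <- phasor_transform(
      concat_windows(render_stack(truth, spec, scan_plan())),
      intensity_threshold = 5)
    gates <- auto_cluster(field, k = 9L, seed = 1L)
    lab <- gate_segment(field, gates)
    m <- match_segments(lab, truth$masks, iou_threshold = 0.9)
    expect_identical(m$n_matched, 9L)
  }
})

test_that("segment spectra average, normalise and report empty segments", {
  spec <- small_triplex_spec(noise = NULL)
  truth <- build_scene(spec)
  stacks <- render_stack(truth, spec, scan_plan())
  combined <- concat_windows(stacks)
  k <- length(truth$masks)
  lab_mat <- matrix(0L, spec$rows, spec$cols)
  for (j in seq_len(k)) lab_mat[truth$masks[[j]]] <- j
  lab <- segment_label_image(lab_mat, c(names(truth$masks)))
  tab <- segment_spectra(combined, lab)
  expect_identical(unname(tab$pixel_count),
                   vapply(truth$masks, sum, integer(1), USE.NAMES = FALSE))
  # identical member spectra: the mean is the common spectrum
  px <- which(truth$masks$lipid_droplet, arr.ind = TRUE)[1, ]
  expect_equal(tab$mean[, "lipid_droplet"], combined$intensities[px[1], px[2], ])
  # normalised copies span [0, 1]
  expect_equal(unname(apply(tab$normalized, 2, min)), rep(0, k))
  expect_equal(unname(apply(tab$normalized, 2, max)), rep(1, k))
  # the LD spectrum peaks at the CH2 frame (2851 cm^-1)
  ld_peak <- combined$axis$values[which.max(tab$normalized[, "lipid_droplet"])]
  expect_equal(ld_peak, combined$axis$values[which.min(abs(combined$axis$values - 2851))])

  # single-pixel segment reproduces that pixel's spectrum exactly
  one <- matrix(0L, spec$rows, spec$cols); one[5, 7] <- 1L
  tab1 <- segment_spectra(combined, segment_label_image(one, "px"))
  expect_identical(tab1$mean[, "px"], combined$intensities[5, 7, ])

  # empty segments are reported with count 0 and flagged spectra
  lab2 <- segment_label_image(one, c("px", "empty"),
                              colors = c("#FFFFFF", "#000000"))
  tab2 <- segment_spectra(combined, lab2)
  expect_identical(unname(tab2$pixel_count["empty"]), 0L)
  expect_true(all(is.na(tab2$mean[, "empty"])))
})

test_that("segment spectra are additive over segment unions", {
  spec <- small_triplex_spec()
  truth <- build_scene(spec)
  combined <- concat_windows(render_stack(truth, spec, scan_plan()))
  m <- matrix(0L, spec$rows, spec$cols)
  m[truth$masks$nucleus] <- 1L
  m[truth$masks$cytoplasm] <- 2L
  tab <- segment_spectra(combined, segment_label_image(m, c("n", "c")))
  mu <- matrix(0L, spec$rows, spec$cols)
  mu[truth$masks$nucleus | truth$masks$cytoplasm] <- 1L
  tabu <- segment_spectra(combined, segment_label_image(mu, "u"))
  w <- tab$pixel_count
  expect_equal(tabu$mean[, "u"],
               (w["n"] * tab$mean[, "n"] + w["c"] * tab$mean[, "c"]) / sum(w),
               tolerance = 1e-12)
})

test_that("segment matching scores identity and background correctly", {
  spec <- small_triplex_spec()
  truth <- build_scene(spec)
  k <- length(truth$masks)
  lab_mat <- matrix(0L, spec$rows, spec$cols)
  for (j in seq_len(k)) lab_mat[truth$masks[[j]]] <- j
  lab <- segment_label_image(lab_mat, names(truth$masks))
  m <- match_segments(lab, truth$masks)
  expect_identical(m$n_matched, k)
  expect_true(all(m$table$iou == 1))
  bg <- segment_label_image(matrix(0L, spec$rows, spec$cols), "nothing")
  m0 <- match_segments(bg, truth$masks)
  expect_identical(m0$n_matched, 0L)
})

test_that("composites paint segments in their gate colours", {
  bg <- segment_label_image(matrix(0L, 4, 4), "none")
  expect_true(all(render_composite(bg) == 0))
  uni <- segment_label_image(matrix(1L, 4, 4), "all", colors = "#3366CC")
  img <- render_composite(uni)
  expect_equal(img[1, 1, ], as.numeric(grDevices::col2rgb("#3366CC") / 255))
  expect_identical(length(unique(c(img))), 3L)

  spec <- small_triplex_spec()
  truth <- build_scene(spec)
  k <- length(truth$masks)
  lab_mat <- matrix(0L, spec$rows, spec$cols)
  for (j in seq_len(k)) lab_mat[truth$masks[[j]]] <- j
  lab <- segment_label_image(lab_mat, names(truth$masks))
  img <- render_composite(lab)
  cols <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = "/"))
  expect_gte(length(setdiff(cols, "0/0/0")), 9)
})
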