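test_that("phasor transform reproduces hand-computed values", {
  # delta spectrum at the first (ascending) frame -> (1, 0)
  f <- phasor_transform(stack_from_spectrum(c(1, 0, 0, 0, 0)),
                        intensity_threshold = 0)
  expect_equal(c(f$G[1, 1], f$S[1, 1]), c(1, 0))
  # constant spectrum over a full period -> (0, 0)
  f <- phasor_transform(stack_from_spectrum(rep(3, 4)), intensity_threshold = 0)
  expect_equal(c(f$G[1, 1], f$S[1, 1]), c(0, 0))
  # I = [2, 1, 0, 1]: G = (2 - 0)/4 = 0.5, S = (1 - 1)/4 = 0
  f <- phasor_transform(stack_from_spectrum(c(2, 1, 0, 1)),
                        intensity_threshold = 0)
  expect_equal(c(f$G[1, 1], f$S[1, 1]), c(0.5, 0))
})

test_that("phasor transform agrees with the naive per-pixel oracle", {
  for (seed in 1:3) {
    st <- random_stack(8, 8, 16, seed = seed)
    f <- phasor_transform(st, intensity_threshold = 0)
    o <- naive_phasor(st)
    expect_lt(max(abs(f$G - o$G)), 1e-12)
    expect_lt(max(abs(f$S - o$S)), 1e-12)
  }
  # higher harmonic too
  st <- random_stack(4, 4, 12, seed = 9)
  f <- phasor_transform(st, harmonic = 2L, intensity_threshold = 0)
  o <- naive_phasor(st, harmonic = 2)
  expect_lt(max(abs(f$G - o$G)), 1e-12)
})

test_that("phasor coordinates are bounded and scale invariant", {
  st <- random_stack(10, 10, 24, seed = 4)
  f <- phasor_transform(st, intensity_threshold = 0)
  expect_true(all((f$G^2 + f$S^2)[f$valid_mask] <= 1 + 1e-9))
  # multiplying the spectrum by any positive constant leaves (G, S) unchanged
  for (c in c(0.001, 7, 3e4)) {
    st2 <- hyperstack(st$intensities * c, st$axis)
    f2 <- phasor_transform(st2, intensity_threshold = 0)
    expect_equal(f2$G, f$G, tolerance = 1e-12)
    expect_equal(f2$S, f$S, tolerance = 1e-12)
  }
})

test_that("the transform is linear: mixtures land on the weighted mean", {
  wn <- seq(2000, 2250, length.out = 64)
  ref <- builtin_references()
  a <- eval_spec <- evaluate_reference(ref$stearic_d35, wn)$intensities
  b <- evaluate_reference(ref$am_ester, wn)$intensities
  pa <- phasor_transform(stack_from_spectrum(a, wn), intensity_threshold = 0)
  pb <- phasor_transform(stack_from_spectrum(b, wn), intensity_threshold = 0)
  pm <- phasor_transform(stack_from_spectrum(a + b, wn), intensity_threshold = 0)
  pred <- phasor_of_mixture(list(
    list(point = c(pa$G[1, 1], pa$S[1, 1]), intensity = sum(a)),
    list(point = c(pb$G[1, 1], pb$S[1, 1]), intensity = sum(b))))
  expect_equal(c(pm$G[1, 1], pm$S[1, 1]), pred, tolerance = 1e-12)
})

test_that("phasor_of_mixture handles identity, symmetry and weighting", {
  expect_equal(phasor_of_mixture(list(list(point = c(0.3, -0.2), intensity = 5))),
               c(0.3, -0.2))
  expect_equal(phasor_of_mixture(list(
    list(point = c(1, 0), intensity = 2),
    list(point = c(-1, 0), intensity = 2))), c(0, 0))
  expect_equal(phasor_of_mixture(list(
    list(point = c(1, 0), intensity = 3),
    list(point = c(0, 1), intensity = 1))), c(0.75, 0.25))
  expect_error(phasor_of_mixture(list(list(point = c(1, 0), intensity = 0))),
               "positive intensity")
})

test_that("peak translation moves the phasor monotonically in angle", {
  wn <- seq(2000, 2250, length.out = 64)
  centers <- seq(2030, 2220, by = 10)
  angles <- vapply(centers, function(cen) {
    ref <- reference_spectrum("peak", list(peak_model(cen, 20)),
                              band_window = c(cen - 10, cen + 10))
    y <- evaluate_reference(ref, wn)$intensities
    f <- phasor_transform(stack_from_spectrum(y, wn), intensity_threshold = 0)
    atan2(f$S[1, 1], f$G[1, 1]) %% (2 * pi)
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
})

test_that("window concatenation abuts frames and validates inputs", {
  spec <- small_triplex_spec(noise = NULL)
  truth <- build_scene(spec)
  stacks <- render_stack(truth, spec, scan_plan())
  expect_equal(vapply(stacks, function(s) dim(s)[3], numeric(1)), c(40, 35, 40))
  combined <- concat_windows(stacks)
  expect_equal(dim(combined)[3], 115)
  expect_setequal(unique(combined$axis$window_id), 0:2)
  # identity on a single stack
  expect_identical(concat_windows(list(stacks[[1]])), stacks[[1]])
  # per-pixel spectra are concatenated unchanged
  expect_identical(combined$intensities[40, 40, 41:75],
                   stacks[[2]]$intensities[40, 40, ])
  # dimension mismatch and overlapping windows are rejected
  small <- hyperstack(array(1, c(2, 2, 3)), wavenumber_axis(c(1, 2, 3)))
  expect_error(concat_windows(list(stacks[[1]], small)), "dimensions")
  overlapping <- hyperstack(array(1, dim(stacks[[1]])),
                            wavenumber_axis(seq(2900, 3000, length.out = 40)))
  expect_error(concat_windows(list(stacks[[1]], overlapping)), "overlap")
})

test_that("phasor histogram conserves counts and resolves the scene clusters", {
  st <- random_stack(6, 6, 10, seed = 2)
  f <- phasor_transform(st, intensity_threshold = 0)
  h <- phasor_histogram(f, bin_count = 32L)
  expect_identical(sum(h$counts), sum(f$valid_mask))
  # identical spectra -> single occupied bin
  stc <- hyperstack(array(rep(c(2, 1, 0, 1), each = 36), c(6, 6, 4)),
                    wavenumber_axis(1:4))
  hc <- phasor_histogram(phasor_transform(stc, intensity_threshold = 0), 32L)
  expect_identical(sum(hc$counts > 0), 1L)
  expect_identical(max(hc$counts), 36L)

  # noiseless triplex scene: at least 3 separated histogram modes
  spec <- small_triplex_spec(noise = NULL)
  truth <- build_scene(spec)
  combined <- concat_windows(render_stack(truth, spec, scan_plan()))
  field <- phasor_transform(combined)
  hist <- phasor_histogram(field, bin_count = 64L)
  counts <- hist$counts
  is_max <- matrix(FALSE, nrow(counts), ncol(counts))
  for (i in 2:(nrow(counts) - 1)) {
    for (j in 2:(ncol(counts) - 1)) {
      nb <- counts[(i - 1):(i + 1), (j - 1):(j + 1)]
      is_max[i, j] <- counts[i, j] > 0 && counts[i, j] == max(nb) &&
        sum(nb == counts[i, j]) == 1
    }
  }
  expect_gte(sum(is_max), 3)
})

test_that("an all-background field warns rather than errors", {
  st <- hyperstack(array(0.001, c(3, 3, 4)), wavenumber_axis(1:4))
  expect_warning(f <- phasor_transform(st, intensity_threshold = 10),
                 "no pixel passes")
  expect_false(any(f$valid_mask))
})

test_that("phasor fields serialise and reload", {
  spec <- small_triplex_spec()
  truth <- build_scene(spec)
  combined <- concat_windows(render_stack(truth, spec, scan_plan()))
  f <- phasor_transform(combined)
  tp <- withr::local_tempfile(fileext = ".tif")
  jp <- withr::local_tempfile(fileext = ".json")
  write_phasor_field(f, tp, jp)
  back <- read_phasor_field(tp, jp)
  expect_identical(back$valid_mask, f$valid_mask)
  expect_lt(max(abs(back$G - f$G)), 1e-6)
  expect_lt(max(abs(back$S - f$S)), 1e-6)
  expect_equal(back$harmonic, f$harmonic)
})
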