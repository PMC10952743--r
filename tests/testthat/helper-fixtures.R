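# Shared fixtures: small scenes and an independent phasor oracle.

# A scaled-down triplex scene (96 x 96) with the preset's class weights and
# noise model; small enough for fast unit tests while keeping all 9 classes.
small_triplex_spec <- function(seed = 5L,
                               noise = list(gaussian_sd = 0.03,
                                            poisson_scale = 0.0016)) {
  preset <- scene_presets("triplex_crsan")
  scene_spec(rows = 128L, cols = 128L,
             cell = list(center = c(63.5, 63.5), semi = c(54, 45), angle = 0.3),
             nucleus = list(center = c(58, 69), semi = c(21, 17), angle = -0.2),
             nucleoli = list(n = 1L, radius = 4),
             lds = list(n = 6L, radius = 3, n_loaded = 3L),
             periphery_width = 2, boundary_width = 2,
             pockets = list(crsan = list(n = 2L, radius = 5),
                            am = list(n = 1L, radius = 4)),
             classes = preset$classes, noise = noise, seed = seed)
}

# Independent phasor oracle: per-pixel double loop over frames, no shared
# code with phasor_transform beyond the ascending-axis convention.
naive_phasor <- function(stack, harmonic = 1) {
  d <- dim(stack$intensities)
  ord <- order(stack$axis$values)
  G <- S <- matrix(0, d[1], d[2])
  n <- d[3]
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      I <- stack$intensities[r, c, ord]
      tot <- 0; gs <- 0; ss <- 0
      for (k in seq_len(n)) {
        a <- 2 * pi * harmonic * (k - 1) / n
        tot <- tot + I[k]
        gs <- gs + I[k] * cos(a)
        ss <- ss + I[k] * sin(a)
      }
      if (tot > 0) { G[r, c] <- gs / tot; S[r, c] <- ss / tot }
    }
  }
  list(G = G, S = S)
}

# single-pixel-column stack from a plain spectrum vector (ascending axis)
stack_from_spectrum <- function(intensities, wavenumbers = seq_along(intensities)) {
  hyperstack(array(intensities, c(1, 1, length(intensities))),
             wavenumber_axis(wavenumbers))
}

random_stack <- function(rows, cols, frames, seed = 1L) {
  withr::with_seed(seed, {
    hyperstack(array(stats::runif(rows * cols * frames), c(rows, cols, frames)),
               wavenumber_axis(seq_len(frames)))
  })
}
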