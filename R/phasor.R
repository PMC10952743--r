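#' Concatenate acquisition windows into one stack
#'
#' Spectral phasor analysis of a multi-window experiment operates on the
#' combined image stack: per-pixel spectra from each window are abutted with
#' no resampling. Windows must not overlap in wavenumber and all stacks must
#' share image dimensions. Window ids are re-tagged so they remain distinct
#' and non-decreasing across the concatenated frame axis.
#'
#' @param stacks A list of [hyperstack()] objects, in the desired order.
#' @return A single [hyperstack()] with the concatenated frame axis.
#' @export
concat_windows <- function(stacks) {
  if (inherits(stacks, "hyper_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1L, all(vapply(stacks, inherits, TRUE, "hyper_stack")))
  if (length(stacks) == 1L) return(stacks[[1]])
  dims <- vapply(stacks, function(s) dim(s$intensities)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all stacks must share the same image dimensions", call. = FALSE)
  }
  rng <- vapply(stacks, function(s) range(s$axis$values), numeric(2))
  ord <- order(rng[1, ])
  for (i in seq_len(length(stacks) - 1L)) {
    if (rng[2, ord[i]] >= rng[1, ord[i + 1L]]) {
      stop("windows overlap in wavenumber; they must be disjoint", call. = FALSE)
    }
  }
  values <- unlist(lapply(stacks, function(s) s$axis$values))
  wid <- integer(0)
  next_id <- 0L
  for (s in stacks) {
    w <- s$axis$window_id
    wid <- c(wid, w - min(w) + next_id)
    next_id <- next_id + length(unique(w))
  }
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(values)))
  at <- 0L
  for (s in stacks) {
    nf <- dim(s$intensities)[3]
    arr[, , at + seq_len(nf)] <- s$intensities
    at <- at + nf
  }
  hyperstack(arr, wavenumber_axis(values, wid, stacks[[1]]$axis$step_nm))
}

#' Per-pixel spectral phasor transform
#'
#' For each pixel with spectrum I(k) over frames k = 0..N-1 taken in
#' ascending-wavenumber order, the first-harmonic (or harmonic n) phasor
#' coordinates are
#' \deqn{G = \sum_k I(k)\cos(2\pi nk/N) / \sum_k I(k), \quad
#'       S = \sum_k I(k)\sin(2\pi nk/N) / \sum_k I(k).}
#' Similar spectral shapes map to nearby (G, S) points independently of
#' intensity, which is what makes phasor space a segmentation space. For
#' multi-window stacks the Fourier coordinate is the frame index of the
#' ascending-sorted concatenated axis (windows abutted, gaps ignored).
#'
#' Pixels whose total intensity falls below `intensity_threshold` have an
#' undefined (noise-dominated) phasor; they are flagged invalid and carry
#' (G, S) = (0, 0).
#'
#' @param stack A [hyperstack()] with at least 2 frames.
#' @param harmonic Positive integer Fourier harmonic (default 1).
#' @param intensity_threshold Minimum per-pixel total intensity for a valid
#'   phasor. Default: 1% of the maximum per-pixel total intensity.
#' @return A `phasor_field` with matrices `G`, `S`, `total_intensity`,
#'   logical `valid_mask`, and scalars `harmonic`, `intensity_threshold`.
#' @export
phasor_transform <- function(stack, harmonic = 1L, intensity_threshold = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  d <- dim(stack$intensities)
  n_frames <- d[3]
  if (n_frames < 2L) stop("phasor transform needs at least 2 frames", call. = FALSE)
  if (harmonic < 1L) stop("harmonic must be >= 1", call. = FALSE)
  ord <- order(stack$axis$values)
  p <- matrix(stack$intensities, d[1] * d[2], n_frames)[, ord, drop = FALSE]
  k <- seq_len(n_frames) - 1
  ang <- 2 * pi * harmonic * k / n_frames
  tot <- rowSums(p)
  if (is.null(intensity_threshold)) intensity_threshold <- 0.01 * max(tot)
  valid <- tot >= intensity_threshold & tot > 0
  g <- s <- numeric(length(tot))
  g[valid] <- (p[valid, , drop = FALSE] %*% cos(ang)) / tot[valid]
  s[valid] <- (p[valid, , drop = FALSE] %*% sin(ang)) / tot[valid]
  if (!any(valid)) {
    warning("no pixel passes the intensity threshold; phasor field is empty",
            call. = FALSE)
  }
  structure(list(G = matrix(g, d[1], d[2]), S = matrix(s, d[1], d[2]),
                 total_intensity = matrix(tot, d[1], d[2]),
                 valid_mask = matrix(valid, d[1], d[2]),
                 harmonic = as.integer(harmonic),
                 intensity_threshold = intensity_threshold),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field> %d x %d, harmonic %d, %d valid pixels\n",
              nrow(x$G), ncol(x$G), x$harmonic, sum(x$valid_mask)))
  invisible(x)
}

#' Predicted phasor of a spectral mixture
#'
#' The phasor transform is linear in the spectrum, so the phasor of a sum of
#' component spectra is the total-intensity-weighted mean of the component
#' phasors. This is the law that makes phasor-space unmixing geometric:
#' mixtures lie on the segment (or in the simplex) spanned by the pure
#' component points.
#'
#' @param components List of `list(point = c(G, S), intensity = )` entries.
#' @return Numeric `c(G, S)` of the mixture.
#' @export
phasor_of_mixture <- function(components) {
  stopifnot(length(components) >= 1L)
  w <- vapply(components, function(c) c$intensity, numeric(1))
  if (any(w < 0)) stop("component intensities must be >= 0", call. = FALSE)
  if (sum(w) <= 0) stop("at least one component must have positive intensity",
                        call. = FALSE)
  pts <- vapply(components, function(c) as.numeric(c$point), numeric(2))
  as.numeric(pts %*% w / sum(w))
}

#' 2-D histogram of a phasor field
#'
#' Counts valid pixels on a fixed `bin_count` x `bin_count` grid over
#' \[-1, 1\]^2 (this is the "phasor plot"). Total counts equal the number of
#' valid pixels; points on the +1 boundary fall in the last bin.
#'
#' @param field A `phasor_field`.
#' @param bin_count Bins per side, >= 2.
#' @return A `phasor_histogram` with `counts` (G bins as rows), `breaks`.
#' @export
phasor_histogram <- function(field, bin_count = 200L) {
  stopifnot(inherits(field, "phasor_field"), bin_count >= 2L)
  breaks <- seq(-1, 1, length.out = bin_count + 1L)
  g <- field$G[field$valid_mask]
  s <- field$S[field$valid_mask]
  bin <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                          bin_count)
  counts <- matrix(0L, bin_count, bin_count)
  if (length(g) > 0L) {
    tab <- table(factor(bin(g), levels = seq_len(bin_count)),
                 factor(bin(s), levels = seq_len(bin_count)))
    counts <- matrix(as.integer(tab), bin_count, bin_count)
  }
  structure(list(counts = counts, bin_count = as.integer(bin_count),
                 breaks = breaks),
            class = "phasor_histogram")
}

#' Serialise a phasor field to a 3-plane float TIFF + JSON sidecar
#'
#' Planes are (G, S, total intensity); G and S are stored shifted to
#' \[0, 1\] as (x + 1)/2, the intensity plane is normalised by its maximum,
#' all recorded in the sidecar together with `harmonic` and
#' `intensity_threshold`.
#'
#' @param field A `phasor_field`.
#' @param tiff_path,json_path Output paths.
#' @export
write_phasor_field <- function(field, tiff_path, json_path) {
  stopifnot(inherits(field, "phasor_field"))
  tmax <- max(field$total_intensity)
  if (tmax <= 0) tmax <- 1
  pages <- list((field$G + 1) / 2, (field$S + 1) / 2,
                field$total_intensity / tmax)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(list(harmonic = field$harmonic,
                            intensity_threshold = field$intensity_threshold,
                            intensity_scale = tmax),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(tiff_path, json_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  tot <- pages[[3]] * meta$intensity_scale
  valid <- tot >= meta$intensity_threshold & tot > 0
  g <- pages[[1]] * 2 - 1
  s <- pages[[2]] * 2 - 1
  g[!valid] <- 0; s[!valid] <- 0
  structure(list(G = g, S = s, total_intensity = tot, valid_mask = valid,
                 harmonic = as.integer(meta$harmonic),
                 intensity_threshold = meta$intensity_threshold),
            class = "phasor_field")
}

#' Export a phasor histogram as a CSV grid
#'
#' @param hist A `phasor_histogram`.
#' @param path Output CSV path (bin_count rows x bin_count columns, G bins
#'   as rows).
#' @export
write_phasor_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "phasor_histogram"))
  utils::write.table(hist$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}
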