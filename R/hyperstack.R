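#' Construct a wavenumber axis
#'
#' A wavenumber axis binds each frame of a hyperspectral stack to a Raman
#' shift (cm^-1) and groups frames into acquisition windows. Frames are kept
#' in acquisition order: within a window the instrument tunes the pump laser
#' monotonically, so values must be strictly monotonic (either direction)
#' within each window, and window ids must be non-decreasing over frames.
#'
#' @param values Numeric vector of Raman shifts (cm^-1), one per frame.
#' @param window_id Integer vector tagging each frame with its acquisition
#'   window; defaults to a single window 0.
#' @param step_nm Nominal pump-tuning step in nm (metadata only).
#' @return A `wavenumber_axis` object.
#' @export
wavenumber_axis <- function(values, window_id = rep(0L, length(values)),
                            step_nm = NA_real_) {
  values <- as.numeric(values)
  window_id <- as.integer(window_id)
  if (length(values) != length(window_id)) {
    stop("`values` and `window_id` must have the same length", call. = FALSE)
  }
  if (length(values) == 0L) {
    stop("a wavenumber axis needs at least one frame", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (is.unsorted(window_id)) {
    stop("window_id must be non-decreasing over frame index", call. = FALSE)
  }
  for (w in unique(window_id)) {
    v <- values[window_id == w]
    if (length(v) > 1L) {
      d <- diff(v)
      if (!(all(d > 0) || all(d < 0))) {
        stop("wavenumbers must be strictly monotonic within window ", w,
             call. = FALSE)
      }
    }
  }
  structure(list(values = values, window_id = window_id,
                 step_nm = as.numeric(step_nm)[1]),
            class = "wavenumber_axis")
}

#' @export
length.wavenumber_axis <- function(x) length(x$values)

#' @export
print.wavenumber_axis <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<wavenumber_axis> %d frames, %d window(s), %.1f-%.1f cm^-1\n",
              length(x$values), length(unique(x$window_id)), rng[1], rng[2]))
  invisible(x)
}

#' Construct a hyperspectral stack
#'
#' The central data object of the pipeline: a rows x cols x frames array of
#' non-negative SRS intensities bound to a [wavenumber_axis()].
#'
#' @param intensities Numeric array, rows x cols x frames.
#' @param axis A `wavenumber_axis` whose length equals the frame count.
#' @return A `hyper_stack` object.
#' @export
hyperstack <- function(intensities, axis) {
  if (!inherits(axis, "wavenumber_axis")) {
    stop("`axis` must be a wavenumber_axis", call. = FALSE)
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array (rows x cols x frames)",
         call. = FALSE)
  }
  if (dim(intensities)[3] == 0L) {
    stop("a hyperstack needs at least one frame", call. = FALSE)
  }
  if (dim(intensities)[3] != length(axis)) {
    stop(sprintf("frame count (%d) does not match axis length (%d)",
                 dim(intensities)[3], length(axis)), call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(intensities = intensities, axis = axis),
            class = "hyper_stack")
}

#' @export
dim.hyper_stack <- function(x) dim(x$intensities)

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<hyper_stack> %d x %d pixels, %d frames\n", d[1], d[2], d[3]))
  print(x$axis)
  invisible(x)
}

#' Construct a single-point SRS spectrum
#'
#' @param wavenumbers Strictly increasing Raman shifts (cm^-1).
#' @param intensities Non-negative intensities, same length.
#' @return An `srs_spectrum` object.
#' @export
srs_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length",
         call. = FALSE)
  }
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "srs_spectrum")
}

# Sidecar JSON for an axis: {wavenumbers, window_ids, step_nm} plus the
# storage encoding of the paired TIFF (dtype, scale).
axis_sidecar <- function(axis, dtype, scale) {
  out <- list(wavenumbers = axis$values, window_ids = axis$window_id,
              dtype = dtype, scale = scale)
  if (is.finite(axis$step_nm)) out$step_nm <- axis$step_nm
  out
}

#' Read a hyperspectral stack from TIFF + JSON sidecar
#'
#' The stack is a multi-page grayscale TIFF (one page per wavenumber frame);
#' the sidecar is JSON with keys `wavenumbers`, `window_ids`, `step_nm`, and
#' the storage keys `dtype` ("uint16" or "float32") and `scale` written by
#' [write_stack()]. Page order defines frame order.
#'
#' @param stack_path Path to the multi-page TIFF.
#' @param axis_path Path to the JSON sidecar.
#' @return A [hyperstack()].
#' @export
read_stack <- function(stack_path, axis_path) {
  pages <- tiff::readTIFF(stack_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(axis_path, simplifyVector = TRUE)
  wn <- as.numeric(meta$wavenumbers)
  if (length(wn) != length(pages)) {
    stop(sprintf(
      "stack has %d pages but axis sidecar lists %d wavenumbers",
      length(pages), length(wn)), call. = FALSE)
  }
  wid <- if (!is.null(meta$window_ids)) as.integer(meta$window_ids)
         else rep(0L, length(wn))
  axis <- wavenumber_axis(wn, wid,
                          if (is.null(meta$step_nm)) NA_real_ else meta$step_nm)
  dtype <- if (is.null(meta$dtype)) "float32" else meta$dtype
  scale <- if (is.null(meta$scale)) 1 else as.numeric(meta$scale)
  arr <- simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate multi-channel pages
    p
  }))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (identical(dtype, "uint16")) {
    arr <- round(arr * 65535)
  } else {
    arr <- arr * scale
  }
  hyperstack(arr, axis)
}

#' Write a hyperspectral stack to TIFF + JSON sidecar
#'
#' Integer-valued stacks within \[0, 65535\] are stored as 16-bit unsigned
#' pages and round-trip bit-exactly; other stacks are stored as 32-bit float
#' pages normalised by a `scale` recorded in the sidecar.
#'
#' @param stack A [hyperstack()].
#' @param stack_path Output TIFF path.
#' @param axis_path Output JSON sidecar path.
#' @return Invisibly, `NULL`.
#' @export
write_stack <- function(stack, stack_path, axis_path) {
  stopifnot(inherits(stack, "hyper_stack"))
  x <- stack$intensities
  integral <- all(x == round(x)) && max(x) <= 65535
  if (integral) {
    dtype <- "uint16"; scale <- 65535
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 65535)
    bits <- 16L
  } else {
    dtype <- "float32"
    scale <- max(x)
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, stack_path, bits.per.sample = bits)
  jsonlite::write_json(axis_sidecar(stack$axis, dtype, scale), axis_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Convert a pump-wavelength tuning step to a wavenumber step
#'
#' First-order increment of the Raman shift for a small change of the pump
#' wavelength: d(nu~)/d(lambda) of nu~ = 1e7 / lambda gives
#' delta_nu~ = 1e7 * step_nm / pump_nm^2 (cm^-1).
#'
#' @param step_nm Pump tuning step (nm), >= 0.
#' @param pump_nm Pump wavelength (nm), > 0.
#' @return Wavenumber step in cm^-1.
#' @export
pump_step_to_wavenumber_step <- function(step_nm, pump_nm) {
  if (any(step_nm < 0) || any(pump_nm <= 0)) {
    stop("step_nm must be >= 0 and pump_nm > 0", call. = FALSE)
  }
  1e7 * step_nm / pump_nm^2
}

#' Extract a single-frequency image, optionally off-resonance subtracted
#'
#' Selects the frame whose wavenumber is nearest to `center` (ties broken
#' toward the lower frame index). When `off_resonance` is given, the nearest
#' off-resonance frame is subtracted pixelwise and negatives are clipped to
#' zero, mirroring background-subtracted SRS display images.
#'
#' @param stack A [hyperstack()].
#' @param center Requested wavenumber (cm^-1).
#' @param off_resonance Optional off-resonance wavenumber (cm^-1).
#' @return A `frequency_image` with fields `image`, `center_wavenumber`,
#'   `off_resonance_wavenumber`.
#' @export
extract_frequency_image <- function(stack, center, off_resonance = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  nearest_frame <- function(target) {
    v <- stack$axis$values
    step <- if (length(v) > 1L) max(abs(diff(v))) else Inf
    d <- abs(v - target)
    if (min(d) > step) {
      stop(sprintf("wavenumber %.1f cm^-1 is outside the axis range by more than one step",
                   target), call. = FALSE)
    }
    which.min(d)  # which.min returns the first (lowest-index) minimum
  }
  img <- stack$intensities[, , nearest_frame(center)]
  off <- NULL
  if (!is.null(off_resonance)) {
    img <- img - stack$intensities[, , nearest_frame(off_resonance)]
    img[img < 0] <- 0
    off <- off_resonance
  }
  structure(list(image = img, center_wavenumber = center,
                 off_resonance_wavenumber = off),
            class = "frequency_image")
}

#' Construct a segment label image
#'
#' @param labels Integer matrix; 0 means unassigned, segments are dense
#'   labels 1..K.
#' @param names Character vector of K segment names (label i -> names\[i\]).
#' @param colors Character vector of K hex colours.
#' @return A `segment_label_image`.
#' @export
segment_label_image <- function(labels, names, colors = NULL) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  k <- max(0L, labels)
  used <- sort(unique(labels[labels > 0L]))
  if (length(used) > 0L && (min(used) < 1L || k > length(names))) {
    stop("every nonzero label must index into `names`", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("segment names must be unique", call. = FALSE)
  }
  if (is.null(colors)) colors <- grDevices::hcl.colors(max(length(names), 2L), "Dark 3")[seq_along(names)]
  structure(list(labels = labels, names = as.character(names),
                 colors = as.character(colors)),
            class = "segment_label_image")
}

#' Write / read a label image as 16-bit TIFF + JSON name map
#'
#' @param seg A [segment_label_image()].
#' @param tiff_path Output TIFF path.
#' @param json_path Output JSON path for the name/colour map.
#' @return Invisibly `NULL`; `read_label_image` returns the object.
#' @export
write_label_image <- function(seg, tiff_path, json_path) {
  stopifnot(inherits(seg, "segment_label_image"))
  tiff::writeTIFF(seg$labels / 65535, tiff_path, bits.per.sample = 16L)
  jsonlite::write_json(list(names = seg$names, colors = seg$colors),
                       json_path, auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(tiff_path, json_path) {
  m <- tiff::readTIFF(tiff_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  segment_label_image(round(m * 65535), meta$names, meta$colors)
}

#' Read / write a spectrum as two-column CSV (wavenumber_cm1, intensity)
#'
#' @param path CSV path.
#' @return `read_spectrum_csv` returns an [srs_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  srs_spectrum(df[[1]], df[[2]])
}

#' @rdname read_spectrum_csv
#' @param spec An [srs_spectrum()] to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "srs_spectrum"))
  utils::write.csv(
    data.frame(wavenumber_cm1 = spec$wavenumbers, intensity = spec$intensities),
    path, row.names = FALSE)
  invisible(NULL)
}
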