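#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Exactly one input source
#' must be given: a scene preset name (the simulator provides stacks and
#' ground truth) or a list of stack/axis path pairs.
#'
#' @param preset Scene preset name (see [scene_presets()]), a [scene_spec()]
#'   object, or `NULL`.
#' @param stack_paths,axis_paths Character vectors of TIFF/JSON paths (one
#'   pair per window), or `NULL`.
#' @param windows Optional list of `c(lo, hi)` wavenumber ranges; only
#'   frames inside one of the ranges are analysed (window subset selection).
#' @param harmonic Phasor harmonic (default 1).
#' @param intensity_threshold Numeric threshold, or `"auto"` (default) for a
#'   two-class k-means (ISODATA-style) split of the per-pixel total
#'   intensities, or `"fraction"` for 1% of the maximum total intensity.
#' @param mode Segmentation mode: `list(kmeans = k)` or
#'   `list(gates = <list of phasor_gate>)`.
#' @param truth `"classes"` (match all scene classes), `"probes"` (match the
#'   merged probe classes; used for silent-region runs) or `"none"`.
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @param seed Integer master seed; stage sub-seeds are derived by fixed
#'   offsets (simulation uses `seed`, clustering `seed + 100`).
#' @param log Emit per-stage messages with timings.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, stack_paths = NULL,
                            axis_paths = NULL, windows = NULL,
                            harmonic = 1L, intensity_threshold = "auto",
                            mode = list(kmeans = 9L), truth = "classes",
                            out_dir = NULL, seed = 1L, log = TRUE) {
  if (is.null(preset) == is.null(stack_paths)) {
    stop("exactly one of `preset` or `stack_paths` must be given", call. = FALSE)
  }
  if (!is.null(stack_paths) && length(stack_paths) != length(axis_paths)) {
    stop("`stack_paths` and `axis_paths` must pair up", call. = FALSE)
  }
  if (!is.null(mode$kmeans) && mode$kmeans < 1L) {
    stop("kmeans mode needs k >= 1", call. = FALSE)
  }
  if (is.null(mode$kmeans) && is.null(mode$gates)) {
    stop("`mode` must be list(kmeans = k) or list(gates = ...)", call. = FALSE)
  }
  truth <- match.arg(truth, c("classes", "probes", "none"))
  structure(list(preset = preset, stack_paths = stack_paths,
                 axis_paths = axis_paths, windows = windows,
                 harmonic = as.integer(harmonic),
                 intensity_threshold = intensity_threshold,
                 mode = mode, truth = truth, out_dir = out_dir,
                 seed = as.integer(seed), log = isTRUE(log)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # seed excluded: reports of the same analysis under different seeds should
  # be comparable (and report their differing metrics)
  plain <- unclass_deep(config[setdiff(names(config),
                                       c("out_dir", "log", "seed"))])
  plain$mode <- lapply(plain$mode, function(m) {
    if (is.list(m)) lapply(m, unclass_deep) else m
  })
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Restrict a stack to frames inside given wavenumber ranges
#'
#' @param stack A [hyperstack()].
#' @param ranges List of `c(lo, hi)` ranges (cm^-1).
#' @return A [hyperstack()] with only the selected frames, or `NULL` when no
#'   frame matches.
#' @export
select_windows <- function(stack, ranges) {
  keep <- rep(FALSE, length(stack$axis))
  for (r in ranges) {
    keep <- keep | (stack$axis$values >= r[1] & stack$axis$values <= r[2])
  }
  if (!any(keep)) return(NULL)
  hyperstack(stack$intensities[, , keep, drop = FALSE],
             wavenumber_axis(stack$axis$values[keep],
                             stack$axis$window_id[keep],
                             stack$axis$step_nm))
}

# Two-class 1-D k-means split of log-total intensities (ISODATA-style);
# returns the midpoint of the two cluster centers mapped back to intensity.
# The log domain keeps the background/cell split from being dragged upward
# by the brightest cell pixels. Initialised at the 5%/95% quantiles, so it
# is deterministic.
auto_threshold <- function(tot) {
  v <- log1p(as.numeric(tot))
  init <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
  if (diff(init) == 0) return(expm1(init[1]))
  fit <- suppressWarnings(stats::kmeans(v, centers = matrix(init, 2, 1),
                                        iter.max = 100L))
  expm1(mean(fit$centers))
}

# Merge scene classes into the three probe-bearing truth classes used for
# silent-region evaluation: everything whose silent-window signal is pure
# B-H (weak or strong), the co-localised stearic+alkyne droplets, and the
# alkyne-dominated pockets.
probe_truth_masks <- function(truth) {
  m <- truth$masks
  pure_bh <- c("nucleus", "nucleolus", "cytoplasm", "crsan")
  pure_bh <- pure_bh[pure_bh %in% names(m)]
  out <- list()
  if (length(pure_bh) > 0L) {
    out$bh_probe <- Reduce(`|`, m[pure_bh])
  }
  if ("stearic_am_coloc" %in% names(m)) out$stearic_am_coloc <- m$stearic_am_coloc
  if ("am_pocket" %in% names(m)) out$alkyne_pocket <- m$am_pocket
  if ("fesan" %in% names(m)) out$fesan <- m$fesan
  out
}

#' Run the end-to-end unmixing pipeline
#'
#' Executes: simulate (when a preset is configured) or load stacks ->
#' window selection -> concatenation -> phasor transform -> segmentation
#' (seeded k-means gates or explicit gates) -> per-segment spectra ->
#' composite rendering -> ground-truth matching (when available), writes
#' artifacts plus a JSON report, and returns the report.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with `segments_found`, `per_class_iou`,
#'   `n_matched`, `rie_table`, `seeds`, `config_hash`, `timings` and the
#'   intermediate objects (`field`, `labels`, `spectra`, `matching`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    if (config$log) message(sprintf("[%s] %.2fs", name, dt))
    out
  }

  truth <- NULL
  stacks <- if (!is.null(config$preset)) {
    stage("simulate", {
      spec <- if (inherits(config$preset, "scene_spec")) config$preset
              else scene_presets(config$preset)
      spec$seed <- config$seed
      truth <- build_scene(spec)  # promise evaluates in this frame
      plan <- if (!is.null(spec$default_plan)) spec$default_plan else scan_plan()
      render_stack(truth, spec, plan)
    })
  } else {
    stage("load", mapply(read_stack, config$stack_paths, config$axis_paths,
                         SIMPLIFY = FALSE))
  }

  if (!is.null(config$windows)) {
    stacks <- stage("select_windows", {
      out <- lapply(stacks, select_windows, ranges = config$windows)
      out <- out[!vapply(out, is.null, TRUE)]
      if (length(out) == 0L) stop("window selection removed every frame")
      out
    })
  }
  combined <- stage("concat", concat_windows(stacks))

  field <- stage("phasor", {
    thr <- config$intensity_threshold
    if (identical(thr, "auto")) {
      d <- dim(combined$intensities)
      tot <- rowSums(matrix(combined$intensities, d[1] * d[2], d[3]))
      thr <- auto_threshold(tot)
    } else if (identical(thr, "fraction")) {
      thr <- NULL  # phasor_transform's own 1%-of-max default
    }
    phasor_transform(combined, config$harmonic, thr)
  })

  labels <- stage("segment", {
    gates <- if (!is.null(config$mode$kmeans)) {
      auto_cluster(field, config$mode$kmeans, seed = config$seed + 100L)
    } else {
      config$mode$gates
    }
    gate_segment(field, gates)
  })

  spectra <- stage("spectra", segment_spectra(combined, labels))
  composite <- stage("composite", render_composite(labels, field$total_intensity))

  matching <- NULL
  if (!is.null(truth) && config$truth != "none") {
    matching <- stage("evaluate", {
      masks <- if (config$truth == "probes") probe_truth_masks(truth)
               else truth$masks
      match_segments(labels, masks)
    })
  }

  rie_table <- stage("rie", builtin_rie_table())

  report <- structure(list(
    segments_found = sum(spectra$pixel_count > 0),
    per_class_iou = if (!is.null(matching)) {
      stats::setNames(matching$table$iou, matching$table$class)
    } else NULL,
    n_matched = if (!is.null(matching)) matching$n_matched else NULL,
    rie_table = rie_table,
    seeds = c(master = config$seed, simulate = config$seed,
              cluster = config$seed + 100L),
    config_hash = config_hash(config),
    timings = timings,
    field = field, labels = labels, spectra = spectra,
    composite = composite, matching = matching, truth = truth,
    combined = combined), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    stage("write", write_report_artifacts(report, config))
  }
  report
}

# RIE of every packaged probe reference against the packaged EdU reference,
# evaluated on a 1 cm^-1 grid.
builtin_rie_table <- function(method = "height") {
  refs <- builtin_references()
  grid <- seq(2000, 3100, by = 1)
  edu <- evaluate_reference(refs$edu, grid)
  probes <- names(refs)[!vapply(refs, function(r) is.na(r$rie_height), TRUE)]
  data.frame(
    component = probes,
    rie = vapply(probes, function(n) {
      compute_rie(evaluate_reference(refs[[n]], grid),
                  refs[[n]]$band_window, edu, method)$rie
    }, numeric(1)),
    row.names = NULL)
}

write_report_artifacts <- function(report, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_label_image(report$labels, file.path(out, "segments.tif"),
                    file.path(out, "segments.json"))
  write_composite_png(report$composite, file.path(out, "composite.png"))
  write_segment_spectra_csv(report$spectra, file.path(out, "segment_spectra.csv"))
  write_phasor_field(report$field, file.path(out, "phasor.tif"),
                     file.path(out, "phasor.json"))
  write_phasor_histogram_csv(phasor_histogram(report$field),
                             file.path(out, "phasor_histogram.csv"))
  yaml::write_yaml(unclass_deep(config[setdiff(names(config), "mode")]),
                   file.path(out, "config.yaml"))
  jsonlite::write_json(report_metrics(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

# The serialisable metric subset of a report (what determinism is judged on).
report_metrics <- function(report) {
  list(segments_found = report$segments_found,
       per_class_iou = as.list(report$per_class_iou),
       n_matched = report$n_matched,
       rie_table = report$rie_table,
       seeds = as.list(report$seeds),
       config_hash = report$config_hash)
}

#' Compare two pipeline reports for determinism regressions
#'
#' Refuses to compare reports produced from different configurations; for
#' same-config reports returns the names of differing metrics (empty when
#' the runs are identical).
#'
#' @param report_a,report_b `pipeline_report`s from [run_pipeline()].
#' @return List with `identical` flag and `differing` metric names.
#' @export
run_report_compare <- function(report_a, report_b) {
  if (!identical(report_a$config_hash, report_b$config_hash)) {
    stop("reports come from different configurations; comparison refused",
         call. = FALSE)
  }
  a <- report_metrics(report_a)
  b <- report_metrics(report_b)
  differing <- names(a)[!mapply(identical, a, b)]
  list(identical = length(differing) == 0L, differing = differing)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d segments found\n", x$segments_found))
  if (!is.null(x$n_matched)) {
    cat(sprintf("  %d/%d ground-truth classes recovered at IoU >= %.2f\n",
                x$n_matched, length(x$per_class_iou),
                x$matching$iou_threshold))
  }
  invisible(x)
}
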