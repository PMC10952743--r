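#' Scan plan for a multi-window acquisition
#'
#' Describes the spectral windows of a wavelength-scanned SRS acquisition as
#' (lo, hi, frames) triples. Frames within each window are generated in
#' acquisition order, i.e. descending wavenumber, emulating stepwise pump
#' tuning. The default is the triplex plan: 3050-2800 cm^-1 in 40 frames
#' (C-H region), 2650-2450 cm^-1 in 35 frames (B-H region) and
#' 2250-2000 cm^-1 in 40 frames (C-D / alkyne region), a ~6.4-7.1 cm^-1 step.
#'
#' @param lo,hi Numeric vectors of window bounds (cm^-1), lo < hi.
#' @param frames Integer vector of frame counts, >= 2 per window.
#' @return A `scan_plan` data.frame with columns lo, hi, frames.
#' @export
scan_plan <- function(lo = c(2800, 2450, 2000),
                      hi = c(3050, 2650, 2250),
                      frames = c(40L, 35L, 40L)) {
  stopifnot(length(lo) == length(hi), length(lo) == length(frames))
  if (any(lo >= hi)) stop("each window needs lo < hi", call. = FALSE)
  if (any(frames < 2L)) stop("each window needs >= 2 frames", call. = FALSE)
  ord <- order(lo)
  for (i in seq_len(length(lo) - 1L)) {
    if (hi[ord[i]] >= lo[ord[i + 1L]]) {
      stop("scan windows must not overlap", call. = FALSE)
    }
  }
  structure(data.frame(lo = lo, hi = hi, frames = as.integer(frames)),
            class = c("scan_plan", "data.frame"))
}

#' Specify a synthetic single-cell SRS scene
#'
#' Geometric and spectral ground truth for a simulated cell: an elliptical
#' cell with a boundary band, a nucleus containing nucleoli, cytoplasmic
#' lipid droplets (LDs) with a periphery annulus, and optional circular
#' probe "pockets". Each named class carries a weight vector over the
#' packaged reference-spectrum library; a pixel's analytic spectrum is the
#' weighted sum of the component spectra of its class.
#'
#' @param rows,cols Image size in pixels.
#' @param cell,nucleus Lists `list(center = c(row, col), semi = c(a, b),
#'   angle = )` describing ellipses (0-based pixel coordinates, row-major).
#' @param nucleoli List `list(n, radius)`.
#' @param lds List `list(n, radius, n_loaded)`: `n_loaded` of the `n`
#'   droplets carry the probe payload of the `ld_loaded` region.
#' @param periphery_width,boundary_width Widths (pixels) of the LD-periphery
#'   annulus and the cell-boundary band.
#' @param pockets Named list of `list(n, radius)` circular probe regions
#'   placed in the cytoplasm; region names become `pocket_<name>`.
#' @param classes Ordered named list: class name -> `list(region, weights)`,
#'   where `region` is one of nucleus, nucleolus, cytoplasm, ld_plain,
#'   ld_loaded, ld_periphery, cell_boundary, pocket_<name>, and `weights`
#'   is a named non-negative vector over [builtin_references()] components.
#' @param noise List `list(gaussian_sd, poisson_scale)`; either 0 disables
#'   that term, `NULL` disables noise entirely.
#' @param seed Integer seed driving object placement and noise.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(rows = 256L, cols = 256L,
                       cell = list(center = c(127.5, 127.5),
                                   semi = c(105, 88), angle = 0.3),
                       nucleus = list(center = c(117, 138),
                                      semi = c(46, 38), angle = -0.2),
                       nucleoli = list(n = 2L, radius = 7),
                       lds = list(n = 14L, radius = 4.5, n_loaded = 9L),
                       periphery_width = 2.5,
                       boundary_width = 3,
                       pockets = list(),
                       classes,
                       noise = list(gaussian_sd = 0.03, poisson_scale = 0.0016),
                       seed = 42L) {
  stopifnot(rows >= 16L, cols >= 16L)
  if (lds$n_loaded > lds$n) stop("n_loaded cannot exceed n droplets", call. = FALSE)
  for (cl in classes) {
    if (any(cl$weights < 0)) stop("class weights must be >= 0", call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell = cell, nucleus = nucleus, nucleoli = nucleoli,
                 lds = lds, periphery_width = periphery_width,
                 boundary_width = boundary_width, pockets = pockets,
                 classes = classes, noise = noise, seed = as.integer(seed)),
            class = "scene_spec")
}

# normalised elliptical radius of 0-based pixel coords (row r, col c)
ellipse_radius <- function(r, c, ell) {
  dr <- r - ell$center[1]
  dc <- c - ell$center[2]
  u <- dr * cos(ell$angle) + dc * sin(ell$angle)
  v <- -dr * sin(ell$angle) + dc * cos(ell$angle)
  sqrt((u / ell$semi[1])^2 + (v / ell$semi[2])^2)
}

place_disks <- function(n, radius, ok_fun, min_sep, existing, compartment,
                        rows, cols, retries = 1000L) {
  centers <- existing
  placed <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > retries) {
        stop(sprintf("could not place object %d of %d in compartment '%s' after %d retries",
                     i, n, compartment, retries), call. = FALSE)
      }
      cand <- c(stats::runif(1, 0, rows - 1), stats::runif(1, 0, cols - 1))
      if (!ok_fun(cand)) next
      if (nrow(centers) > 0L) {
        d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        if (any(d < min_sep)) next
      }
      break
    }
    centers <- rbind(centers, cand)
    placed <- rbind(placed, cand)
  }
  placed
}

#' Build the ground-truth class masks of a scene
#'
#' Deterministic given the spec's seed: nucleoli, LDs and pockets are placed
#' uniformly at random inside their parent compartments by rejection
#' sampling (bounded retries), peripheries and the boundary band are derived
#' geometrically, and the named classes partition the cell footprint.
#'
#' @param spec A [scene_spec()].
#' @return A `ground_truth`: named list `masks` of logical matrices (one per
#'   class, in spec class order) plus the placed geometry.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  rr <- matrix(seq_len(spec$rows) - 1, spec$rows, spec$cols)
  cc <- matrix(rep(seq_len(spec$cols) - 1, each = spec$rows), spec$rows, spec$cols)
  r_cell <- ellipse_radius(rr, cc, spec$cell)
  r_nuc <- ellipse_radius(rr, cc, spec$nucleus)
  cell_mask <- r_cell <= 1
  bw <- spec$boundary_width / mean(spec$cell$semi)
  boundary <- cell_mask & r_cell > 1 - bw
  nucleus_all <- r_nuc <= 1

  geom <- withr::with_seed(spec$seed, {
    nuc_margin <- (spec$nucleoli$radius + 1) / min(spec$nucleus$semi)
    nucleoli <- place_disks(
      spec$nucleoli$n, spec$nucleoli$radius,
      function(p) ellipse_radius(p[1], p[2], spec$nucleus) <= 1 - nuc_margin,
      min_sep = 2 * spec$nucleoli$radius + 2,
      existing = matrix(numeric(0), 0, 2), compartment = "nucleolus",
      rows = spec$rows, cols = spec$cols)

    ld_r <- spec$lds$radius
    cyto_ok <- function(p, obj_r) {
      margin_cell <- (spec$boundary_width + obj_r + spec$periphery_width + 1) /
        min(spec$cell$semi)
      margin_nuc <- (obj_r + spec$periphery_width + 1) / min(spec$nucleus$semi)
      ellipse_radius(p[1], p[2], spec$cell) <= 1 - margin_cell &&
        ellipse_radius(p[1], p[2], spec$nucleus) >= 1 + margin_nuc
    }
    lds <- if (spec$lds$n > 0L) place_disks(
      spec$lds$n, ld_r, function(p) cyto_ok(p, ld_r),
      min_sep = 2 * (ld_r + spec$periphery_width) + 2,
      existing = matrix(numeric(0), 0, 2), compartment = "lipid droplet",
      rows = spec$rows, cols = spec$cols) else matrix(numeric(0), 0, 2)

    pocket_centers <- list()
    occupied <- lds
    occupied_r <- rep(ld_r + spec$periphery_width, nrow(lds))
    for (pn in names(spec$pockets)) {
      pk <- spec$pockets[[pn]]
      ok <- function(p) {
        if (!cyto_ok(p, pk$radius)) return(FALSE)
        if (nrow(occupied) > 0L) {
          d <- sqrt((occupied[, 1] - p[1])^2 + (occupied[, 2] - p[2])^2)
          if (any(d < occupied_r + pk$radius + 2)) return(FALSE)
        }
        TRUE
      }
      pc <- place_disks(pk$n, pk$radius, ok, min_sep = 2 * pk$radius + 2,
                        existing = matrix(numeric(0), 0, 2),
                        compartment = paste0("pocket_", pn),
                        rows = spec$rows, cols = spec$cols)
      pocket_centers[[pn]] <- pc
      occupied <- rbind(occupied, pc)
      occupied_r <- c(occupied_r, rep(pk$radius, nrow(pc)))
    }
    list(nucleoli = nucleoli, lds = lds, pockets = pocket_centers)
  })

  disk_mask <- function(centers, radius) {
    m <- matrix(FALSE, spec$rows, spec$cols)
    for (i in seq_len(nrow(centers))) {
      m <- m | (sqrt((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2) <= radius)
    }
    m
  }

  nucleolus_mask <- disk_mask(geom$nucleoli, spec$nucleoli$radius) & nucleus_all
  nucleus_mask <- nucleus_all & !nucleolus_mask & !boundary
  n_ld <- nrow(geom$lds)
  n_loaded <- min(spec$lds$n_loaded, n_ld)
  loaded_idx <- seq_len(n_loaded)  # placement is random, so any subset is
  ld_loaded <- disk_mask(geom$lds[loaded_idx, , drop = FALSE], spec$lds$radius)
  ld_plain <- disk_mask(geom$lds[setdiff(seq_len(n_ld), loaded_idx), , drop = FALSE],
                        spec$lds$radius)
  ld_all <- ld_loaded | ld_plain
  periphery <- disk_mask(geom$lds, spec$lds$radius + spec$periphery_width) &
    !ld_all & cell_mask & !boundary & !nucleus_all

  regions <- list(cell_boundary = boundary,
                  nucleolus = nucleolus_mask,
                  nucleus = nucleus_mask,
                  ld_plain = ld_plain & !boundary,
                  ld_loaded = ld_loaded & !boundary,
                  ld_periphery = periphery)
  taken <- boundary | nucleus_all | ld_all | periphery
  for (pn in names(spec$pockets)) {
    pm <- disk_mask(geom$pockets[[pn]], spec$pockets[[pn]]$radius) &
      cell_mask & !taken
    regions[[paste0("pocket_", pn)]] <- pm
    taken <- taken | pm
  }
  regions$cytoplasm <- cell_mask & !taken

  masks <- lapply(spec$classes, function(cl) {
    if (is.null(regions[[cl$region]])) {
      stop("unknown region '", cl$region, "' in class definition", call. = FALSE)
    }
    regions[[cl$region]]
  })
  names(masks) <- names(spec$classes)
  structure(list(masks = masks, geometry = geom, spec = spec),
            class = "ground_truth")
}

#' Analytic (noiseless) class spectra of a scene
#'
#' @param spec A [scene_spec()].
#' @param axis Wavenumber axis to evaluate on.
#' @return Matrix, length(axis) x classes.
#' @export
class_spectra <- function(spec, axis) {
  refs <- builtin_references()
  out <- matrix(0, length(axis), length(spec$classes),
                dimnames = list(NULL, names(spec$classes)))
  for (j in seq_along(spec$classes)) {
    w <- spec$classes[[j]]$weights
    for (comp in names(w)) {
      if (is.null(refs[[comp]])) {
        stop("unknown reference component '", comp, "'", call. = FALSE)
      }
      out[, j] <- out[, j] + w[[comp]] * eval_reference_raw(refs[[comp]], axis)
    }
  }
  out
}

#' Apply the simulator noise model to non-negative intensities
#'
#' Poisson-scaled shot noise (`x -> rpois(x / p) * p`) plus additive
#' Gaussian noise, clipped at zero to keep SRS intensities physical.
#'
#' @param x Numeric vector/matrix/array of analytic intensities, >= 0.
#' @param noise List `list(gaussian_sd, poisson_scale)` or `NULL` (identity).
#' @param seed Integer seed.
#' @return Same shape as `x`.
#' @export
apply_noise <- function(x, noise, seed) {
  if (is.null(noise)) return(x)
  withr::with_seed(as.integer(seed), {
    y <- x
    p <- noise$poisson_scale
    if (!is.null(p) && p > 0) {
      y[] <- stats::rpois(length(x), as.numeric(x) / p) * p
    }
    sd <- noise$gaussian_sd
    if (!is.null(sd) && sd > 0) {
      y[] <- y + stats::rnorm(length(x), 0, sd)
    }
    y[y < 0] <- 0
    y
  })
}

#' Render a scene into hyperspectral stacks
#'
#' Evaluates each class's analytic composite spectrum on every window of the
#' scan plan (frames in acquisition order, descending wavenumber), paints it
#' onto the class mask, and applies the seeded noise model per window
#' (sub-seed = scene seed + window index). Pixels outside the cell are
#' signal-free (noise only).
#'
#' @param truth A `ground_truth` from [build_scene()].
#' @param spec The generating [scene_spec()].
#' @param plan A [scan_plan()].
#' @return List of [hyperstack()]s, one per window.
#' @export
render_stack <- function(truth, spec, plan = scan_plan()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "scene_spec"),
            inherits(plan, "scan_plan"))
  npix <- spec$rows * spec$cols
  out <- vector("list", nrow(plan))
  for (w in seq_len(nrow(plan))) {
    values <- seq(plan$hi[w], plan$lo[w], length.out = plan$frames[w])
    spectra <- class_spectra(spec, values)
    m <- matrix(0, npix, plan$frames[w])
    for (j in seq_along(truth$masks)) {
      idx <- which(truth$masks[[j]])
      if (length(idx) > 0L) {
        m[idx, ] <- matrix(spectra[, j], length(idx), plan$frames[w], byrow = TRUE)
      }
    }
    m <- apply_noise(m, spec$noise, spec$seed + w)
    axis <- wavenumber_axis(values, rep(w - 1L, plan$frames[w]), step_nm = 0.4)
    out[[w]] <- hyperstack(array(m, c(spec$rows, spec$cols, plan$frames[w])),
                           axis)
  }
  out
}

#' Packaged scene presets
#'
#' Returns the study scenes:
#' \describe{
#'   \item{triplex_crsan}{The headline triplex scene: six label-free
#'     compartments (nucleus, nucleolus, cytoplasm, LDs, LD periphery, cell
#'     boundary) plus a metallacarborane (CrSAN) distributed through the
#'     cytoplasm with weak nuclear association and dense cytoplasmic
#'     accumulations (class G), LDs co-loaded with stearic acid-d35 and the
#'     AM-ester butadiyne (class H), and AM-ester-dominated cytoplasmic
#'     pockets (class I) — nine classes in total.}
#'   \item{singleplex_fesan}{Six label-free compartments plus FeSAN in the
#'     cytoplasm and nucleolus — seven classes.}
#'   \item{triplex_imidazole}{As the triplex scene but with the pan-cellular
#'     imidazole butadiyne (present in nucleus and nucleolus too) replacing
#'     the AM-ester.}
#' }
#' Each preset records its matching scan plan in `$default_plan`.
#'
#' @param name Optional preset name; omit to get the full named list.
#' @return A `scene_spec` (or named list of them).
#' @export
scene_presets <- function(name = NULL) {
  wts <- function(...) c(...)
  base_classes <- function(probe, nuc_amp, cyto_amp) {
    # probe amplitudes multiply the RIE-scaled reference spectra, i.e. they
    # play the role of local concentrations
    list(
      nucleus = list(region = "nucleus",
                     weights = wts(protein_ch3 = 1.0, lipid_ch2 = 0.25,
                                   stats::setNames(nuc_amp, probe))),
      nucleolus = list(region = "nucleolus",
                       weights = wts(protein_ch3 = 1.5, lipid_ch2 = 0.15,
                                     stats::setNames(nuc_amp, probe))),
      cytoplasm = list(region = "cytoplasm",
                       weights = wts(protein_ch3 = 0.7, lipid_ch2 = 0.55,
                                     stats::setNames(cyto_amp, probe))))
  }
  triplex <- function(alkyne) {
    cls <- c(base_classes("metallacarborane", 0.15, 0.5),
      list(
        lipid_droplet = list(region = "ld_plain",
                             weights = wts(protein_ch3 = 0.15, lipid_ch2 = 1.5)),
        ld_periphery = list(region = "ld_periphery",
                            weights = wts(protein_ch3 = 0.45, lipid_ch2 = 1.0)),
        cell_boundary = list(region = "cell_boundary",
                             weights = wts(protein_ch3 = 0.75, lipid_ch2 = 0.85)),
        crsan = list(region = "pocket_crsan",
                     weights = wts(protein_ch3 = 0.7, lipid_ch2 = 0.55,
                                   metallacarborane = 1.5)),
        stearic_am_coloc = list(region = "ld_loaded",
                                weights = wts(protein_ch3 = 0.15, lipid_ch2 = 1.5,
                                              stearic_d35 = 0.55,
                                              stats::setNames(0.35, alkyne))),
        am_pocket = list(region = "pocket_am",
                         weights = wts(protein_ch3 = 0.7, lipid_ch2 = 0.55,
                                       metallacarborane = 0.15,
                                       stats::setNames(0.6, alkyne)))))
    # A-I display order
    cls[c("nucleus", "nucleolus", "cytoplasm", "lipid_droplet", "ld_periphery",
          "cell_boundary", "crsan", "stearic_am_coloc", "am_pocket")]
  }
  tri_cr <- scene_spec(
    pockets = list(crsan = list(n = 4L, radius = 8),
                   am = list(n = 3L, radius = 6)),
    classes = triplex("am_ester"))
  tri_cr$default_plan <- scan_plan()

  tri_im_classes <- triplex("imidazole")
  # pan-cellular imidazole, including the nuclei
  for (cl in c("nucleus", "nucleolus", "cytoplasm")) {
    tri_im_classes[[cl]]$weights <- c(tri_im_classes[[cl]]$weights,
                                      imidazole = 0.25)
  }
  tri_im <- scene_spec(
    pockets = list(crsan = list(n = 4L, radius = 8),
                   am = list(n = 3L, radius = 6)),
    classes = tri_im_classes)
  tri_im$default_plan <- scan_plan()

  single_classes <- c(base_classes("metallacarborane", 0, 0.4),
    list(
      lipid_droplet = list(region = "ld_plain",
                           weights = wts(protein_ch3 = 0.15, lipid_ch2 = 1.5)),
      ld_periphery = list(region = "ld_periphery",
                          weights = wts(protein_ch3 = 0.45, lipid_ch2 = 1.0)),
      cell_boundary = list(region = "cell_boundary",
                           weights = wts(protein_ch3 = 0.75, lipid_ch2 = 0.85)),
      fesan = list(region = "pocket_fesan",
                   weights = wts(protein_ch3 = 0.7, lipid_ch2 = 0.55,
                                 metallacarborane = 1.2))))
  # FeSAN localises to cytoplasm and nucleolus
  single_classes$nucleolus$weights["metallacarborane"] <- 0.4
  single_classes <- single_classes[c("nucleus", "nucleolus", "cytoplasm",
                                     "lipid_droplet", "ld_periphery",
                                     "cell_boundary", "fesan")]
  single <- scene_spec(
    lds = list(n = 14L, radius = 4.5, n_loaded = 0L),
    pockets = list(fesan = list(n = 4L, radius = 8)),
    classes = single_classes)
  single$default_plan <- scan_plan(lo = c(2800, 2450), hi = c(3050, 2650),
                                   frames = c(40L, 35L))

  presets <- list(triplex_crsan = tri_cr, singleplex_fesan = single,
                  triplex_imidazole = tri_im)
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown scene preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Write a rendered scene to disk
#'
#' Emits one TIFF + JSON stack per window, the ground-truth masks as a
#' multi-page TIFF with a JSON name map, and the fully-resolved scene
#' specification as YAML for provenance.
#'
#' @param truth A `ground_truth`.
#' @param stacks List of [hyperstack()]s from [render_stack()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of written paths.
#' @export
write_scene <- function(truth, stacks, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (w in seq_along(stacks)) {
    sp <- file.path(out_dir, sprintf("window_%02d.tif", w))
    ap <- file.path(out_dir, sprintf("window_%02d.json", w))
    write_stack(stacks[[w]], sp, ap)
    paths[[length(paths) + 1L]] <- sp
  }
  mt <- file.path(out_dir, "truth_masks.tif")
  tiff::writeTIFF(lapply(truth$masks, function(m) m * 1), mt,
                  bits.per.sample = 8L)
  jsonlite::write_json(list(classes = names(truth$masks)),
                       file.path(out_dir, "truth_masks.json"),
                       auto_unbox = FALSE)
  spec_plain <- truth$spec
  spec_plain$classes <- lapply(spec_plain$classes, function(cl) {
    cl$weights <- as.list(cl$weights); cl
  })
  yaml::write_yaml(unclass_deep(spec_plain), file.path(out_dir, "scene_spec.yaml"))
  invisible(paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Read ground-truth masks written by [write_scene()]
#'
#' @param out_dir Directory containing `truth_masks.tif` / `.json`.
#' @return Named list of logical matrices.
#' @export
read_truth_masks <- function(out_dir) {
  pages <- tiff::readTIFF(file.path(out_dir, "truth_masks.tif"), all = TRUE)
  meta <- jsonlite::read_json(file.path(out_dir, "truth_masks.json"),
                              simplifyVector = TRUE)
  masks <- lapply(pages, function(p) p > 0.5)
  names(masks) <- meta$classes
  masks
}
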