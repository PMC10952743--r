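#' A polygonal gate in phasor space
#'
#' A named, simple (non-self-intersecting) polygon in the (G, S) plane.
#' Pixels whose phasor falls inside the polygon (boundary included) belong
#' to the gate's segment; where gates overlap, the gate with the highest
#' priority wins.
#'
#' @param name Segment name.
#' @param polygon Numeric matrix with >= 3 rows and columns (G, S).
#' @param priority Integer; higher priority wins overlaps.
#' @param color Hex colour used in composites.
#' @return A `phasor_gate`.
#' @export
phasor_gate <- function(name, polygon, priority = 1L, color = "#FFFFFF") {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("gate polygon needs >= 3 vertices with (G, S) columns", call. = FALSE)
  }
  if (polygon_self_intersects(polygon)) {
    stop("gate polygon must be simple (non-self-intersecting)", call. = FALSE)
  }
  structure(list(name = as.character(name), polygon = unname(polygon),
                 priority = as.integer(priority), color = as.character(color)),
            class = "phasor_gate")
}

# Segment-intersection test between non-adjacent polygon edges.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3L) return(FALSE)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

validate_gates <- function(gates) {
  stopifnot(length(gates) >= 1L, all(vapply(gates, inherits, TRUE, "phasor_gate")))
  nm <- vapply(gates, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate gate names", call. = FALSE)
  pr <- vapply(gates, function(g) g$priority, integer(1))
  if (anyDuplicated(pr)) stop("gate priorities must be unique", call. = FALSE)
  invisible(gates)
}

#' Back-map phasor gates to an image segmentation
#'
#' Labels each valid pixel by the highest-priority gate polygon containing
#' its (G, S) point (boundary counts as inside); pixels in no gate, and
#' invalid pixels, get label 0. Gate i in the input list produces label i.
#'
#' @param field A `phasor_field`.
#' @param gates List of [phasor_gate()]s with unique names and priorities.
#' @return A [segment_label_image()].
#' @export
gate_segment <- function(field, gates) {
  stopifnot(inherits(field, "phasor_field"))
  validate_gates(gates)
  labels <- matrix(0L, nrow(field$G), ncol(field$G))
  idx <- which(field$valid_mask)
  g <- field$G[idx]
  s <- field$S[idx]
  assigned <- integer(length(idx))
  # ascending priority, so later (higher-priority) gates overwrite
  for (i in order(vapply(gates, function(x) x$priority, integer(1)))) {
    poly <- gates[[i]]$polygon
    inside <- pracma::inpolygon(g, s, poly[, 1], poly[, 2], boundary = TRUE)
    assigned[inside] <- i
  }
  labels[idx] <- assigned
  segment_label_image(labels,
                      vapply(gates, function(x) x$name, character(1)),
                      vapply(gates, function(x) x$color, character(1)))
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to squared distance
# to the nearest chosen center.
kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(0, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1L), ]
  d2 <- rowSums((pts - matrix(centers[1, ], n, ncol(pts), byrow = TRUE))^2)
  if (k > 1L) for (i in 2:k) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[i, ] <- pts[pick, ]
    d2 <- pmin(d2, rowSums((pts - matrix(centers[i, ], n, ncol(pts), byrow = TRUE))^2))
  }
  centers
}

#' Automatic phasor-plot gating by seeded k-means
#'
#' Partitions the valid-pixel (G, S) cloud into k clusters (k-means with
#' k-means++ initialisation under a fixed seed, making the otherwise manual
#' phasor gating reproducible) and returns each cluster as the convex hull
#' of its member points. Gates are ordered by descending member count;
#' priorities increase along that order so that smaller clusters win any
#' hull overlap.
#'
#' @param field A `phasor_field`.
#' @param k Number of clusters, >= 1.
#' @param seed Integer RNG seed.
#' @param nstart Number of k-means++ restarts; the best (lowest within-SS)
#'   solution is kept.
#' @return List of [phasor_gate()]s.
#' @export
auto_cluster <- function(field, k, seed = 1L, nstart = 10L) {
  stopifnot(inherits(field, "phasor_field"), k >= 1L)
  pts <- cbind(field$G[field$valid_mask], field$S[field$valid_mask])
  if (nrow(pts) < k) stop("fewer valid pixels than clusters", call. = FALSE)
  if (nrow(unique(pts)) < k) {
    stop("fewer distinct phasor points than clusters; clustering is degenerate",
         call. = FALSE)
  }
  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(nstart)) {
      f <- suppressWarnings(
        stats::kmeans(pts, centers = kmeanspp_centers(pts, k), iter.max = 100L))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  sizes <- tabulate(fit$cluster, k)
  ord <- order(sizes, decreasing = TRUE)
  palette <- grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
  gates <- vector("list", k)
  for (j in seq_len(k)) {
    members <- pts[fit$cluster == ord[j], , drop = FALSE]
    gates[[j]] <- phasor_gate(sprintf("cluster_%02d", j),
                              convex_hull_polygon(members),
                              priority = j, color = palette[j])
  }
  gates
}

# Convex hull of a point set as a polygon matrix; degenerate (collinear or
# single-point) sets are padded to a thin box so the polygon stays valid.
convex_hull_polygon <- function(pts) {
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[hull, , drop = FALSE]
  if (nrow(poly) < 3L) {
    eps <- 1e-9
    lo <- apply(pts, 2, min) - eps
    hi <- apply(pts, 2, max) + eps
    poly <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]), c(hi[1], hi[2]), c(lo[1], hi[2]))
  }
  poly
}

#' Per-segment mean spectra
#'
#' Averages the member-pixel spectra of each segment of a label image over
#' a stack with the same image dimensions, and min-max normalises a copy of
#' each mean to \[0, 1\]. Empty segments are reported with pixel count 0 and
#' NA spectra rather than dropped.
#'
#' @param stack A [hyperstack()].
#' @param labels A [segment_label_image()] with matching dimensions.
#' @return A `segment_spectra` object: `wavenumbers`, `names`,
#'   `pixel_count`, `mean` and `normalized` (wavenumber x segment matrices).
#' @export
segment_spectra <- function(stack, labels) {
  stopifnot(inherits(stack, "hyper_stack"),
            inherits(labels, "segment_label_image"))
  d <- dim(stack$intensities)
  if (!all(dim(labels$labels) == d[1:2])) {
    stop("stack and label image dimensions differ", call. = FALSE)
  }
  k <- length(labels$names)
  p <- matrix(stack$intensities, d[1] * d[2], d[3])
  lab <- as.integer(labels$labels)
  counts <- tabulate(lab[lab > 0L], k)
  mean_mat <- matrix(NA_real_, d[3], k, dimnames = list(NULL, labels$names))
  norm_mat <- mean_mat
  for (j in seq_len(k)) {
    if (counts[j] == 0L) next
    m <- colMeans(p[lab == j, , drop = FALSE])
    mean_mat[, j] <- m
    rng <- range(m)
    norm_mat[, j] <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  }
  structure(list(wavenumbers = stack$axis$values, names = labels$names,
                 pixel_count = stats::setNames(counts, labels$names),
                 mean = mean_mat, normalized = norm_mat),
            class = "segment_spectra")
}

#' Write segment spectra as CSV (one row per wavenumber, one column per segment)
#'
#' @param spectra A `segment_spectra`.
#' @param path Output CSV path.
#' @param normalized Write the 0-1 normalised spectra (default) or raw means.
#' @export
write_segment_spectra_csv <- function(spectra, path, normalized = TRUE) {
  stopifnot(inherits(spectra, "segment_spectra"))
  m <- if (normalized) spectra$normalized else spectra$mean
  df <- data.frame(wavenumber_cm1 = spectra$wavenumbers, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}

#' Match recovered segments to ground-truth classes
#'
#' Computes the IoU (intersection over union) between every recovered
#' segment and every ground-truth class mask, then finds the one-to-one
#' assignment maximising total IoU (Hungarian algorithm). A class counts as
#' recovered when its matched IoU reaches `iou_threshold`.
#'
#' @param labels A [segment_label_image()].
#' @param truth_masks Named list of logical matrices (one per class).
#' @param iou_threshold Recovery threshold (default 0.5).
#' @return A `segment_matching` list: `table` (data.frame with class,
#'   matched segment, IoU, recovered flag), `n_matched`, `iou_threshold`.
#' @export
match_segments <- function(labels, truth_masks, iou_threshold = 0.5) {
  stopifnot(inherits(labels, "segment_label_image"))
  stopifnot(all(vapply(truth_masks, function(m) all(dim(m) == dim(labels$labels)),
                       TRUE)))
  k_rec <- length(labels$names)
  k_true <- length(truth_masks)
  iou <- matrix(0, k_true, k_rec,
                dimnames = list(names(truth_masks), labels$names))
  for (i in seq_len(k_true)) {
    tm <- truth_masks[[i]]
    for (j in seq_len(k_rec)) {
      rm <- labels$labels == j
      inter <- sum(tm & rm)
      union <- sum(tm | rm)
      iou[i, j] <- if (union > 0) inter / union else 0
    }
  }
  n <- max(k_true, k_rec)
  cost <- matrix(0, n, n)
  cost[seq_len(k_true), seq_len(k_rec)] <- iou
  assignment <- as.integer(clue::solve_LSAP(cost, maximum = TRUE))
  matched_seg <- assignment[seq_len(k_true)]
  matched_iou <- iou[cbind(seq_len(k_true), pmin(matched_seg, k_rec))]
  matched_iou[matched_seg > k_rec] <- 0
  tab <- data.frame(
    class = names(truth_masks),
    segment = ifelse(matched_seg > k_rec, NA_character_,
                     labels$names[matched_seg]),
    iou = matched_iou,
    recovered = matched_iou >= iou_threshold,
    stringsAsFactors = FALSE)
  structure(list(table = tab, iou_matrix = iou,
                 n_matched = sum(tab$recovered),
                 iou_threshold = iou_threshold),
            class = "segment_matching")
}

#' @export
print.segment_matching <- function(x, ...) {
  cat(sprintf("<segment_matching> %d/%d classes recovered at IoU >= %.2f\n",
              x$n_matched, nrow(x$table), x$iou_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Render a segment label image as an RGB composite
#'
#' Each segment is painted in its gate colour on a black background,
#' optionally modulated by a total-intensity image (average-intensity-
#' projection style display).
#'
#' @param labels A [segment_label_image()].
#' @param total_intensity Optional non-negative matrix used to modulate
#'   brightness (scaled by its maximum).
#' @return rows x cols x 3 numeric array in \[0, 1\].
#' @export
render_composite <- function(labels, total_intensity = NULL) {
  stopifnot(inherits(labels, "segment_label_image"))
  d <- dim(labels$labels)
  rgb_of <- t(grDevices::col2rgb(labels$colors) / 255)
  img <- array(0, c(d, 3L))
  lab <- labels$labels
  for (ch in 1:3) {
    plane <- matrix(0, d[1], d[2])
    nz <- lab > 0L
    plane[nz] <- rgb_of[lab[nz], ch]
    img[, , ch] <- plane
  }
  if (!is.null(total_intensity)) {
    m <- max(total_intensity)
    if (m > 0) {
      w <- total_intensity / m
      for (ch in 1:3) img[, , ch] <- img[, , ch] * w
    }
  }
  img
}

#' Write an RGB composite to PNG
#'
#' @param img rows x cols x 3 array in \[0, 1\] from [render_composite()].
#' @param path Output PNG path.
#' @export
write_composite_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(NULL)
}
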