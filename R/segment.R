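#' Analysis settings for vesicle-style (TF-mode) cilium detection
#'
#' TF mode mirrors dot/vesicle-counting high-content analysis: cilium
#' objects are connected regions of the cilia channel (W2) above a fixed
#' intensity threshold whose longest axis falls inside a physical size
#' band. Published settings for ciliary reporter lines put the minimum
#' object size at 1--2 um and the maximum at 8--11 um, with the intensity
#' threshold tuned per cell line on the starved-vehicle vs serum controls;
#' the defaults here sit inside those ranges on the 16-bit scale.
#'
#' @param cilia_intensity_threshold W2 threshold, raw 16-bit scale
#'   (default `intensity_8bit(78)`).
#' @param min_size_um,max_size_um Size band (longest axis, micrometres) for
#'   retained cilium objects.
#' @param nuclei_threshold W1 threshold for nucleus segmentation.
#' @param nucleus_min_area_um2,nucleus_max_area_um2 Area band for nuclei;
#'   components above the maximum are watershed-split before re-filtering.
#' @param size_measure `"feret"` (max Feret / longest-axis, the default) or
#'   `"equivalent_diameter"` (`2 * sqrt(area / pi)`).
#' @param include_border Keep objects touching the field border (default
#'   `TRUE`; excluding them biases counts low at field edges).
#' @param auto_threshold If `TRUE`, replace `cilia_intensity_threshold` by
#'   an Otsu threshold computed per field (off by default; fixed global
#'   settings match the settings-driven screening workflow).
#' @return An object of class `tf_params`.
#' @examples
#' tf_params(min_size_um = 1, max_size_um = 11)
#' @export
tf_params <- function(cilia_intensity_threshold = intensity_8bit(78),
                      min_size_um = 1.5, max_size_um = 10,
                      nuclei_threshold = 4000,
                      nucleus_min_area_um2 = 20, nucleus_max_area_um2 = 100,
                      size_measure = c("feret", "equivalent_diameter"),
                      include_border = TRUE, auto_threshold = FALSE) {
  size_measure <- match.arg(size_measure)
  stopifnot(
    cilia_intensity_threshold > 0, nuclei_threshold > 0,
    min_size_um > 0, min_size_um < max_size_um,
    nucleus_min_area_um2 > 0, nucleus_min_area_um2 < nucleus_max_area_um2
  )
  structure(
    list(cilia_intensity_threshold = cilia_intensity_threshold,
         min_size_um = min_size_um, max_size_um = max_size_um,
         nuclei_threshold = nuclei_threshold,
         nucleus_min_area_um2 = nucleus_min_area_um2,
         nucleus_max_area_um2 = nucleus_max_area_um2,
         size_measure = size_measure,
         include_border = include_border,
         auto_threshold = auto_threshold),
    class = "tf_params"
  )
}

#' Analysis settings for stained-area (MWS-mode) scoring
#'
#' MWS mode scores the cilia channel by stained area rather than object
#' counts: W2 objects passing a minimum intensity, a size band and a
#' minimum stained area contribute to `positive_stained_area`, and each
#' cell owning at least one retained object counts toward
#' `pct_positive_w2`. Published settings put the minimum size at
#' 1--1.8 um, the maximum at 5--10 um, the minimum intensity between 78
#' and 150 (8-bit convention) and the minimum stained area between 1.5 and
#' 3; defaults sit inside those ranges. The stained-area unit is
#' micrometres squared by default (configurable to pixels squared, since
#' the convention varies between analysis packages).
#'
#' @param min_size_um,max_size_um Size band (longest axis, micrometres).
#' @param min_intensity W2 threshold, raw 16-bit scale.
#' @param min_stained_area Minimum per-object stained area.
#' @param stained_area_unit `"um2"` (default) or `"px2"`.
#' @return An object of class `mws_params`.
#' @export
mws_params <- function(min_size_um = 1.4, max_size_um = 7.5,
                       min_intensity = intensity_8bit(78),
                       min_stained_area = 1.5,
                       stained_area_unit = c("um2", "px2")) {
  stained_area_unit <- match.arg(stained_area_unit)
  stopifnot(min_size_um > 0, min_size_um < max_size_um,
            min_intensity > 0, min_stained_area >= 0)
  structure(
    list(min_size_um = min_size_um, max_size_um = max_size_um,
         min_intensity = min_intensity,
         min_stained_area = min_stained_area,
         stained_area_unit = stained_area_unit),
    class = "mws_params"
  )
}

# Fraction of pixels above threshold at which a channel is declared
# saturated/unusable.
SATURATION_FRACTION <- 0.99

# ---- connected components --------------------------------------------------

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged by union-find over the label adjacency graph.
label_components <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  k <- max(lab)
  if (k < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  sel <- a > 0 & b > 0 & a != b
  e1 <- cbind(a[sel], b[sel])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  sel <- a > 0 & b > 0 & a != b
  edges <- rbind(e1, cbind(a[sel], b[sel]))
  if (nrow(edges) == 0) return(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, numeric(1))
  newid <- match(root, sort(unique(root)))
  fg <- lab > 0
  lab[fg] <- newid[lab[fg]]
  lab
}

# Longest axis (max Feret diameter) of a pixel set, in pixels. Computed as
# the maximum pairwise distance between pixel centers on the convex hull,
# plus one pixel for the finite pixel extent (a single pixel has Feret 1).
feret_px <- function(rows, cols) {
  n <- length(rows)
  if (n == 1) return(1)
  pts <- cbind(cols, rows)
  if (n > 3) {
    h <- tryCatch(grDevices::chull(pts), error = function(e) seq_len(n))
    if (length(h) >= 2) pts <- pts[h, , drop = FALSE]
  }
  d2 <- 0
  m <- nrow(pts)
  for (i in seq_len(m - 1)) {
    di <- (pts[(i + 1):m, 1] - pts[i, 1])^2 + (pts[(i + 1):m, 2] - pts[i, 2])^2
    d2 <- max(d2, di)
  }
  sqrt(d2) + 1
}

# Per-object measurements from a labeled matrix.
measure_objects <- function(lab, intensity, pixel_size_um) {
  fg <- which(lab > 0)
  if (!length(fg)) {
    return(tibble(label = integer(0), area_um2 = numeric(0),
                  feret_um = numeric(0), equiv_diameter_um = numeric(0),
                  x = numeric(0), y = numeric(0),
                  mean_intensity = numeric(0), on_border = logical(0)))
  }
  l <- as.integer(lab[fg])
  idx <- arrayInd(fg, dim(lab))
  rows <- idx[, 1]; cols <- idx[, 2]
  by_label <- split(seq_along(l), l)
  labels <- as.integer(names(by_label))
  npx <- lengths(by_label)
  px2 <- pixel_size_um^2
  nr <- nrow(lab); nc <- ncol(lab)
  feret <- vapply(by_label, function(ii) feret_px(rows[ii], cols[ii]), numeric(1))
  cx <- vapply(by_label, function(ii) mean(cols[ii]), numeric(1))
  cy <- vapply(by_label, function(ii) mean(rows[ii]), numeric(1))
  mi <- if (is.null(intensity)) rep(NA_real_, length(labels)) else {
    iv <- intensity[fg]
    vapply(by_label, function(ii) mean(iv[ii]), numeric(1))
  }
  border <- vapply(by_label, function(ii) {
    any(rows[ii] == 1L | rows[ii] == nr | cols[ii] == 1L | cols[ii] == nc)
  }, logical(1))
  tibble(
    label = labels,
    area_um2 = unname(npx * px2),
    feret_um = unname(feret * pixel_size_um),
    equiv_diameter_um = unname(2 * sqrt(npx * px2 / pi)),
    x = unname((cx - 0.5) * pixel_size_um),
    y = unname((cy - 0.5) * pixel_size_um),
    mean_intensity = unname(mi),
    on_border = unname(border)
  )
}

channel_saturated <- function(img, threshold) {
  mean(img > threshold) >= SATURATION_FRACTION
}

# ---- nuclei ----------------------------------------------------------------

#' Segment nuclei in the W1 channel
#'
#' Thresholds W1 at `nuclei_threshold`, labels 8-connected components,
#' watershed-splits components whose area exceeds the single-nucleus
#' maximum (touching blobs), and retains components within the nucleus area
#' band. A field whose W1 channel is saturated (at least 99% of pixels
#' above threshold) is flagged unusable rather than counted.
#'
#' @param field A `field_image` (see [generate_field()]).
#' @param params A [tf_params()] object.
#' @return A list with `mask` (labeled matrix of retained nuclei),
#'   `nuclei_count`, `centroids` (tibble, micrometres), `usable`, `reason`.
#' @export
segment_nuclei <- function(field, params = tf_params()) {
  stopifnot(inherits(field, "field_image"), !is.null(field$w1))
  img <- field$w1
  px <- field$pixel_size_um
  if (channel_saturated(img, params$nuclei_threshold)) {
    return(list(mask = matrix(0, nrow(img), ncol(img)), nuclei_count = NA_integer_,
                centroids = tibble(x = numeric(0), y = numeric(0)),
                usable = FALSE, reason = "W1 saturated"))
  }
  mask <- img > params$nuclei_threshold
  lab <- label_components(mask)
  px2 <- px^2
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * px2
    over <- which(areas > params$nucleus_max_area_um2)
    if (length(over)) {
      sub <- matrix(lab %in% over, nrow(lab), ncol(lab))
      dm <- EBImage::distmap(sub)
      ws <- EBImage::imageData(EBImage::watershed(dm))
      lab[sub] <- ws[sub] + max(lab)
    }
    keep_fg <- lab > 0
    if (any(keep_fg)) {
      areas <- tabulate(lab[keep_fg], nbins = max(lab)) * px2
      ok <- which(areas >= params$nucleus_min_area_um2 &
                    areas <= params$nucleus_max_area_um2)
      newid <- rep(0, max(lab))
      newid[ok] <- seq_along(ok)
      lab[keep_fg] <- newid[lab[keep_fg]]
    }
  }
  objs <- measure_objects(lab, NULL, px)
  list(mask = lab, nuclei_count = nrow(objs),
       centroids = objs[, c("x", "y")], usable = TRUE, reason = NA_character_)
}

# ---- TF-mode cilium detection ---------------------------------------------

#' Detect cilium objects in the W2 channel (TF mode)
#'
#' Connected regions of W2 above the intensity threshold whose longest axis
#' lies inside `[min_size_um, max_size_um]` are retained as cilium objects
#' ("vesicles" in dot-counting terminology). Size is the maximum Feret
#' diameter by default: cilia are elongated, so the longest axis is the
#' measure the published 1--2 um minima and 8--11 um maxima refer to.
#' Objects touching the field border are retained (configurable) when their
#' visible extent passes the filters.
#'
#' @inheritParams segment_nuclei
#' @return A tibble of retained objects (`label`, `area_um2`, `feret_um`,
#'   `equiv_diameter_um`, centroid `x`/`y` in micrometres,
#'   `mean_intensity`, `on_border`), with attributes `usable` (logical) and
#'   `reason`.
#' @export
detect_cilia_tf <- function(field, params = tf_params()) {
  stopifnot(inherits(field, "field_image"), !is.null(field$w2))
  img <- field$w2
  px <- field$pixel_size_um
  thr <- params$cilia_intensity_threshold
  if (isTRUE(params$auto_threshold)) {
    thr <- EBImage::otsu(EBImage::Image(img / 65535), range = c(0, 1)) * 65535
  }
  empty <- measure_objects(matrix(0, 1, 1), NULL, px)[0, ]
  if (channel_saturated(img, thr)) {
    attr(empty, "usable") <- FALSE
    attr(empty, "reason") <- "W2 saturated"
    return(empty)
  }
  lab <- label_components(img > thr)
  objs <- measure_objects(lab, img, px)
  size <- if (params$size_measure == "feret") objs$feret_um else objs$equiv_diameter_um
  keep <- size >= params$min_size_um & size <= params$max_size_um
  if (!params$include_border) keep <- keep & !objs$on_border
  out <- objs[keep, , drop = FALSE]
  attr(out, "usable") <- TRUE
  attr(out, "reason") <- NA_character_
  out
}

# ---- MWS-mode scoring ------------------------------------------------------

#' Score the W2 channel by stained area and percent positive cells (MWS mode)
#'
#' Segments W2 objects by minimum intensity, size band and minimum stained
#' area, then reports the total retained stained area, the percentage of
#' cells owning at least one retained object (`pct_positive_w2`) and the
#' mean stained area per retained object. An object belongs to the nucleus
#' whose territory contains its centroid; territories are the
#' nearest-nucleus (Voronoi) partition of the field, the practical
#' equivalent of watershed expansion from nucleus seeds.
#'
#' @inheritParams segment_nuclei
#' @param nuclei Result of [segment_nuclei()] on the same field.
#' @param params An [mws_params()] object.
#' @return A one-row tibble: `positive_stained_area`, `pct_positive_w2`,
#'   `mean_stain_area`, `n_objects`, `usable`.
#' @export
score_mws <- function(field, nuclei, params = mws_params()) {
  stopifnot(inherits(field, "field_image"), !is.null(field$w2))
  px <- field$pixel_size_um
  img <- field$w2
  flagged <- function(reason) {
    tibble(positive_stained_area = NA_real_, pct_positive_w2 = NA_real_,
           mean_stain_area = NA_real_, n_objects = NA_integer_,
           usable = FALSE, reason = reason)
  }
  if (!isTRUE(nuclei$usable)) return(flagged(nuclei$reason))
  if (channel_saturated(img, params$min_intensity)) return(flagged("W2 saturated"))
  lab <- label_components(img > params$min_intensity)
  objs <- measure_objects(lab, img, px)
  min_area_um2 <- if (params$stained_area_unit == "um2") {
    params$min_stained_area
  } else {
    params$min_stained_area * px^2
  }
  keep <- objs$feret_um >= params$min_size_um &
    objs$feret_um <= params$max_size_um &
    objs$area_um2 >= min_area_um2
  objs <- objs[keep, , drop = FALSE]
  n_cells <- nuclei$nuclei_count
  if (is.na(n_cells) || n_cells == 0) return(flagged("no nuclei"))
  total <- sum(objs$area_um2)
  n_obj <- nrow(objs)
  pct <- if (n_obj == 0) 0 else {
    cen <- nuclei$centroids
    owner <- vapply(seq_len(n_obj), function(i) {
      which.min((cen$x - objs$x[i])^2 + (cen$y - objs$y[i])^2)
    }, integer(1))
    100 * length(unique(owner)) / n_cells
  }
  tibble(positive_stained_area = total,
         pct_positive_w2 = pct,
         mean_stain_area = if (n_obj > 0) total / n_obj else NA_real_,
         n_objects = n_obj, usable = TRUE, reason = NA_character_)
}
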