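# Independent brute-force oracles and planted-field builders. These are
# deliberately naive implementations (flood fill, all-pairs distances) that
# share no code with the package's segmentation path.

# 8-connected flood-fill labeling.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- cur
      while (nrow(stack) > 0) {
        p <- stack[nrow(stack), ]
        stack <- stack[-nrow(stack), , drop = FALSE]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack <- rbind(stack, c(ii, jj))
          }
        }
      }
    }
  }
  lab
}

# Longest axis of one labeled component by all-pairs pixel-center distance
# (plus one pixel extent), no convex hull involved.
oracle_feret_um <- function(lab, id, pixel_size_um) {
  idx <- which(lab == id, arr.ind = TRUE)
  if (nrow(idx) == 1) return(pixel_size_um)
  d2max <- 0
  for (a in seq_len(nrow(idx) - 1)) {
    d2 <- (idx[(a + 1):nrow(idx), 1] - idx[a, 1])^2 +
      (idx[(a + 1):nrow(idx), 2] - idx[a, 2])^2
    d2max <- max(d2max, max(d2))
  }
  (sqrt(d2max) + 1) * pixel_size_um
}

# Threshold -> flood fill -> measure -> size-filter, entirely brute force.
oracle_detect <- function(w2, threshold, pixel_size_um, min_size_um = -Inf,
                          max_size_um = Inf) {
  lab <- oracle_label(w2 > threshold)
  k <- max(lab)
  if (k == 0) return(list(count = 0L, areas_um2 = numeric(0)))
  areas <- tabulate(lab[lab > 0], nbins = k) * pixel_size_um^2
  feret <- vapply(seq_len(k), function(id) oracle_feret_um(lab, id, pixel_size_um),
                  numeric(1))
  keep <- feret >= min_size_um & feret <= max_size_um
  list(count = sum(keep), areas_um2 = sort(areas[keep]))
}

# A field_image wrapper around raw matrices.
matrix_field <- function(w1, w2, pixel_size_um = 0.325, ...) {
  ciliascreen:::new_field_image("T", "A01", 1L, "IR1", w1, w2, pixel_size_um)
}

# Plant a horizontal bar whose nominal physical length is len_um: occupies
# round(len_um / px) columns and max(1, round(0.5 / px)) rows.
plant_bar_um <- function(mat, row, col, len_um, pixel_size_um, value = 30000) {
  n <- max(1L, round(len_um / pixel_size_um))
  w <- max(1L, round(0.5 / pixel_size_um))
  mat[row:(row + w - 1L), col:(col + n - 1L)] <- value
  mat
}

# A reproducible random planted W2 field: bars and square blobs on a jittered
# grid so objects never touch; returns the matrix (binary-valued).
planted_w2 <- function(seed, nr = 128, nc = 128, value = 30000) {
  set.seed(seed)
  m <- matrix(0, nr, nc)
  pitch <- 24
  for (gi in seq(4, nr - 20, by = pitch)) {
    for (gj in seq(4, nc - 20, by = pitch)) {
      if (runif(1) < 0.3) next
      i <- gi + sample(0:4, 1); j <- gj + sample(0:4, 1)
      if (runif(1) < 0.5) {
        len <- sample(3:14, 1)
        m[i:(i + 1), j:(j + len - 1)] <- value
      } else {
        sz <- sample(2:6, 1)
        m[i:(i + sz - 1), j:(j + sz - 1)] <- value
      }
    }
  }
  m
}

# Fabricated segment_nuclei-style result for metric tests.
fake_nuclei <- function(n, usable = TRUE) {
  k <- if (is.na(n)) 0L else n
  list(mask = NULL, nuclei_count = n,
       centroids = tibble::tibble(x = seq_len(k) * 10, y = seq_len(k) * 10),
       usable = usable, reason = NA_character_)
}

# Fabricated TF detection table with given per-object areas.
fake_cilia <- function(areas_um2) {
  tbl <- tibble::tibble(
    label = seq_along(areas_um2), area_um2 = areas_um2,
    feret_um = sqrt(areas_um2) * 2, equiv_diameter_um = sqrt(areas_um2),
    x = seq_along(areas_um2) * 5, y = seq_along(areas_um2) * 5,
    mean_intensity = 30000, on_border = FALSE
  )
  attr(tbl, "usable") <- TRUE
  tbl
}

# Metric-level site tibble for screen tests: one row per site with a given
# vesicle_count_per_cell (nuclei fixed at 50).
fake_sites <- function(well_id, run_index, vcpc, plate_id = "P1",
                       nuclei = 50, area = 100) {
  n <- length(vcpc)
  tibble::tibble(
    plate_id = plate_id, well_id = well_id, site_index = seq_len(n),
    run_index = run_index, nuclei_count = nuclei,
    vesicle_count = round(vcpc * nuclei),
    vesicle_count_per_cell = vcpc,
    total_vesicle_area_um2 = area * vcpc,
    vesicle_area_per_cell = area * vcpc / nuclei,
    pct_positive_w2 = 100 * vcpc, positive_stained_area = area * vcpc,
    mean_stain_area = 2, usable = TRUE
  )
}
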