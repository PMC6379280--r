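#' Simulate one two-channel imaging field with ground truth
#'
#' Renders a single site of a live-cell ciliation assay: channel W1 holds
#' Hoechst-like nuclei (Gaussian blobs), channel W2 holds the ciliary
#' reporter -- elongated high-intensity cilium objects anchored beside
#' nuclei, plus cytoplasmic background vesicles, a constant camera offset,
#' and Gaussian read noise with a Poisson-like (intensity-proportional)
#' shot-noise component. The paired ground truth records every cell, its
#' ciliation state and cilium geometry, so detection can be scored exactly.
#'
#' The same `seed` always yields bit-identical pixels and ground truth.
#'
#' @param profile A [sim_profile()].
#' @param effect A [perturbation()] applied to the field before rendering,
#'   or `NULL` for the unperturbed baseline.
#' @param seed Integer seed fixing the field completely.
#' @param dim Field size in pixels, `c(rows, cols)`.
#' @param pixel_size_um Physical pixel pitch in micrometres (default 0.325,
#'   a 20x-objective class sampling).
#' @param corruption One of `"none"`, `"cell_loss"` (a majority of cells
#'   detach), `"haze"` (a broad out-of-focus background bump in W2).
#' @param render If `FALSE`, skip pixel rendering and return only ground
#'   truth (images are `NULL`); useful for fast metric-level simulation.
#' @param plate_id,well_id,site_index,run_index Identity stamped on the
#'   returned field.
#'
#' @return A list with elements `field` (class `field_image`: `w1`, `w2`
#'   integer matrices plus identity and `pixel_size_um`) and `truth` (class
#'   `field_truth`: `n_cells`, a `cells` tibble with nucleus positions,
#'   ciliated flags and cilium geometry, `n_background`, `corruption`).
#' @examples
#' fg <- generate_field(sim_profile("arl13b_low_bg", cells_per_field = 10),
#'                      seed = 1, dim = c(256, 256))
#' fg$truth$n_cells
#' @export
generate_field <- function(profile, effect = NULL, seed,
                           dim = c(1024, 1024), pixel_size_um = 0.325,
                           corruption = c("none", "cell_loss", "haze"),
                           render = TRUE,
                           plate_id = "SIM", well_id = "A01",
                           site_index = 1L, run_index = "IR1") {
  corruption <- match.arg(corruption)
  check_field_geometry(dim, pixel_size_um)
  validate_sim_profile(profile)
  with_fixed_seed(seed, {
    layout <- sample_layout(profile, dim, pixel_size_um)
    if (!is.null(effect)) layout <- apply_perturbation(layout, effect, profile)
    if (corruption == "cell_loss") layout <- apply_cell_loss(layout)
    imgs <- if (render) {
      render_layout(layout, profile, dim, pixel_size_um,
                    haze = corruption == "haze")
    } else list(w1 = NULL, w2 = NULL)
    list(
      field = new_field_image(plate_id, well_id, site_index, run_index,
                              imgs$w1, imgs$w2, pixel_size_um),
      truth = new_field_truth(layout, corruption)
    )
  })
}

#' Simulate a paired IR1/IR2 site
#'
#' Generates the baseline run (IR1) and the post-perturbation run (IR2) of
#' the same field: nucleus layout and cilium geometry are shared, the
#' perturbation flips a `disassembly_fraction` subset of the ciliated flags
#' and shrinks surviving cilia before IR2 is rendered with fresh noise.
#' Corruption, when requested, affects IR2 (cell detachment or haze).
#'
#' Cilium loss is coupled across disassembly fractions: at a fixed seed each
#' cell carries a latent uniform, so a larger `disassembly_fraction` loses a
#' superset of the cilia lost at a smaller one.
#'
#' @inheritParams generate_field
#' @param effect A [perturbation()] describing the well's treatment.
#' @return A list `ir1`, `ir2` (each `list(field, truth)` as in
#'   [generate_field()]).
#' @export
generate_site_pair <- function(profile, effect, seed,
                               dim = c(1024, 1024), pixel_size_um = 0.325,
                               corruption = c("none", "cell_loss", "haze"),
                               render = TRUE,
                               plate_id = "SIM", well_id = "A01",
                               site_index = 1L) {
  corruption <- match.arg(corruption)
  check_field_geometry(dim, pixel_size_um)
  validate_sim_profile(profile)
  with_fixed_seed(seed, {
    layout <- sample_layout(profile, dim, pixel_size_um)
    imgs1 <- if (render) {
      render_layout(layout, profile, dim, pixel_size_um, haze = FALSE)
    } else list(w1 = NULL, w2 = NULL)
    layout2 <- apply_perturbation(layout, effect, profile)
    if (corruption == "cell_loss") layout2 <- apply_cell_loss(layout2)
    imgs2 <- if (render) {
      render_layout(layout2, profile, dim, pixel_size_um,
                    haze = corruption == "haze")
    } else list(w1 = NULL, w2 = NULL)
    list(
      ir1 = list(
        field = new_field_image(plate_id, well_id, site_index, "IR1",
                                imgs1$w1, imgs1$w2, pixel_size_um),
        truth = new_field_truth(layout, "none")
      ),
      ir2 = list(
        field = new_field_image(plate_id, well_id, site_index, "IR2",
                                imgs2$w1, imgs2$w2, pixel_size_um),
        truth = new_field_truth(layout2, corruption)
      )
    )
  })
}

check_field_geometry <- function(dim, pixel_size_um) {
  if (length(dim) != 2 || any(!is.finite(dim)) || any(dim < 8)) {
    abort("Field dimensions must be two finite pixel counts >= 8.")
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be a positive length in micrometres.")
  }
  invisible(TRUE)
}

new_field_image <- function(plate_id, well_id, site_index, run_index,
                            w1, w2, pixel_size_um) {
  if (!is.null(w1) && !is.null(w2) && !identical(base::dim(w1), base::dim(w2))) {
    abort("W1 and W2 rasters must have identical dimensions.")
  }
  structure(
    list(plate_id = plate_id, well_id = well_id,
         site_index = as.integer(site_index), run_index = run_index,
         w1 = w1, w2 = w2, pixel_size_um = pixel_size_um),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- if (is.null(x$w1)) "unrendered" else paste(dim(x$w1), collapse = "x")
  cat("<field_image> ", x$plate_id, " ", x$well_id, " site ", x$site_index,
      " ", x$run_index, " (", d, " px, ", x$pixel_size_um, " um/px)\n", sep = "")
  invisible(x)
}

new_field_truth <- function(layout, corruption) {
  cells <- layout$cells
  keep <- c("x", "y", "ciliated", "length_um", "width_um", "angle")
  structure(
    list(
      n_cells = nrow(cells),
      cells = tibble::new_tibble(as.list(cells)[keep], nrow = nrow(cells)),
      n_ciliated = sum(cells$ciliated),
      total_cilium_area_um2 = sum(cells$length_um[cells$ciliated] *
                                    cells$width_um[cells$ciliated]),
      n_background = nrow(layout$vesicles),
      corruption = corruption
    ),
    class = "field_truth"
  )
}

#' @export
print.field_truth <- function(x, ...) {
  cat("<field_truth> ", x$n_cells, " cells, ", x$n_ciliated, " ciliated, ",
      x$n_background, " background objects",
      if (x$corruption != "none") paste0(" [", x$corruption, "]"), "\n", sep = "")
  invisible(x)
}

# ---- layout sampling -------------------------------------------------------

sample_layout <- function(profile, dim, pixel_size_um) {
  fh <- dim[1] * pixel_size_um
  fw <- dim[2] * pixel_size_um
  margin <- 2
  n_target <- rpois(1, profile$cells_per_field)
  d2min <- profile$min_center_distance_um^2
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; max_attempts <- 80L * max(n_target, 1L)
  while (length(xs) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    px <- runif(1, margin, fw - margin)
    py <- runif(1, margin, fh - margin)
    if (!length(xs) || all((xs - px)^2 + (ys - py)^2 >= d2min)) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  n <- length(xs)
  ciliated <- runif(n) < profile$ciliation_fraction
  angle <- runif(n, 0, 2 * pi)
  length_um <- rtruncnorm_spec(n, profile$cilium_length_um)
  length_um[!ciliated] <- NA_real_
  angle[!ciliated] <- NA_real_
  cells <- tibble::new_tibble(list(
    x = xs, y = ys,
    u_loss = runif(n), u_keep = runif(n),
    ciliated = ciliated,
    length_um = length_um,
    width_um = ifelse(ciliated, profile$cilium_width_um, NA_real_),
    angle = angle
  ), nrow = n)
  n_ves <- rpois(1, profile$background_vesicles_per_cell * n)
  vesicles <- if (n_ves > 0 && n > 0) {
    host <- sample.int(n, n_ves, replace = TRUE)
    tibble::new_tibble(list(
      x = pmin(fw, pmax(0, xs[host] + rnorm(n_ves, 0, 5))),
      y = pmin(fh, pmax(0, ys[host] + rnorm(n_ves, 0, 5))),
      size_um = rtruncnorm_spec(n_ves, profile$background_vesicle_size_um),
      amp = pmax(0, rnorm(n_ves, profile$background_vesicle_amplitude$mean,
                          profile$background_vesicle_amplitude$sd))
    ), nrow = n_ves)
  } else {
    tibble::new_tibble(list(x = numeric(0), y = numeric(0),
                            size_um = numeric(0), amp = numeric(0)), nrow = 0L)
  }
  list(cells = cells, vesicles = vesicles, boost = 1)
}

apply_perturbation <- function(layout, effect, profile) {
  stopifnot(inherits(effect, "perturbation"))
  cells <- layout$cells
  lost <- cells$ciliated & cells$u_loss < effect$disassembly_fraction
  cells$ciliated <- cells$ciliated & !lost
  cells$length_um[lost] <- NA_real_
  cells$width_um[lost] <- NA_real_
  cells$angle[lost] <- NA_real_
  cells$length_um[cells$ciliated] <-
    cells$length_um[cells$ciliated] * effect$length_shrink_factor
  layout$cells <- cells
  if (isTRUE(profile$boost_on_serum)) layout$boost <- effect$background_boost
  layout
}

# Detached-cell corruption: the 60% of cells with the smallest latent
# uniform are removed (deterministic given the layout), and the mechanical
# disturbance that detaches cells also deciliates half of the survivors
# (shear forces independently strip cilia).
apply_cell_loss <- function(layout, fraction = 0.6, shear_deciliation = 0.5) {
  cells <- layout$cells
  n <- nrow(cells)
  if (n == 0) return(layout)
  drop_n <- ceiling(fraction * n)
  keep <- rank(cells$u_keep, ties.method = "first") > drop_n
  cells <- cells[keep, , drop = FALSE]
  sheared <- cells$ciliated & runif(nrow(cells)) < shear_deciliation
  cells$ciliated <- cells$ciliated & !sheared
  cells$length_um[sheared] <- NA_real_
  cells$width_um[sheared] <- NA_real_
  cells$angle[sheared] <- NA_real_
  layout$cells <- cells
  layout
}

# ---- rendering -------------------------------------------------------------

render_layout <- function(layout, profile, dim, pixel_size_um, haze = FALSE) {
  nr <- dim[1]; nc <- dim[2]
  off <- profile$background_offset
  w1 <- matrix(off, nr, nc)
  w2 <- matrix(off, nr, nc)
  cells <- layout$cells
  sig_n <- (profile$nucleus_diameter_um / 3.8) / pixel_size_um
  for (i in seq_len(nrow(cells))) {
    p <- patch_blob(nr, nc, um_to_col(cells$x[i], pixel_size_um),
                    um_to_row(cells$y[i], pixel_size_um),
                    profile$nucleus_amplitude, sig_n)
    if (!is.null(p)) w1[p$rows, p$cols] <- w1[p$rows, p$cols] + p$patch
  }
  anchor_r <- profile$nucleus_diameter_um / 2 + 0.6
  s_px <- (profile$cilium_width_um / 2) / pixel_size_um
  for (i in which(cells$ciliated)) {
    ca <- cells$angle[i]
    x0 <- cells$x[i] + anchor_r * cos(ca)
    y0 <- cells$y[i] + anchor_r * sin(ca)
    x1 <- x0 + cells$length_um[i] * cos(ca)
    y1 <- y0 + cells$length_um[i] * sin(ca)
    p <- patch_segment(nr, nc,
                       um_to_col(x0, pixel_size_um), um_to_row(y0, pixel_size_um),
                       um_to_col(x1, pixel_size_um), um_to_row(y1, pixel_size_um),
                       profile$cilium_amplitude, s_px)
    if (!is.null(p)) w2[p$rows, p$cols] <- w2[p$rows, p$cols] + p$patch
  }
  ves <- layout$vesicles
  for (i in seq_len(nrow(ves))) {
    p <- patch_blob(nr, nc, um_to_col(ves$x[i], pixel_size_um),
                    um_to_row(ves$y[i], pixel_size_um),
                    ves$amp[i] * layout$boost,
                    (ves$size_um[i] / 2.355) / pixel_size_um)
    if (!is.null(p)) w2[p$rows, p$cols] <- w2[p$rows, p$cols] + p$patch
  }
  if (haze) {
    hx <- runif(1, 0.2, 0.8) * nc * pixel_size_um
    hy <- runif(1, 0.2, 0.8) * nr * pixel_size_um
    hs <- runif(1, 30, 45) / pixel_size_um
    p <- patch_blob(nr, nc, um_to_col(hx, pixel_size_um),
                    um_to_row(hy, pixel_size_um),
                    profile$cilium_amplitude, hs, extent = 2.5)
    if (!is.null(p)) w2[p$rows, p$cols] <- w2[p$rows, p$cols] + p$patch
  }
  top <- 2^profile$bit_depth - 1
  nsd2 <- profile$noise_sd^2
  shot <- profile$shot_scale
  quantize <- function(img) {
    # img is offset + non-negative signal, so the shot-noise term needs no clamp
    out <- round(img + rnorm(length(img)) * sqrt(nsd2 + shot * img))
    out[out < 0] <- 0
    out[out > top] <- top
    dim(out) <- c(nr, nc)
    out
  }
  list(w1 = quantize(w1), w2 = quantize(w2))
}
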