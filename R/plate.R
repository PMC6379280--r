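#' Simulate a full paired-run plate dataset
#'
#' Generates both imaging runs for every (well, site) of a plate design:
#' IR1 is the starved baseline, IR2 the post-perturbation run sharing the
#' same nucleus layout with the well's perturbation applied in between.
#' Corrupted sites listed in the design are realized in IR2 (cell loss or
#' haze). With `dir` set, one 16-bit grayscale TIFF is written per
#' (well, site, wavelength, run) as
#' `{plate}_{well}_s{site}_w{1|2}_{IR1|IR2}.tif` together with
#' `manifest.csv` and `ground_truth.csv`; otherwise rendered fields are
#' kept in memory (suitable for small designs only).
#'
#' Identical (design, profile, dimensions) input yields bit-identical
#' images, manifest and ground truth.
#'
#' @param design A [plate_design()].
#' @param profile A [sim_profile()].
#' @param dim Field size in pixels, `c(rows, cols)`.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param render If `FALSE`, generate ground truth and manifest only
#'   (fast metric-level simulation; no pixels).
#' @param dir Optional output directory for TIFFs and CSVs.
#' @return An object of class `plate_dataset`: `manifest` (one row per
#'   well/site/wavelength/run), `truth` (per well/site/run ground-truth
#'   tibble), `fields` (named list of `field_image`, in-memory mode only),
#'   plus the design, profile and geometry used.
#' @examples
#' pd <- plate_design(
#'   data.frame(well = c("A01", "B01"), role = c("vehicle_starved", "serum_control")),
#'   sites_per_well = 2, seed = 3
#' )
#' plate <- generate_plate(pd, sim_profile("arl13b_low_bg", cells_per_field = 8),
#'                         dim = c(128, 128), render = FALSE)
#' plate$truth
#' @export
generate_plate <- function(design, profile, dim = c(1024, 1024),
                           pixel_size_um = 0.325, render = TRUE, dir = NULL) {
  stopifnot(inherits(design, "plate_design"))
  validate_sim_profile(profile)
  check_field_geometry(dim, pixel_size_um)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wells <- design$wells
  S <- design$sites_per_well
  corr_key <- paste(design$corrupted$well, design$corrupted$site)
  # per-site seeds drawn from the plate's own stream: unlike arithmetic
  # well/site formulas, sampled seeds carry no cross-well structure
  site_seeds <- with_fixed_seed(design$seed, {
    matrix(sample.int(2147483646L, nrow(wells) * S), nrow(wells), S)
  })
  fields <- if (render && is.null(dir)) list() else NULL
  truth_rows <- vector("list", nrow(wells) * S * 2)
  manifest_rows <- vector("list", nrow(wells) * S * 2)
  k <- 0L
  for (wi in seq_len(nrow(wells))) {
    w <- wells[wi, ]
    effect <- perturbation(w$disassembly_fraction, w$length_shrink_factor,
                           w$background_boost)
    for (s in seq_len(S)) {
      hit <- match(paste(w$well, s), corr_key)
      corruption <- if (is.na(hit)) "none" else design$corrupted$corruption[hit]
      pair <- generate_site_pair(
        profile, effect, seed = site_seeds[wi, s],
        dim = dim, pixel_size_um = pixel_size_um, corruption = corruption,
        render = render, plate_id = design$plate_id, well_id = w$well,
        site_index = s
      )
      for (run in c("IR1", "IR2")) {
        fr <- if (run == "IR1") pair$ir1 else pair$ir2
        k <- k + 1L
        truth_rows[[k]] <- list(
          plate_id = design$plate_id, well_id = w$well, site_index = s,
          run_index = run,
          n_cells = fr$truth$n_cells, n_ciliated = fr$truth$n_ciliated,
          n_background = fr$truth$n_background,
          total_cilium_area_um2 = fr$truth$total_cilium_area_um2,
          corruption = fr$truth$corruption
        )
        paths <- if (is.null(dir)) c(NA_character_, NA_character_) else {
          file.path(dir, sprintf("%s_%s_s%d_w%d_%s.tif",
                                 design$plate_id, w$well, s, 1:2, run))
        }
        manifest_rows[[k]] <- list(
          plate = design$plate_id, well = w$well, site = s, run = run,
          path1 = paths[1], path2 = paths[2]
        )
        if (render) {
          if (!is.null(dir)) {
            write_field_tiff(fr$field, paths)
          } else {
            fields[[field_key(w$well, s, run)]] <- fr$field
          }
        }
      }
    }
  }
  bind_row_lists <- function(rows) {
    cols <- names(rows[[1]])
    as_tibble(lapply(stats::setNames(cols, cols), function(cn) {
      unlist(lapply(rows, `[[`, cn), use.names = FALSE)
    }))
  }
  wide <- bind_row_lists(manifest_rows)
  manifest <- tibble(
    plate = rep(wide$plate, each = 2), well = rep(wide$well, each = 2),
    site = rep(wide$site, each = 2), wavelength = rep(1:2, nrow(wide)),
    run = rep(wide$run, each = 2),
    path = as.vector(rbind(wide$path1, wide$path2))
  )
  truth <- bind_row_lists(truth_rows)
  if (!is.null(dir)) {
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  }
  structure(
    list(manifest = manifest, truth = truth, fields = fields,
         design = design, profile = profile, dim = dim,
         pixel_size_um = pixel_size_um, dir = dir),
    class = "plate_dataset"
  )
}

field_key <- function(well, site, run) paste(well, site, run, sep = "_")

write_field_tiff <- function(field, paths) {
  top <- 65535
  tiff::writeTIFF(field$w1 / top, paths[1], bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(field$w2 / top, paths[2], bits.per.sample = 16L,
                  compression = "none")
  invisible(paths)
}

#' @export
print.plate_dataset <- function(x, ...) {
  n_fields <- nrow(dplyr::distinct(x$manifest, .data$well, .data$site, .data$run))
  cat("<plate_dataset> ", x$design$plate_id, ": ", nrow(x$design$wells),
      " wells x ", x$design$sites_per_well, " sites x 2 runs = ", n_fields,
      " field images (", x$profile$profile_name, ")\n", sep = "")
  if (!is.null(x$dir)) cat("  on disk at ", x$dir, "\n", sep = "")
  if (is.null(x$fields) && is.null(x$dir)) cat("  ground truth only (not rendered)\n")
  invisible(x)
}

#' Retrieve one rendered field from a plate dataset
#'
#' Reads from memory or from the dataset's TIFF directory as appropriate.
#'
#' @param plate A `plate_dataset`.
#' @param well_id,site_index,run_index Field identity.
#' @return A `field_image`.
#' @export
plate_field <- function(plate, well_id, site_index, run_index) {
  stopifnot(inherits(plate, "plate_dataset"))
  key <- field_key(well_id, site_index, run_index)
  if (!is.null(plate$fields)) {
    f <- plate$fields[[key]]
    if (is.null(f)) abort(paste0("No such field: ", key))
    return(f)
  }
  if (is.null(plate$dir)) {
    abort("Plate was generated with render = FALSE; no pixel data available.")
  }
  rows <- dplyr::filter(plate$manifest, .data$well == well_id,
                        .data$site == site_index, .data$run == run_index)
  if (nrow(rows) != 2) abort(paste0("No such field in manifest: ", key))
  read_field_image(rows$path[rows$wavelength == 1],
                   rows$path[rows$wavelength == 2],
                   plate_id = plate$design$plate_id, well_id = well_id,
                   site_index = site_index, run_index = run_index,
                   pixel_size_um = plate$pixel_size_um)
}

#' Read a two-channel field from 16-bit TIFF files
#'
#' @param w1_path,w2_path Paths to the nuclei (W1) and cilia (W2) TIFFs.
#' @param plate_id,well_id,site_index,run_index Identity to stamp.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return A `field_image`.
#' @export
read_field_image <- function(w1_path, w2_path, plate_id = "P1",
                             well_id = "A01", site_index = 1L,
                             run_index = "IR1", pixel_size_um = 0.325) {
  w1 <- round(tiff::readTIFF(w1_path) * 65535)
  w2 <- round(tiff::readTIFF(w2_path) * 65535)
  new_field_image(plate_id, well_id, site_index, run_index, w1, w2,
                  pixel_size_um)
}
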