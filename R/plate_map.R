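WELL_ROLES <- c("vehicle_starved", "serum_control", "reference_stabilizer",
                "reference_disassembler", "compound")
CORRUPTION_KINDS <- c("cell_loss", "haze")

# Default between-run effects by well role. Serum removes ~40% of cilia
# (middle of the 20-60% dynamic range seen with 25% serum in this assay
# format) and shrinks survivors; the HSP90-inhibitor reference induces
# disassembly, the Aurora-A-inhibitor reference blocks it.
role_default_effect <- function(role) {
  switch(role,
    vehicle_starved = c(0, 1, 1),
    serum_control = c(0.4, 0.85, 1.5),
    reference_disassembler = c(0.5, 0.8, 1),
    reference_stabilizer = c(0, 1, 1),
    compound = c(0, 1, 1)
  )
}

#' Construct and validate a plate design
#'
#' A plate design assigns each well a role (starved-vehicle baseline
#' control, serum control, reference compounds, or test compound), the
#' between-run perturbation it produces, and optionally a set of corrupted
#' sites (detached cells or image haze) for quality-control testing.
#'
#' @param wells A data frame with columns `well` (e.g. `"A01"`..`"H12"`) and
#'   `role` (one of `r paste(WELL_ROLES, collapse = ", ")`), and optionally
#'   `compound_id`, `concentration_nM`, `disassembly_fraction`,
#'   `length_shrink_factor`, `background_boost`. Missing effect columns are
#'   filled from role defaults.
#' @param sites_per_well Number of imaged sites per well (default 9, the
#'   standard for this assay).
#' @param corrupted Optional data frame with columns `well`, `site`,
#'   `corruption` (`"cell_loss"` or `"haze"`); defaults to none.
#' @param seed Integer seed for the whole plate simulation.
#' @param plate_id Identifier stamped on images and tables.
#' @return An object of class `plate_design`.
#' @examples
#' pd <- plate_design(
#'   data.frame(well = c("A01", "A02"), role = c("vehicle_starved", "serum_control")),
#'   sites_per_well = 3, seed = 7
#' )
#' pd$wells
#' @export
plate_design <- function(wells, sites_per_well = 9, corrupted = NULL,
                         seed = 1, plate_id = "P1") {
  wells <- as_tibble(wells)
  if (!all(c("well", "role") %in% names(wells))) {
    abort("Plate map needs at least the columns 'well' and 'role'.")
  }
  bad_well <- !grepl("^[A-H](0[1-9]|1[0-2])$", wells$well)
  if (any(bad_well)) {
    abort(paste0("Invalid well id(s) (expected A01..H12): row ",
                 paste(which(bad_well), collapse = ", "), " (",
                 paste(unique(wells$well[bad_well]), collapse = ", "), ")"))
  }
  dup <- wells$well[duplicated(wells$well)]
  if (length(dup)) {
    abort(paste0("Duplicate well id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_role <- !(wells$role %in% WELL_ROLES)
  if (any(bad_role)) {
    abort(paste0("Unknown role(s): row ",
                 paste(which(bad_role), collapse = ", "), " (",
                 paste(unique(wells$role[bad_role]), collapse = ", "), ")"))
  }
  if (!any(wells$role == "vehicle_starved")) {
    abort("No baseline control: the plate map must contain at least one 'vehicle_starved' well.")
  }
  if (all(wells$role == "vehicle_starved")) {
    abort("A screening design needs at least one perturbed (non-vehicle) well role.")
  }
  if (sites_per_well < 1) abort("sites_per_well must be >= 1.")
  defaults <- t(vapply(wells$role, role_default_effect, numeric(3)))
  if (!"compound_id" %in% names(wells)) wells$compound_id <- NA_character_
  wells$compound_id <- as.character(wells$compound_id)
  auto_id <- is.na(wells$compound_id) | wells$compound_id == ""
  wells$compound_id[auto_id] <- dplyr::case_when(
    wells$role[auto_id] == "vehicle_starved" ~ "vehicle",
    wells$role[auto_id] == "serum_control" ~ "serum",
    wells$role[auto_id] == "reference_stabilizer" ~ "alisertib",
    wells$role[auto_id] == "reference_disassembler" ~ "ganetespib",
    TRUE ~ paste0("cmpd_", wells$well[auto_id])
  )
  if (!"concentration_nM" %in% names(wells)) wells$concentration_nM <- NA_real_
  for (k in seq_along(eff_cols <- c("disassembly_fraction", "length_shrink_factor",
                                    "background_boost"))) {
    col <- eff_cols[k]
    if (!col %in% names(wells)) wells[[col]] <- NA_real_
    miss <- is.na(wells[[col]])
    wells[[col]][miss] <- defaults[miss, k]
  }
  if (any(wells$disassembly_fraction < 0 | wells$disassembly_fraction > 1)) {
    abort("disassembly_fraction must lie in [0, 1].")
  }
  corrupted <- if (is.null(corrupted)) {
    tibble(well = character(0), site = integer(0), corruption = character(0))
  } else {
    as_tibble(corrupted)
  }
  if (nrow(corrupted)) {
    stopifnot(all(c("well", "site", "corruption") %in% names(corrupted)))
    if (anyDuplicated(corrupted[, c("well", "site")])) {
      abort("Duplicate (well, site) corruption entries are not allowed.")
    }
    if (!all(corrupted$corruption %in% CORRUPTION_KINDS)) {
      abort(paste0("Corruption kind must be one of: ",
                   paste(CORRUPTION_KINDS, collapse = ", ")))
    }
    if (!all(corrupted$well %in% wells$well)) {
      abort("Corrupted sites reference wells absent from the design.")
    }
    if (any(corrupted$site < 1 | corrupted$site > sites_per_well)) {
      abort("Corrupted site index outside 1..sites_per_well.")
    }
  }
  structure(
    list(wells = wells[, c("well", "role", "compound_id", "concentration_nM",
                           "disassembly_fraction", "length_shrink_factor",
                           "background_boost")],
         sites_per_well = as.integer(sites_per_well),
         corrupted = corrupted,
         seed = as.integer(seed),
         plate_id = plate_id),
    class = "plate_design"
  )
}

#' @export
print.plate_design <- function(x, ...) {
  cat("<plate_design> ", x$plate_id, ": ", nrow(x$wells), " wells x ",
      x$sites_per_well, " sites, seed ", x$seed, "\n", sep = "")
  print(table(x$wells$role))
  if (nrow(x$corrupted)) {
    cat("Corrupted sites: ", nrow(x$corrupted), "\n", sep = "")
  }
  invisible(x)
}

#' Read a plate map CSV into a validated plate design
#'
#' The CSV needs columns `well` and `role`; `compound_id`,
#' `concentration_nM`, `disassembly_fraction`, `length_shrink_factor` and
#' `background_boost` are optional and default by role. Validation errors
#' name the offending rows and wells.
#'
#' @param path Path to the plate map CSV.
#' @inheritParams plate_design
#' @return A `plate_design`.
#' @export
read_plate_map <- function(path, sites_per_well = 9, corrupted = NULL,
                           seed = 1, plate_id = "P1") {
  if (!file.exists(path)) abort(paste0("Plate map not found: ", path))
  wells <- readr::read_csv(path, show_col_types = FALSE)
  plate_design(wells, sites_per_well = sites_per_well, corrupted = corrupted,
               seed = seed, plate_id = plate_id)
}

#' Write a plate design's well map to CSV
#'
#' @param design A `plate_design`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(design, path) {
  stopifnot(inherits(design, "plate_design"))
  readr::write_csv(design$wells, path)
  invisible(path)
}

#' A default 96-well screening layout
#'
#' Column 1 holds starved-vehicle baseline controls, column 2 serum
#' controls, column 3 the two reference compounds (Aurora-A-inhibitor
#' stabilizer at 200 nM, rows A--D; HSP90-inhibitor disassembler at
#' 500 nM, rows E--H), and columns 4--12 hold 36 test compounds in
#' duplicate wells (vertical pairs).
#'
#' @inheritParams plate_design
#' @param mode Screen direction; in `"block_disassembly"` every
#'   non-vehicle well additionally receives serum, so test compounds
#'   default to the serum-level disassembly fraction (a blocker would be
#'   simulated by overriding its `disassembly_fraction` downward).
#' @return A `plate_design` with 96 wells.
#' @export
design_screen_96 <- function(mode = c("induce_disassembly", "block_disassembly"),
                             sites_per_well = 9, corrupted = NULL, seed = 1,
                             plate_id = "P1") {
  mode <- match.arg(mode)
  rows <- LETTERS[1:8]
  wells <- tibble(
    well = paste0(rep(rows, times = 12), sprintf("%02d", rep(1:12, each = 8))),
    col = rep(1:12, each = 8),
    row = rep(1:8, times = 12)
  )
  wells$role <- dplyr::case_when(
    wells$col == 1 ~ "vehicle_starved",
    wells$col == 2 ~ "serum_control",
    wells$col == 3 & wells$row <= 4 ~ "reference_stabilizer",
    wells$col == 3 ~ "reference_disassembler",
    TRUE ~ "compound"
  )
  wells$concentration_nM <- dplyr::case_when(
    wells$role == "reference_stabilizer" ~ 200,
    wells$role == "reference_disassembler" ~ 500,
    wells$role == "compound" ~ 1000,
    TRUE ~ NA_real_
  )
  cmp <- wells$role == "compound"
  wells$compound_id <- NA_character_
  wells$compound_id[cmp] <- paste0(
    "cmpd_", sprintf("%02d", (wells$col[cmp] - 4) * 4 + ceiling(wells$row[cmp] / 2))
  )
  if (mode == "block_disassembly") {
    serum_like <- wells$role %in% c("compound", "reference_stabilizer",
                                    "reference_disassembler")
    wells$disassembly_fraction <- NA_real_
    wells$disassembly_fraction[serum_like] <- 0.4
    wells$disassembly_fraction[wells$role == "reference_stabilizer"] <- 0.05
    wells$disassembly_fraction[wells$role == "reference_disassembler"] <- 0.7
  }
  plate_design(wells[, setdiff(names(wells), c("col", "row"))],
               sites_per_well = sites_per_well, corrupted = corrupted,
               seed = seed, plate_id = plate_id)
}
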